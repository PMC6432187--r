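#' Reference table of Alexander-polynomial fingerprints
#'
#' Alexander polynomials (symmetric normalisation) of all prime knots up
#' to 8 crossings plus the unknot, with the fingerprint
#' `Delta_p = |Delta(t) * Delta(1/t)|` evaluated at `t = -1.1`. This
#' product cancels the `+/- t^k` normalisation ambiguity of the
#' polynomial and identifies the small knots uniquely; note 4_1 and 5_1
#' differ by only about 1.5% at this evaluation point, which motivates
#' the default classification tolerance of 1e-3 (well below half that
#' gap). The Alexander invariant is achiral, so mirror knots share a
#' fingerprint.
#'
#' @return A tibble with `label`, `crossings` and `delta_p`.
#' @export
knot_table <- function() {
  # coefficients from highest to lowest power, symmetric about t^0
  coefs <- list(
    "0_1" = c(1),
    "3_1" = c(1, -1, 1),
    "4_1" = c(1, -3, 1),
    "5_1" = c(1, -1, 1, -1, 1),
    "5_2" = c(2, -3, 2),
    "6_1" = c(2, -5, 2),
    "6_2" = c(1, -3, 3, -3, 1),
    "6_3" = c(1, -3, 5, -3, 1),
    "7_1" = c(1, -1, 1, -1, 1, -1, 1),
    "7_2" = c(3, -5, 3),
    "7_3" = c(2, -3, 3, -3, 2),
    "7_4" = c(4, -7, 4),
    "7_5" = c(2, -4, 5, -4, 2),
    "7_6" = c(1, -5, 7, -5, 1),
    "7_7" = c(1, -5, 9, -5, 1),
    "8_1" = c(3, -7, 3),
    "8_2" = c(1, -3, 3, -3, 3, -3, 1),
    "8_3" = c(4, -9, 4),
    "8_4" = c(2, -5, 5, -5, 2),
    "8_5" = c(1, -3, 4, -5, 4, -3, 1),
    "8_6" = c(2, -6, 7, -6, 2),
    "8_7" = c(1, -3, 5, -5, 5, -3, 1),
    "8_8" = c(2, -6, 9, -6, 2),
    "8_9" = c(1, -3, 5, -7, 5, -3, 1),
    "8_10" = c(1, -3, 6, -7, 6, -3, 1),
    "8_11" = c(2, -7, 9, -7, 2),
    "8_12" = c(1, -7, 13, -7, 1),
    "8_13" = c(2, -7, 11, -7, 2),
    "8_14" = c(2, -8, 11, -8, 2),
    "8_15" = c(3, -8, 11, -8, 3),
    "8_16" = c(1, -4, 8, -9, 8, -4, 1),
    "8_17" = c(1, -4, 8, -11, 8, -4, 1),
    "8_18" = c(1, -5, 10, -13, 10, -5, 1),
    "8_19" = c(1, -1, 0, 1, 0, -1, 1),
    "8_20" = c(1, -2, 3, -2, 1),
    "8_21" = c(1, -4, 5, -4, 1))
  eval_poly <- function(cf, t) {
    m <- (length(cf) - 1) / 2
    sum(cf * t^(m:(-m)))
  }
  t0 <- -1.1
  dp <- vapply(coefs, function(cf) {
    abs(eval_poly(cf, t0) * eval_poly(cf, 1 / t0))
  }, numeric(1))
  cross_n <- vapply(strsplit(names(coefs), "_"), function(s)
    as.integer(s[1]), integer(1))
  cross_n[1] <- 0L
  tibble::tibble(label = names(coefs), crossings = cross_n,
                 delta_p = unname(dp))
}

#' Virtually close an open chain
#'
#' Extends both endpoints radially outward from the chain's centre of
#' mass onto a sphere of radius three times the maximal bead-to-centre
#' distance, then joins them through a far apex point, adding exactly
#' three vertices. Deterministic given the conformation. The closure arc
#' stays well outside the chain's bounding sphere, keeping spurious
#' entanglement with the chain minimal; conformations close to the
#' knotting transition can nevertheless be closure-sensitive (a known
#' caveat of any virtual closure).
#'
#' @param positions An `N x 3` matrix of chain coordinates, or an already
#'   closed curve (class `closed_curve`), which is returned unchanged.
#' @return An object of class `closed_curve`: the vertex matrix of a
#'   closed polygon (the edge from the last to the first vertex is
#'   implicit) with a `provenance` attribute.
#' @export
close_chain <- function(positions) {
  if (inherits(positions, "closed_curve")) return(positions)
  if (inherits(positions, "polymer_conf")) {
    stopifnot(positions$n_chains == 1)
    positions <- positions$positions
  }
  p <- as.matrix(positions)
  n <- nrow(p)
  stopifnot(n >= 3)
  com <- colMeans(p)
  rmax <- sqrt(max(rowSums(sweep(p, 2, com)^2)))
  if (rmax < 1e-12) stop("degenerate chain: all beads coincide")
  radial <- function(v) {
    d <- v - com
    nd <- sqrt(sum(d^2))
    if (nd < 1e-12) d <- c(1, 0, 0) else d <- d / nd
    com + 3 * rmax * d
  }
  q1 <- radial(p[1, ])
  qn <- radial(p[n, ])
  u1 <- (q1 - com) / (3 * rmax)
  un <- (qn - com) / (3 * rmax)
  bis <- u1 + un
  if (sqrt(sum(bis^2)) < 1e-8) {
    # antipodal endpoints: any perpendicular direction
    bis <- c(-u1[2], u1[1], 0)
    if (sqrt(sum(bis^2)) < 1e-8) bis <- c(0, -u1[3], u1[2])
  }
  apex <- com + 6 * rmax * bis / sqrt(sum(bis^2))
  out <- rbind(p, qn, apex, q1)
  structure(out, class = "closed_curve",
            provenance = list(kind = "closed-from-open",
                              added = 3L, rmax = rmax))
}

#' Project a closed curve and list its crossings
#'
#' Projects the polygon onto the plane perpendicular to `direction` and
#' finds every crossing of non-adjacent segments, recording for each the
#' positions of the under- and over-strand along the curve and the
#' crossing sign. A non-generic projection (segment nearly parallel to
#' the direction, near-tangential crossing, crossing too close to a
#' vertex) raises a condition of class `degenerate_projection` so the
#' caller can retry with a perturbed direction.
#'
#' @param curve A `closed_curve` (or bare vertex matrix of a closed
#'   polygon).
#' @param direction Length-3 projection direction (normalised internally).
#' @param eps Genericity tolerance.
#' @return A list with `n` (number of crossings), and vectors `t_under`,
#'   `t_over` (positions along the curve, in units of segment index) and
#'   `sign` per crossing.
#' @export
project_and_list_crossings <- function(curve, direction, eps = 1e-7) {
  v <- unclass(as.matrix(curve))
  n <- nrow(v)
  d <- direction / sqrt(sum(direction^2))
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- c(d[2] * a[3] - d[3] * a[2], d[3] * a[1] - d[1] * a[3],
          d[1] * a[2] - d[2] * a[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2], d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  P <- v %*% cbind(e1, e2)
  h <- drop(v %*% d)
  nxt <- c(2:n, 1)
  seg <- P[nxt, ] - P  # 2D segment vectors
  seg_len <- sqrt(rowSums(seg^2))
  len3 <- sqrt(rowSums((v[nxt, ] - v)^2))
  degenerate <- function(msg) {
    cond <- structure(class = c("degenerate_projection", "error",
                                "condition"),
                      list(message = msg, call = sys.call(-1)))
    stop(cond)
  }
  if (any(seg_len < eps * len3)) {
    degenerate("segment nearly parallel to the projection direction")
  }
  t_under <- c(); t_over <- c(); sgn <- c()
  for (i in 1:(n - 1)) {
    if (i + 2 > n) next
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]  # cyclic adjacency
    if (length(js) == 0) next
    # bounding-box prefilter
    xi <- range(P[c(i, nxt[i]), 1]); yi <- range(P[c(i, nxt[i]), 2])
    keep <- pmin(P[js, 1], P[nxt[js], 1]) <= xi[2] &
            pmax(P[js, 1], P[nxt[js], 1]) >= xi[1] &
            pmin(P[js, 2], P[nxt[js], 2]) <= yi[2] &
            pmax(P[js, 2], P[nxt[js], 2]) >= yi[1]
    js <- js[keep]
    for (j in js) {
      det0 <- seg[i, 1] * seg[j, 2] - seg[i, 2] * seg[j, 1]
      if (abs(det0) < eps * seg_len[i] * seg_len[j]) {
        # parallel in projection; only degenerate if actually overlapping
        next
      }
      rhs <- P[j, ] - P[i, ]
      s <- (rhs[1] * seg[j, 2] - rhs[2] * seg[j, 1]) / det0
      u <- (rhs[1] * seg[i, 2] - rhs[2] * seg[i, 1]) / det0
      if (s <= -eps || s >= 1 + eps || u <= -eps || u >= 1 + eps) next
      if (s < eps || s > 1 - eps || u < eps || u > 1 - eps) {
        degenerate("crossing too close to a vertex")
      }
      zi <- h[i] + s * (h[nxt[i]] - h[i])
      zj <- h[j] + u * (h[nxt[j]] - h[j])
      if (abs(zi - zj) < eps * (1 + abs(zi))) {
        degenerate("strands touch at a crossing (non-generic)")
      }
      if (zi > zj) {
        io <- i; so <- s; iu <- j; su <- u
        d_over <- seg[i, ]; d_under <- seg[j, ]
      } else {
        io <- j; so <- u; iu <- i; su <- s
        d_over <- seg[j, ]; d_under <- seg[i, ]
      }
      t_under <- c(t_under, iu + su)
      t_over <- c(t_over, io + so)
      sgn <- c(sgn, sign(d_over[1] * d_under[2] - d_over[2] * d_under[1]))
    }
  }
  if (length(t_under) == 0) {
    return(list(n = 0L, t_under = numeric(0), t_over = numeric(0),
                sign = numeric(0)))
  }
  ord <- order(t_under)
  list(n = length(t_under), t_under = t_under[ord], t_over = t_over[ord],
       sign = sgn[ord])
}

#' Alexander fingerprint of a crossing diagram
#'
#' Builds the Alexander matrix from the crossing relations (generators
#' are the arcs between consecutive undercrossings), deletes one row and
#' column, and evaluates `|det|` at `t` and `1/t`; the returned product
#' `Delta_p = |Delta(t) Delta(1/t)|` is independent of the `+/- t^k`
#' normalisation of the Alexander polynomial. An (accidentally) singular
#' diagram returns `NA`, signalling the caller to retry with a different
#' projection.
#'
#' @param crossings Result of [project_and_list_crossings()].
#' @param t Evaluation point (default `-1.1`).
#' @return `Delta_p` (1 for the unknot diagram with 0 or 1 crossings).
#' @export
alexander_delta_p <- function(crossings, t = -1.1) {
  n <- crossings$n
  if (n <= 1) return(1)
  # generator j owns curve positions (t_under[j-1], t_under[j]] (cyclic)
  over_gen <- vapply(crossings$t_over, function(tt) {
    j <- which(crossings$t_under >= tt)
    if (length(j) == 0) 1L else j[1]
  }, integer(1))
  det_at <- function(tv) {
    A <- matrix(0, n, n)
    for (k in seq_len(n)) {
      kp <- if (k == n) 1L else k + 1L
      j <- over_gen[k]
      if (j == k || j == kp) {
        A[k, k] <- A[k, k] - 1
        A[k, kp] <- A[k, kp] + 1
      } else if (crossings$sign[k] > 0) {
        A[k, k] <- 1; A[k, kp] <- -tv; A[k, j] <- tv - 1
      } else {
        A[k, k] <- -tv; A[k, kp] <- 1; A[k, j] <- tv - 1
      }
    }
    det(A[-n, -n, drop = FALSE])
  }
  d1 <- det_at(t)
  d2 <- det_at(1 / t)
  abs(d1 * d2)
}

#' Classify a knot from its fingerprint
#'
#' Nearest match of `Delta_p` in the reference [knot_table()] within a
#' relative tolerance; `"unclassified"` otherwise.
#'
#' @param delta_p Fingerprint value.
#' @param tol Relative tolerance (default 1e-3, below half the 4_1/5_1
#'   gap at `t = -1.1`).
#' @return The class label, e.g. `"0_1"`, `"3_1"`, `"8_19"` or
#'   `"unclassified"`.
#' @export
classify_knot <- function(delta_p, tol = 1e-3) {
  tab <- knot_table()
  rel <- abs(tab$delta_p - delta_p) / tab$delta_p
  i <- which.min(rel)
  if (rel[i] <= tol) tab$label[i] else "unclassified"
}

#' Identify the knot type of a conformation
#'
#' Full pipeline: virtual closure, projection along a seed-derived random
#' direction (re-drawn on degenerate projections or singular diagrams up
#' to `max_retry` times), Alexander fingerprint and table lookup.
#'
#' @param positions Chain coordinates (`N x 3` matrix, single-chain
#'   [conformation()], or `closed_curve`).
#' @param seed Integer seed for the projection direction (reproducible).
#' @param max_retry Maximum number of perturbed directions to try.
#' @param tol Classification tolerance, see [classify_knot()].
#' @return A one-row tibble with `label`, `delta_p`, `crossings` (of the
#'   projection used) and `retries`.
#' @export
identify_knot <- function(positions, seed = 1, max_retry = 20, tol = 1e-3) {
  curve <- close_chain(positions)
  rs <- derive_seed(seed, 17)
  for (r in seq_len(max_retry)) {
    set.seed(rs + r - 1)
    dir <- stats::rnorm(3)
    res <- tryCatch(project_and_list_crossings(curve, dir),
                    degenerate_projection = function(e) NULL)
    if (is.null(res)) next
    dp <- alexander_delta_p(res)
    if (is.na(dp)) next
    return(tibble::tibble(label = classify_knot(dp, tol), delta_p = dp,
                          crossings = res$n, retries = r - 1L))
  }
  stop("no generic projection found after ", max_retry, " retries")
}

#' Knot statistics over a trajectory
#'
#' Classifies every frame and tabulates the fraction of each knot class;
#' with per-frame weights (e.g. canonical reweighting factors) the
#' fractions become reweighted expectations, so the knot type can serve
#' as a topological order parameter.
#'
#' @param trajectory A list of conformations (anything [close_chain()]
#'   accepts).
#' @param weights Optional per-frame weights.
#' @param seed Integer seed (per-frame projection seeds derived from it).
#' @return A list with `frames` (per-frame tibble: `frame`, `label`,
#'   `delta_p`, `crossings`) and `fractions` (tibble: `label`,
#'   `fraction`).
#' @export
knot_fraction <- function(trajectory, weights = NULL, seed = 1) {
  nf <- length(trajectory)
  if (is.null(weights)) weights <- rep(1, nf)
  stopifnot(length(weights) == nf)
  frames <- purrr::map_dfr(seq_len(nf), function(i) {
    dplyr::mutate(identify_knot(trajectory[[i]],
                                seed = derive_seed(seed, i)),
                  frame = i, .before = 1)
  })
  fr <- frames
  fr$w <- weights
  fractions <- fr |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(fraction = sum(.data$w) / sum(weights),
                     .groups = "drop")
  list(frames = frames, fractions = fractions)
}
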