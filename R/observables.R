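#' Squared radius of gyration
#'
#' `Rgyr^2 = sum_i (r_i - r_cm)^2 / N` on unwrapped chain coordinates.
#'
#' @param positions An `N x 3` matrix of bead positions of one chain,
#'   or a [conformation()] (averaged over chains).
#' @return Length squared.
#' @examples
#' rod <- make_fixture("rod", N = 28)
#' radius_of_gyration_sq(rod)  # (N^2 - 1) / 12 = 65.25 for unit spacing
#' @export
radius_of_gyration_sq <- function(positions) {
  if (inherits(positions, "polymer_conf")) {
    return(mean(vapply(seq_len(positions$n_chains), function(c0) {
      radius_of_gyration_sq(chain_positions(positions, c0))
    }, numeric(1))))
  }
  p <- as.matrix(positions)
  cm <- colMeans(p)
  mean(rowSums(sweep(p, 2, cm)^2))
}

#' End-to-end distance and direction
#'
#' `Ree = |r_1 - r_N|` with its unit vector. For `Ree < 1e-12` (closed
#' loops) the direction is undefined (`NA`) and such chains are excluded
#' from the end-to-end correlation parameter.
#'
#' @param positions An `N x 3` matrix of one chain's bead positions.
#' @return A list with `ree` and `unit` (length-3 vector, possibly `NA`).
#' @export
end_to_end <- function(positions) {
  p <- as.matrix(positions)
  v <- p[1, ] - p[nrow(p), ]
  ree <- sqrt(sum(v^2))
  if (ree < 1e-12) {
    list(ree = 0, unit = rep(NA_real_, 3))
  } else {
    list(ree = ree, unit = v / ree)
  }
}

#' End-to-end correlation parameter
#'
#' `CR = 2 / (M (M - 1)) * sum_{i<j} (Rhat_i . Rhat_j)^2`: the mean squared
#' pairwise alignment of the per-chain end-to-end unit vectors, similar to
#' a nematic order parameter and invariant under flipping any chain's
#' head/tail. `CR = 1` for completely aligned bundles and `1/3` in
#' expectation for uncorrelated chains (amorphous aggregates or the
#' fragmented regime).
#'
#' @param units An `M x 3` matrix of unit vectors (rows may contain `NA`
#'   for chains with undefined direction; such chains are excluded and the
#'   denominator adjusted).
#' @return A list with `cr`, the number of `pairs` used, and `flagged`
#'   (`TRUE` when any chain was excluded).
#' @examples
#' u <- matrix(rep(c(0, 0, 1), 4), ncol = 3, byrow = TRUE)
#' end_to_end_correlation(u)$cr  # 1
#' @export
end_to_end_correlation <- function(units) {
  u <- as.matrix(units)
  stopifnot(ncol(u) == 3, nrow(u) >= 2)
  ok <- stats::complete.cases(u)
  flagged <- any(!ok)
  u <- u[ok, , drop = FALSE]
  m <- nrow(u)
  if (m < 2) return(list(cr = NA_real_, pairs = 0L, flagged = TRUE))
  nrm <- sqrt(rowSums(u^2))
  stopifnot(all(abs(nrm - 1) < 1e-8))
  g <- u %*% t(u)
  cr <- sum(g[upper.tri(g)]^2) / choose(m, 2)
  list(cr = cr, pairs = choose(m, 2), flagged = flagged)
}

#' Phase-separation (aggregation) parameter
#'
#' `Gamma2 = 1 / (2 M^2) * sum_{i,j} |r_cm^i - r_cm^j|^2` over all ordered
#' chain pairs, with minimal-image centre-of-mass distances. Large in the
#' fragmented regime, drops sharply at aggregation. Centres of mass are
#' computed on unwrapped chains (valid while chain extents stay below
#' `L/2`) and wrapped once via the minimal image.
#'
#' @param rcm An `M x 3` matrix of per-chain centres of mass.
#' @param L Cubic box edge.
#' @return `Gamma2` (length squared).
#' @examples
#' rcm <- rbind(c(0, 0, 0), c(3, 0, 0))
#' phase_separation(rcm, L = 20)  # d^2 / 4 = 2.25
#' @export
phase_separation <- function(rcm, L) {
  r <- as.matrix(rcm)
  m <- nrow(r)
  stopifnot(ncol(r) == 3, m >= 1, L > 0)
  acc <- 0
  if (m >= 2) {
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        d <- minimal_image(r[i, ] - r[j, ], L)
        acc <- acc + sum(d^2)
      }
    }
  }
  acc / m^2  # = (1 / 2M^2) * ordered double sum
}

#' Observable vector of a conformation
#'
#' Per-conformation structural and aggregation observables: mean squared
#' radius of gyration and end-to-end distance over chains, the end-to-end
#' correlation `CR` and phase separation `Gamma2` for multi-chain systems.
#'
#' @param conf A [conformation()].
#' @return A one-row tibble with `rgyr2`, `ree`, `cr`, `gamma2`.
#' @export
measure_observables <- function(conf) {
  M <- conf$n_chains
  rg <- numeric(M); re <- numeric(M)
  units <- matrix(NA_real_, M, 3)
  rcm <- matrix(0, M, 3)
  for (c0 in seq_len(M)) {
    p <- chain_positions(conf, c0)
    rg[c0] <- radius_of_gyration_sq(p)
    ee <- end_to_end(p)
    re[c0] <- ee$ree
    units[c0, ] <- ee$unit
    rcm[c0, ] <- colMeans(p)
  }
  cr <- if (M >= 2) end_to_end_correlation(units)$cr else NA_real_
  g2 <- if (M >= 2 && !is.null(conf$box)) {
    phase_separation(rcm, conf$box)
  } else NA_real_
  tibble::tibble(rgyr2 = mean(rg), ree = mean(re), cr = cr, gamma2 = g2)
}

#' Two-dimensional potential-energy histogram
#'
#' Bins a series of `(ELJ, EBend)` pairs into a weighted 2D histogram at a
#' target temperature (weights per sample as in [reweight()]), together
#' with the 1D projection along the total energy `E = ELJ + kappa EBend`
#' (the diagonal of the 2D histogram). Phase coexistence that is invisible
#' in the 1D projection — two peaks aligned along the diagonal — remains
#' separated in the 2D distribution.
#'
#' @param series Tibble with columns `elj`, `ebend` and, for reweighting,
#'   `ep` and `lnw`.
#' @param kappa Bending stiffness used for the diagonal projection.
#' @param beta Target inverse temperature; `NULL` weights all samples
#'   equally.
#' @param n_bins Number of bins per axis.
#' @return An object of class `energy_hist2d`: bin centre vectors
#'   `elj_centers`, `ebend_centers`, the probability matrix `p`
#'   (rows = `elj`), and a tibble `projection` with `e` and `p`.
#' @export
energy_histogram_2d <- function(series, kappa, beta = NULL, n_bins = 40) {
  stopifnot(all(c("elj", "ebend") %in% names(series)), nrow(series) > 0)
  w <- if (is.null(beta)) {
    rep(1, nrow(series))
  } else {
    lw <- -beta * series$ep - series$lnw
    exp(lw - max(lw))
  }
  rx <- range(series$elj); ry <- range(series$ebend)
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
  rx <- pad(rx); ry <- pad(ry)
  bx <- seq(rx[1], rx[2], length.out = n_bins + 1)
  by <- seq(ry[1], ry[2], length.out = n_bins + 1)
  ix <- pmin(findInterval(series$elj, bx, rightmost.closed = TRUE), n_bins)
  iy <- pmin(findInterval(series$ebend, by, rightmost.closed = TRUE), n_bins)
  p <- matrix(0, n_bins, n_bins)
  for (k in seq_along(ix)) p[ix[k], iy[k]] <- p[ix[k], iy[k]] + w[k]
  p <- p / sum(p)
  e <- series$elj + kappa * series$ebend
  re <- pad(range(e))
  be <- seq(re[1], re[2], length.out = n_bins + 1)
  ie <- pmin(findInterval(e, be, rightmost.closed = TRUE), n_bins)
  pe <- vapply(seq_len(n_bins), function(b) sum(w[ie == b]), numeric(1))
  pe <- pe / sum(pe)
  structure(
    list(elj_centers = (bx[-1] + bx[-length(bx)]) / 2,
         ebend_centers = (by[-1] + by[-length(by)]) / 2,
         p = p, kappa = kappa,
         projection = tibble::tibble(e = (be[-1] + be[-length(be)]) / 2,
                                     p = pe)),
    class = "energy_hist2d")
}

#' @export
print.energy_hist2d <- function(x, ...) {
  cat("<energy_hist2d>", length(x$elj_centers), "x", length(x$ebend_centers),
      "bins, kappa =", x$kappa, "\n")
  invisible(x)
}

#' @rdname energy_histogram_2d
#' @param x An `energy_hist2d` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.energy_hist2d <- function(x, ...) {
  grid <- expand.grid(elj = x$elj_centers, ebend = x$ebend_centers)
  tibble::tibble(elj = grid$elj, ebend = grid$ebend, p = as.vector(x$p))
}
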