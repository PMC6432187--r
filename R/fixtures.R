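#' Deterministic conformation and curve fixtures
#'
#' Generates the reference conformations used throughout the test suite
#' and as starting points for simulations: straight rods, hairpins,
#' random coils, aligned and random multi-chain bundles, parametric
#' `(p, q)` torus-knot polygons and the exactly solvable two-level toy
#' series for reweighting checks. All fixtures are deterministic given
#' `seed`.
#'
#' @param kind One of `"rod"`, `"hairpin"`, `"coil"`, `"aligned-bundle"`,
#'   `"random-bundle"`, `"torus-knot"`, `"two-state-toy"`.
#' @param N Beads per chain.
#' @param M Number of chains (bundle kinds).
#' @param spacing Bond length (default 1, the bead-stick convention; use
#'   `bond_length(spec)` for bead-spring chains).
#' @param sep Lateral chain separation for aligned bundles (default
#'   `2^(1/6) * spacing`, the LJ minimum).
#' @param box Cubic box edge for bundle kinds (required for
#'   `"random-bundle"`).
#' @param p,q Torus-knot winding numbers (coprime).
#' @param n_vertices Vertices of the torus-knot polygon.
#' @param n Length of the two-state toy series.
#' @param seed Integer seed for the random kinds.
#' @return A [conformation()], a `closed_curve` (torus knot), or a tibble
#'   (two-state toy: columns `ep`, `lnw` with flat simulation weights).
#' @examples
#' make_fixture("rod", N = 28)
#' make_fixture("torus-knot", p = 2, q = 3)
#' @export
make_fixture <- function(kind, N = 28, M = 4, spacing = 1, sep = NULL,
                         box = NULL, p = 2, q = 3, n_vertices = 120,
                         n = 100, seed = 1) {
  kind <- match.arg(kind, c("rod", "hairpin", "coil", "aligned-bundle",
                            "random-bundle", "torus-knot", "two-state-toy"))
  if (is.null(sep)) sep <- 2^(1 / 6) * spacing
  switch(kind,
    "rod" = conformation(rod_positions(N, spacing), 1, box),
    "hairpin" = conformation(hairpin_positions(N, spacing), 1, box),
    "coil" = conformation(coil_positions(N, spacing, seed), 1, box),
    "aligned-bundle" = {
      side <- ceiling(sqrt(M))
      pos <- do.call(rbind, lapply(seq_len(M) - 1, function(c0) {
        off <- c((c0 %% side) * sep, (c0 %/% side) * sep, 0)
        sweep(rod_positions(N, spacing), 2, -off)
      }))
      conformation(pos, M, box)
    },
    "random-bundle" = {
      stopifnot(!is.null(box), N * spacing < box / 2)
      set.seed(seed)
      pos <- do.call(rbind, lapply(seq_len(M), function(c0) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        cm <- runif(3, 0, box)
        rodc <- rod_positions(N, spacing)
        rodc <- sweep(rodc, 2, colMeans(rodc))
        # rotate the z-aligned rod onto u
        sweep(rodc %*% t(rotation_to(c(0, 0, 1), u)), 2, -cm)
      }))
      conformation(pos, M, box)
    },
    "torus-knot" = torus_knot_curve(p, q, n_vertices),
    "two-state-toy" = {
      m <- ceiling(n / 2)
      tibble::tibble(ep = rep(c(0, 1), m)[seq_len(2 * m)],
                     lnw = 0)
    })
}

rod_positions <- function(N, spacing) {
  cbind(0, 0, (seq_len(N) - 1) * spacing)
}

hairpin_positions <- function(N, spacing) {
  stopifnot(N >= 4)
  k <- ceiling((N - 1) / 2)  # beads in the ascending leg
  up <- cbind(0, 0, (seq_len(k) - 1) * spacing)
  turn <- c(spacing, 0, (k - 1) * spacing)
  ndown <- N - k - 1
  down <- cbind(spacing, 0, ((k - 2) - seq_len(ndown) + 1) * spacing)
  rbind(up, turn, down)
}

coil_positions <- function(N, spacing, seed, min_dist = 0.85) {
  set.seed(seed)
  pos <- matrix(0, N, 3)
  for (i in 2:N) {
    for (try in 1:200) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      cand <- pos[i - 1, ] + spacing * u
      d2 <- rowSums(sweep(pos[seq_len(i - 2), , drop = FALSE], 2, cand)^2)
      if (i == 2 || all(d2 > (min_dist * spacing)^2)) break
    }
    pos[i, ] <- cand
  }
  pos
}

rotation_to <- function(a, b) {
  # rotation matrix mapping unit vector a onto unit vector b
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c0 <- sum(a * b)
  if (c0 < -1 + 1e-12) return(diag(c(1, -1, -1)))  # antipodal about x
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c0)
}

torus_knot_curve <- function(p, q, n_vertices = 120, R = 2, r = 1) {
  stopifnot(p >= 1, q >= 1, n_vertices >= 3 * (p + q))
  s <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  x <- (R + r * cos(q * s)) * cos(p * s)
  y <- (R + r * cos(q * s)) * sin(p * s)
  z <- r * sin(q * s)
  structure(cbind(x, y, z), class = "closed_curve",
            provenance = list(kind = "torus-knot", p = p, q = q))
}
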