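# shared helpers for the suite

langevin <- function(x) 1 / tanh(x) - 1 / x

# batch-means standard error of a (possibly autocorrelated) series
batch_se <- function(x, batches = 20) {
  b <- rep(seq_len(batches), each = ceiling(length(x) / batches))[seq_along(x)]
  m <- tapply(x, b, mean)
  stats::sd(m) / sqrt(batches)
}

# rotate a point set by a random rigid motion (deterministic under seed)
random_rigid_motion <- function(pos, seed) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  Rm <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  pos %*% t(Rm) + matrix(stats::rnorm(3, sd = 2), nrow(pos), 3, byrow = TRUE)
}

# synthetic microcanonical caloric curves: a monotone decreasing beta
# ("none"), one with a steep monotone drop (second-order inflection) and
# one with an S-shaped back-bend (first order); entropy by integration
synthetic_beta <- function(ep, kind = c("none", "first", "second")) {
  kind <- match.arg(kind)
  base <- 2.5 - 0.03 * ep
  switch(kind,
         none = base,
         first = base + 0.5 * tanh((ep - 25) / 3),
         second = base - 0.5 * tanh((ep - 25) / 3))
}

synthetic_entropy <- function(ep, kind) {
  de <- ep[2] - ep[1]
  cumsum(synthetic_beta(ep, kind)) * de
}

# analytic density-of-states object on a grid (for microcanonical tests)
analytic_dos <- function(ep, ln_omega, de = ep[2] - ep[1]) {
  structure(list(bins = tibble::tibble(ep = ep,
                                       ln_omega = ln_omega - max(ln_omega),
                                       count = 1),
                 de = de, provenance = list()),
            class = "density_of_states")
}
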