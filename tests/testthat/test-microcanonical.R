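test_that("density of states comes out of weights and histogram bin-wise", {
  w <- weight_table(0, 1, lnw = c(0, -1, -2, -3))
  h <- c(10, 10, 10, 0)
  dos <- dos_from_weights(w, h)
  # lnOmega = ln H - ln W, shifted so the maximum covered bin is 0
  expect_equal(dos$bins$ln_omega, c(-2, -1, 0, NA))
  expect_true(is.na(dos$bins$ln_omega[4]))
  # flat histogram + flat weights -> constant
  d2 <- dos_from_weights(weight_table(0, 1, rep(0, 4)), rep(7, 4))
  expect_equal(d2$bins$ln_omega, rep(0, 4))
  # adding c to lnW shifts lnOmega by -c only (invisible after shift)
  w3 <- weight_table(0, 1, w$lnw + 5)
  expect_equal(dos_from_weights(w3, h)$bins$ln_omega, dos$bins$ln_omega)
})

test_that("sampling with W = 1/Omega recovers a power-law density of states", {
  # Omega ~ Ep^2 on [1, 100]: weights W = Ep^-2 make the sampled Ep
  # uniform; lnOmega from the production histogram must have slope 2 on
  # log-log axes
  set.seed(21)
  centers <- 1 + (seq_len(99) - 0.5)
  w <- weight_table(1, 1, lnw = -2 * log(centers))
  ep <- runif(2e5, 1, 100)
  h <- tabulate(floor(ep - 1) + 1, 99)
  dos <- dos_from_weights(w, h)
  fit <- lm(ln_omega ~ log(ep), data = dos$bins)
  expect_lt(abs(coef(fit)[2] - 2), 0.02)
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("beta and gamma reproduce analytic derivatives of lnOmega", {
  ep <- seq(10, 60, 0.25)
  a <- 5
  dos <- analytic_dos(ep, a * log(ep))
  prof <- micro_beta_gamma(dos, smooth_sigma = 0)
  mid_b <- prof$beta$ep > 20 & prof$beta$ep < 50
  rel_b <- abs(prof$beta$beta[mid_b] - a / prof$beta$ep[mid_b]) /
    (a / prof$beta$ep[mid_b])
  expect_lt(max(rel_b), 0.01)
  mid_g <- prof$gamma$ep > 20 & prof$gamma$ep < 50
  rel_g <- abs(prof$gamma$gamma[mid_g] + a / prof$gamma$ep[mid_g]^2) /
    (a / prof$gamma$ep[mid_g]^2)
  expect_lt(max(rel_g), 0.01)
  # linear lnOmega: constant beta, zero gamma
  dlin <- analytic_dos(ep, 0.7 * ep)
  plin <- micro_beta_gamma(dlin, smooth_sigma = 0)
  expect_equal(plin$beta$beta, rep(0.7, nrow(plin$beta)), tolerance = 1e-9)
  expect_equal(max(abs(plin$gamma$gamma)), 0, tolerance = 1e-9)
})

test_that("finite-difference error shrinks under grid refinement", {
  err_at <- function(de) {
    ep <- seq(10, 60, de)
    prof <- micro_beta_gamma(analytic_dos(ep, 5 * log(ep)),
                             smooth_sigma = 0)
    mid <- prof$beta$ep > 20 & prof$beta$ep < 50
    max(abs(prof$beta$beta[mid] - 5 / prof$beta$ep[mid]))
  }
  e1 <- err_at(1)
  e2 <- err_at(0.5)
  expect_lt(e2, e1)
})

test_that("convex intruder classifies first order, steep inflection second", {
  ep <- seq(1, 50, 0.25)
  # entropy with a convex intruder (S-shaped beta, back-bending)
  c1 <- classify_transition(micro_beta_gamma(
    analytic_dos(ep, synthetic_entropy(ep, "first")), smooth_sigma = 1))
  expect_equal(c1$order, "first")
  expect_lt(abs(c1$ep_prime - 25), 2)
  expect_gt(c1$gamma_peak, 0)
  # monotone beta with a steep drop: negative gamma peak
  c2 <- classify_transition(micro_beta_gamma(
    analytic_dos(ep, synthetic_entropy(ep, "second")), smooth_sigma = 1))
  expect_equal(c2$order, "second")
  expect_lt(abs(c2$ep_prime - 25), 2)
  expect_lt(c2$gamma_peak, 0)
  # featureless entropies: no transition (linear beta and a pure
  # ground-state wall, whose gamma is monotone)
  c0 <- classify_transition(micro_beta_gamma(
    analytic_dos(ep, synthetic_entropy(ep, "none")), smooth_sigma = 1))
  expect_equal(c0$order, "none")
  cw <- classify_transition(micro_beta_gamma(
    analytic_dos(ep, 30 * log(ep)), smooth_sigma = 1))
  expect_equal(cw$order, "none")
})

test_that("first-order entropies imply back-bending and bimodal p(Ep)", {
  ep <- seq(1, 50, 0.25)
  S <- synthetic_entropy(ep, "first")
  prof <- micro_beta_gamma(analytic_dos(ep, S), smooth_sigma = 1)
  cls <- classify_transition(prof)
  # back-bending: beta non-monotone around Ep'
  near <- abs(prof$beta$ep - cls$ep_prime) < 6
  expect_true(any(diff(prof$beta$beta[near]) > 0))
  # canonical p(Ep) at beta(Ep') is double-peaked
  b_star <- stats::approx(prof$beta$ep, prof$beta$beta,
                          xout = cls$ep_prime)$y
  lp <- S - b_star * ep
  pk <- scan_peaks(ep, exp(lp - max(lp)), prominence = 0.05)
  expect_gte(nrow(pk), 2)
})

test_that("rescaled beta passes through the origin and is invertible", {
  ep <- seq(1, 50, 0.5)
  prof <- micro_beta_gamma(analytic_dos(ep, 20 * log(ep)), smooth_sigma = 0)
  rb <- rescaled_beta(prof, ep_prime = 25)
  at0 <- stats::approx(rb$dep, rb$dbeta, xout = 0)$y
  expect_equal(at0, 0, tolerance = 1e-9)
  # monotone input stays monotone
  expect_true(all(diff(rb$dbeta) < 0))
  # invertible: recentering back recovers beta
  back <- rb$dbeta + stats::approx(prof$beta$ep, prof$beta$beta, 25)$y
  expect_equal(back, prof$beta$beta, tolerance = 1e-12)
})

test_that("reweighted canonical mean matches direct integration of Omega", {
  # consistency loop on an analytic two-piece density of states
  ep <- seq(0, 30, 0.2)
  lnom <- 8 * log(ep + 1) - 0.02 * ep^2
  beta <- 0.9
  num <- sum(ep * exp(lnom - beta * ep))
  den <- sum(exp(lnom - beta * ep))
  direct <- num / den
  # emulate a perfect flat-histogram series on the same grid
  series <- tibble::tibble(ep = ep, lnw = -lnom)
  r <- reweight(series, beta = beta)
  expect_lt(abs(r$value - direct) / abs(direct), 0.01)
})
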