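test_that("radius of gyration and end-to-end match rod closed forms", {
  rod <- make_fixture("rod", N = 28)
  expect_equal(radius_of_gyration_sq(rod), (28^2 - 1) / 12)
  ee <- end_to_end(chain_positions(rod))
  expect_equal(ee$ree, 27)
  expect_equal(abs(sum(ee$unit * c(0, 0, 1))), 1)
  # coincident beads
  expect_equal(radius_of_gyration_sq(matrix(1, 5, 3)), 0)
  # rotation invariance
  coil <- chain_positions(make_fixture("coil", N = 15, seed = 3))
  expect_equal(radius_of_gyration_sq(random_rigid_motion(coil, 4)),
               radius_of_gyration_sq(coil), tolerance = 1e-10)
  # closed loop: undefined direction
  loop <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 0, 0))
  eel <- end_to_end(loop)
  expect_equal(eel$ree, 0)
  expect_true(all(is.na(eel$unit)))
  # reflection flips the unit vector, preserves the distance
  refl <- coil %*% diag(c(-1, 1, 1))
  expect_equal(end_to_end(refl)$ree, end_to_end(coil)$ree)
  expect_equal(end_to_end(refl)$unit * c(-1, 1, 1), end_to_end(coil)$unit)
})

test_that("end-to-end correlation hits its aligned and orthogonal limits", {
  aligned <- matrix(rep(c(0, 0, 1), 4), ncol = 3, byrow = TRUE)
  expect_equal(end_to_end_correlation(aligned)$cr, 1)
  # head/tail symmetric: flipping chains changes nothing
  aligned[2, ] <- -aligned[2, ]
  expect_equal(end_to_end_correlation(aligned)$cr, 1)
  ortho <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(end_to_end_correlation(ortho)$cr, 0)
  # undefined rows are excluded with adjusted denominator
  withna <- rbind(c(1, 0, 0), c(NA, NA, NA), c(1, 0, 0))
  r <- end_to_end_correlation(withna)
  expect_true(r$flagged)
  expect_equal(r$pairs, 1)
  expect_equal(r$cr, 1)
})

test_that("uncorrelated unit vectors average to CR = 1/3", {
  set.seed(11)
  n_sets <- 1e5
  u <- matrix(rnorm(3 * 4 * n_sets), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  # mean over sets of M = 4: CR per set is the mean of 6 squared dots
  idx <- matrix(seq_len(4 * n_sets), ncol = 4, byrow = TRUE)
  cr <- vapply(seq_len(n_sets), function(s) {
    g <- u[idx[s, ], ] %*% t(u[idx[s, ], ])
    mean(g[upper.tri(g)]^2)
  }, numeric(1))
  se <- sd(cr) / sqrt(n_sets)
  expect_lt(abs(mean(cr) - 1 / 3), 3 * se)
})

test_that("phase separation parameter obeys its closed forms and bounds", {
  expect_equal(phase_separation(matrix(1, 4, 3), 10), 0)
  d <- 3.2
  expect_equal(phase_separation(rbind(c(0, 0, 0), c(d, 0, 0)), 20), d^2 / 4)
  # invariance under global translation mod L
  set.seed(12)
  rcm <- matrix(runif(12, 0, 8), 4, 3)
  g0 <- phase_separation(rcm, 8)
  expect_equal(phase_separation(rcm + 8 * 3, 8), g0, tolerance = 1e-9)
  expect_equal(phase_separation(sweep(rcm, 2, c(1.3, -2.1, 0.4), "+"), 8),
               phase_separation(sweep(rcm, 2, c(1.3, -2.1, 0.4) + 8, "+"), 8),
               tolerance = 1e-9)
  # bounded by the maximal minimal-image pair distance
  for (s in 1:50) {
    rcm <- matrix(runif(12, -20, 20), 4, 3)
    expect_lte(phase_separation(rcm, 8), (3 / 4) * (8 / 2)^2 * (4 - 1) / 4)
  }
})

test_that("2D energy histograms separate what the 1D projection hides", {
  delta <- tibble::tibble(elj = rep(1, 10), ebend = rep(2, 10),
                          ep = 1, lnw = 0)
  h <- energy_histogram_2d(delta, kappa = 1, n_bins = 10)
  expect_equal(sum(h$p > 0), 1)
  expect_equal(sum(h$p), 1)
  expect_equal(sum(h$projection$p), 1)
  # two Gaussians on an anti-diagonal: bimodal in 2D, unimodal projected
  # onto E = ELJ + kappa EBend (the mechanism that hides latent heat)
  set.seed(13)
  n <- 4000
  kap <- 2
  elj1 <- rnorm(n, -10, 0.4); eb1 <- (0 - elj1) / kap   # E ~ 0
  elj2 <- rnorm(n, -4, 0.4);  eb2 <- (0 - elj2) / kap   # E ~ 0
  ser <- tibble::tibble(elj = c(elj1, elj2), ebend = c(eb1, eb2),
                        ep = 0, lnw = 0)
  h2 <- energy_histogram_2d(ser, kappa = kap, n_bins = 30)
  # marginal over elj bimodal
  marg <- rowSums(h2$p)
  pk <- scan_peaks(h2$elj_centers, marg, prominence = 0.02)
  expect_gte(nrow(pk), 2)
  # projection unimodal
  pkp <- scan_peaks(h2$projection$e, h2$projection$p, prominence = 0.02)
  expect_equal(nrow(pkp), 1)
})

test_that("measure_observables agrees with the sampler's in-loop measurements", {
  spec <- model_spec("bead_spring", kappa = 1)
  conf <- make_fixture("random-bundle", N = 6, M = 3, spacing = 0.7,
                       box = 25, seed = 14)
  run <- run_canonical(conf, spec, 2, sweeps = 1, discard = 0, seed = 1,
                       tune = FALSE,
                       moves = tibble::tibble(kind = "pivot", code = 2L,
                                              prob = 1, amplitude = 1e-12))
  m <- measure_observables(run$conf)
  last <- run$series[nrow(run$series), ]
  expect_equal(last$rgyr2, m$rgyr2, tolerance = 1e-9)
  expect_equal(last$ree, m$ree, tolerance = 1e-9)
  expect_equal(last$cr, m$cr, tolerance = 1e-9)
  expect_equal(last$gamma2, m$gamma2, tolerance = 1e-9)
})
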