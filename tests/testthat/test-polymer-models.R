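test_that("shifted LJ pair energy matches direct evaluation and is continuous", {
  spec <- model_spec("bead_stick")
  # depth at the minimum, shifted: -1 - V(2.5), V(2.5) = 4(2.5^-12 - 2.5^-6)
  v_rc <- 4 * (2.5^-12 - 2.5^-6)
  expect_equal(lj_pair_energy(2^(1 / 6), spec), -1 - v_rc, tolerance = 1e-12)
  expect_identical(lj_pair_energy(2.5, spec), 0)
  expect_identical(lj_pair_energy(3.7, spec), 0)
  # continuity at the cutoff
  expect_lt(abs(lj_pair_energy(2.5 - 1e-9, spec)), 1e-7)
  expect_error(lj_pair_energy(0, spec), "positive")
})

test_that("bending energy is kappa (1 - cos theta), monotone on [0, pi]", {
  expect_identical(bend_energy(0, 5), 0)
  expect_equal(bend_energy(pi / 2, 5), 5)
  expect_equal(bend_energy(pi, 5), 10)
  th <- seq(0, pi, length.out = 50)
  expect_true(all(diff(bend_energy(th, 2.3)) > 0))
})

test_that("FENE bond energy has its minimum at r0 and diverges at the bounds", {
  spec <- model_spec("bead_spring")
  expect_equal(fene_bond_energy(0.7, spec), 0)
  # -(K/2) R^2 ln(1 - ((r-r0)/R)^2) at r = 0.85: -20 * 0.09 * ln(0.75)
  expect_equal(fene_bond_energy(0.85, spec), -20 * 0.09 * log(0.75),
               tolerance = 1e-12)
  expect_identical(fene_bond_energy(1.0, spec), Inf)
  expect_identical(fene_bond_energy(0.39, spec), Inf)
})

test_that("total energy of small reference conformations is the pair sum", {
  spec <- model_spec("bead_stick", kappa = 1)
  rod3 <- make_fixture("rod", N = 3)
  e <- total_energy(rod3, spec)
  expect_equal(e$ebend, 0)
  expect_equal(e$ep, lj_pair_energy(2, spec), tolerance = 1e-12)
  # two isolated single-bead chains beyond the cutoff
  far <- conformation(rbind(c(0, 0, 0), c(5, 0, 0)), n_chains = 2)
  expect_identical(total_energy(far, spec)$ep, 0)
  # overlapping beads flagged, not crashed
  ouch <- conformation(rbind(c(0, 0, 0), c(0, 0, 1), c(1e-12, 0, 0)),
                       n_chains = 1)
  expect_false(total_energy(ouch, spec)$finite)
})

test_that("total energy agrees with an R-level recomputation on a random coil", {
  spec <- model_spec("bead_spring", kappa = 3.2)
  conf <- make_fixture("coil", N = 12, spacing = spec$r0, seed = 4)
  e <- total_energy(conf, spec)
  p <- conf$positions
  d <- as.matrix(dist(p))
  elj <- 0
  for (i in 1:11) for (j in (i + 1):12) {
    if (j - i == 1) next
    elj <- elj + lj_pair_energy(d[i, j], spec)
  }
  bonds <- sqrt(rowSums(diff(p)^2))
  ef <- sum(fene_bond_energy(bonds, spec))
  b1 <- diff(p)
  ct <- rowSums(b1[-11, ] * b1[-1, ]) /
    (bonds[-11] * bonds[-1])
  eb <- sum(1 - ct)
  expect_equal(e$elj, elj, tolerance = 1e-10)
  expect_equal(e$efene, ef, tolerance = 1e-10)
  expect_equal(e$ebend, eb, tolerance = 1e-10)
  expect_equal(e$ep, elj + 3.2 * eb + ef, tolerance = 1e-10)
})

test_that("energy is extensive and invariant under rigid motions", {
  spec <- model_spec("bead_stick", kappa = 2)
  coil <- make_fixture("coil", N = 10, seed = 7)
  e1 <- total_energy(coil, spec)$ep
  # duplicate the chain far outside the cutoff: exactly double
  shifted <- coil$positions + matrix(c(100, 0, 0), 10, 3, byrow = TRUE)
  both <- conformation(rbind(coil$positions, shifted), n_chains = 2)
  expect_equal(total_energy(both, spec)$ep, 2 * e1, tolerance = 1e-10)
  # rigid motion
  moved <- conformation(random_rigid_motion(coil$positions, seed = 2))
  expect_equal(total_energy(moved, spec)$ep, e1, tolerance = 1e-10)
})

test_that("minimal image maps components into [-L/2, L/2)", {
  expect_equal(minimal_image(c(0.9, 0, 0), 1), c(-0.1, 0, 0))
  expect_identical(minimal_image(c(0, 0, 0), 1), c(0, 0, 0))
  # half-open convention at +L/2
  expect_equal(minimal_image(c(0.5, -0.5, 0), 1), c(-0.5, -0.5, 0))
  x <- runif(100, -10, 10)
  y <- minimal_image(x, 2.5)
  expect_true(all(y >= -1.25 & y < 1.25))
  expect_equal(sin(2 * pi * y / 2.5), sin(2 * pi * x / 2.5), tolerance = 1e-9)
})

test_that("box edge follows L = (NM/rho)^(1/3)", {
  expect_equal(box_from_density(13, 4, 1e-3), 52000^(1 / 3))
  expect_identical(box_from_density(1, 1, 1), 1)
  rhos <- c(1e-4, 1e-3, 1e-2, 1e-1)
  expect_true(all(diff(box_from_density(10, 2, rhos)) < 0))
})

test_that("conformation validation enforces the bond invariants", {
  stick <- model_spec("bead_stick")
  expect_true(validate_conformation(make_fixture("rod", N = 5), stick))
  bad <- conformation(rbind(c(0, 0, 0), c(0, 0, 1.5)))
  expect_error(validate_conformation(bad, stick), "bond length")
  spring <- model_spec("bead_spring")
  expect_true(validate_conformation(
    make_fixture("rod", N = 5, spacing = 0.7), spring))
  expect_error(validate_conformation(
    make_fixture("rod", N = 5, spacing = 1.1), spring), "FENE")
})

test_that("incremental energies track the fresh total through long runs", {
  for (kind in c("bead_stick", "bead_spring")) {
    spec <- model_spec(kind, kappa = 2)
    conf <- make_fixture("coil", N = 10, spacing = bond_length(spec),
                         seed = 1)
    run <- run_canonical(conf, spec, temperature = 1.5, sweeps = 1000,
                         discard = 100, seed = 3)
    # ~1e4 elementary moves with no mid-run resync inside the engine below
    # the final fresh-energy comparison
    expect_lt(run$max_drift, 1e-8)
    validate_conformation(run$conf, spec, tol = 1e-7)
  }
})
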