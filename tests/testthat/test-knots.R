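test_that("Alexander fingerprints match the polynomial oracle", {
  # independent oracle: evaluate the known symmetric Alexander polynomials
  poly_dp <- function(cf, t = -1.1) {
    m <- (length(cf) - 1) / 2
    f <- function(x) sum(cf * x^(m:(-m)))
    abs(f(t) * f(1 / t))
  }
  trefoil <- poly_dp(c(1, -1, 1))
  fig8 <- poly_dp(c(1, -3, 1))
  cinq <- poly_dp(c(1, -1, 1, -1, 1))
  expect_equal(trefoil, 9.0546, tolerance = 1e-5)
  expect_equal(fig8, 25.091, tolerance = 1e-5)
  expect_equal(cinq, 25.457, tolerance = 1e-4)
  tab <- knot_table()
  expect_equal(tab$delta_p[tab$label == "3_1"], trefoil)
  expect_equal(tab$delta_p[tab$label == "4_1"], fig8)
  expect_equal(tab$delta_p[tab$label == "5_1"], cinq)
  expect_equal(tab$delta_p[tab$label == "0_1"], 1)
  # computed fingerprints of polygonal torus knots agree with the oracle
  for (cfg in list(list(p = 2, q = 3, dp = trefoil),
                   list(p = 2, q = 5, dp = cinq))) {
    tk <- make_fixture("torus-knot", p = cfg$p, q = cfg$q, n_vertices = 90)
    r <- identify_knot(tk, seed = 31)
    expect_equal(r$delta_p, cfg$dp, tolerance = 1e-3)
  }
})

test_that("closure adds three vertices and leaves straight chains unknotted", {
  rod <- make_fixture("rod", N = 20)
  cc <- close_chain(rod)
  expect_s3_class(cc, "closed_curve")
  expect_equal(nrow(cc), 23)
  r <- identify_knot(rod, seed = 2)
  expect_equal(r$label, "0_1")
  expect_equal(r$delta_p, 1, tolerance = 1e-9)
  # already closed input returned unchanged
  tk <- make_fixture("torus-knot", p = 2, q = 3)
  expect_identical(close_chain(tk), tk)
  # coils and hairpins close to unknots too
  expect_equal(identify_knot(make_fixture("hairpin", N = 20), seed = 3)$label,
               "0_1")
})

test_that("planar convex polygons project with zero crossings", {
  th <- 2 * pi * (0:11) / 12
  poly <- cbind(cos(th), sin(th), 0)
  class(poly) <- "closed_curve"
  cr <- project_and_list_crossings(poly, c(0, 0, 1))
  expect_equal(cr$n, 0)
  # trefoil polygons have at least three crossings in any generic view
  tk <- make_fixture("torus-knot", p = 2, q = 3, n_vertices = 60)
  set.seed(41)
  for (k in 1:5) {
    d <- rnorm(3)
    cr <- tryCatch(project_and_list_crossings(tk, d),
                   degenerate_projection = function(e) NULL)
    if (is.null(cr)) next
    expect_gte(cr$n, 3)
  }
})

test_that("knot classes survive projections, rigid motions and resolution", {
  cases <- list(list(p = 2, q = 3, lab = "3_1"),
                list(p = 2, q = 5, lab = "5_1"),
                list(p = 3, q = 4, lab = "8_19"))
  for (cs in cases) {
    for (nv in c(40, 100, 400)) {
      tk <- make_fixture("torus-knot", p = cs$p, q = cs$q, n_vertices = nv)
      labs <- vapply(1:10, function(s) {
        identify_knot(unclass(tk), seed = s)$label
      }, character(1))
      expect_true(all(labs == cs$lab),
                  label = sprintf("(%d,%d) torus knot at %d vertices",
                                  cs$p, cs$q, nv))
    }
    tkm <- make_fixture("torus-knot", p = cs$p, q = cs$q, n_vertices = 120)
    moved <- random_rigid_motion(unclass(tkm), seed = cs$p * 10 + cs$q)
    class(moved) <- "closed_curve"
    expect_equal(identify_knot(moved, seed = 5)$label, cs$lab)
  }
})

test_that("fingerprints between table entries stay unclassified", {
  tab <- knot_table()
  s <- sort(tab$delta_p)
  midway <- (s[2] + s[3]) / 2
  expect_equal(classify_knot(midway), "unclassified")
  expect_equal(classify_knot(1), "0_1")
  expect_equal(classify_knot(s[5] * (1 + 5e-4)),
               tab$label[match(s[5], tab$delta_p)])
})

test_that("knot fractions count trajectory classes, with optional weights", {
  rods <- replicate(3, make_fixture("rod", N = 15), simplify = FALSE)
  kf <- knot_fraction(rods, seed = 6)
  expect_equal(kf$fractions$label, "0_1")
  expect_equal(kf$fractions$fraction, 1)
  mixed <- c(replicate(3, make_fixture("torus-knot", p = 2, q = 5),
                       simplify = FALSE),
             replicate(7, make_fixture("rod", N = 15), simplify = FALSE))
  km <- knot_fraction(mixed, seed = 7)
  expect_equal(km$fractions$fraction[km$fractions$label == "5_1"], 0.3)
  expect_equal(km$fractions$fraction[km$fractions$label == "0_1"], 0.7)
  # weights reweight the fractions
  kw <- knot_fraction(mixed, weights = c(rep(2, 3), rep(1, 7)), seed = 8)
  expect_equal(kw$fractions$fraction[kw$fractions$label == "5_1"], 6 / 13)
})
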