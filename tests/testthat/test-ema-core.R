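test_that("spheroid shape mapping matches its closed form and is monotone", {
  expect_equal(depolarisation_from_aspect(1), 1 / 3)
  expect_equal(round(depolarisation_from_aspect(5), 3), 0.053)
  expect_equal(round(depolarisation_from_aspect(1 / 5), 2), 0.75)
  a <- exp(seq(log(0.01), log(100), length.out = 50))
  L <- depolarisation_from_aspect(a)
  expect_true(all(diff(L) < 0))
  expect_true(all(L > 0 & L < 1))
  expect_error(depolarisation_from_aspect(0), "positive")
  expect_error(depolarisation_from_aspect(-2), "positive")
})

test_that("aspect inversion round-trips and hits the documented values", {
  expect_equal(aspect_from_depolarisation(1 / 3), 1)
  expect_equal(aspect_from_depolarisation(0.04), 6)
  expect_equal(round(aspect_from_depolarisation(0.96), 3), 0.026)
  L <- seq(0.01, 0.99, by = 0.01)
  expect_equal(depolarisation_from_aspect(aspect_from_depolarisation(L)), L,
               tolerance = 1e-12)
  expect_error(aspect_from_depolarisation(0), "strictly inside")
  expect_error(aspect_from_depolarisation(1), "strictly inside")
})

test_that("absorption/extinction conversion uses c/(4 pi nu) with unit scaling", {
  expect_identical(kappa_from_alpha(0, 1), 0)
  # 50 cm^-1 at 1 THz: 299792458 * 5000 / (4 pi 1e12)
  expect_equal(kappa_from_alpha(50, 1), 0.119283, tolerance = 1e-5)
  expect_equal(kappa_from_alpha(50, 0.2), 5 * kappa_from_alpha(50, 1))
  expect_equal(alpha_from_kappa(kappa_from_alpha(37, 0.7), 0.7), 37,
               tolerance = 1e-12)
  expect_error(kappa_from_alpha(-1, 1), "non-negative")
  expect_error(kappa_from_alpha(1, 0), "positive")
})

test_that("forward model equals the Wiener closed forms at the L endpoints", {
  for (f in c(0.05, 0.2, 0.45, 0.8)) {
    for (n_s in c(1.4, 1.86, 2.5)) {
      expect_equal(neff_forward(f, n_s, 0), sqrt(f + (1 - f) * n_s^2),
                   tolerance = 1e-12)
      expect_equal(neff_forward(f, n_s, 1),
                   sqrt(1 / (f + (1 - f) / n_s^2)), tolerance = 1e-12)
    }
  }
  expect_equal(neff_forward(0, 1.86, 0.7), 1.86)
  expect_equal(neff_forward(1, 1.86, 0.7), 1)
})

test_that("forward model is continuous and strictly decreasing in L", {
  L <- seq(0, 1, by = 0.001)
  ne <- neff_forward(rep(0.3, length(L)), 1.86, L)
  expect_true(all(diff(ne) < 0))
  wb <- wiener_bounds(0.3, 1.86)
  expect_true(all(ne >= wb$lower - 1e-12 & ne <= wb$upper + 1e-12))
  # no jumps anywhere near the step size scale
  expect_lt(max(abs(diff(ne))), 1e-3)
})

test_that("forward model satisfies the AB-EMA residual equation", {
  set.seed(11)
  for (i in 1:50) {
    f <- runif(1, 0.01, 0.9); n_s <- runif(1, 1.2, 3); L <- runif(1)
    ne <- neff_forward(f, n_s, L)
    expect_lt(abs(abema_residual(f, ne, n_s, L)), 1e-10)
  }
})

test_that("all inverse operations round-trip with the forward model", {
  set.seed(42)
  for (i in 1:100) {
    f <- runif(1, 0.02, 0.85)
    n_s <- runif(1, 1.2, 3)
    L <- runif(1, 0.01, 0.99)
    ne <- neff_forward(f, n_s, L)
    expect_equal(as.numeric(ns_from_neff(f, ne, L)), n_s, tolerance = 1e-10)
    expect_equal(porosity_from_neff(ne, n_s, L), f, tolerance = 1e-10)
    expect_equal(depolarisation_from_sample(ne, n_s, f), L,
                 tolerance = 1e-10)
  }
})

test_that("single-sample inversions handle the trivial limits", {
  expect_equal(as.numeric(ns_from_neff(0, 1.5, 0.42)), 1.5)
  # data generated at the upper Wiener limit (L = 0) invert exactly
  ne <- sqrt(0.2 + 0.8 * 1.86^2)
  expect_equal(as.numeric(ns_from_neff(0.2, ne, 0)), 1.86, tolerance = 1e-12)
  expect_equal(porosity_from_neff(1.86, 1.86, 0.3), 0)
  expect_equal(porosity_from_neff(1, 1.86, 0.3), 1)
  expect_error(porosity_from_neff(2.5, 1.86, 0.3), "within")
})

test_that("non-physical solid indices are flagged, not returned silently", {
  # n_eff below what any n_s > 1 could produce at this porosity
  expect_warning(out <- ns_from_neff(0.1, 1.0, 0.5), "non-physical")
  expect_true(is.na(out[1]))
  expect_true(attr(out, "nonphysical")[1])
})

test_that("sample depolarisation snaps to the Wiener endpoints and errors outside", {
  wb <- wiener_bounds(0.25, 1.86)
  expect_identical(depolarisation_from_sample(wb$upper, 1.86, 0.25), 0)
  expect_identical(depolarisation_from_sample(wb$lower, 1.86, 0.25), 1)
  expect_error(depolarisation_from_sample(wb$upper + 0.01, 1.86, 0.25),
               "Wiener")
  expect_error(depolarisation_from_sample(wb$lower - 0.01, 1.86, 0.25),
               "Wiener")
})

test_that("closed-form depolarisation agrees with a brute-force residual scan", {
  set.seed(7)
  Lgrid <- seq(0, 1, by = 1e-5)
  for (i in 1:100) {
    f <- runif(1, 0.05, 0.8)
    n_s <- runif(1, 1.3, 2.8)
    L <- runif(1, 0.02, 0.98)
    ne <- neff_forward(f, n_s, L)
    res <- abs(abema_residual(f, ne, n_s, Lgrid))
    L_scan <- Lgrid[which.min(res)]
    expect_lt(abs(depolarisation_from_sample(ne, n_s, f) - L_scan), 1e-5)
  }
})

test_that("complex permittivity solver reduces to the real solver at kappa = 0", {
  set.seed(3)
  for (i in 1:50) {
    f <- runif(1, 0.02, 0.8); n_s <- runif(1, 1.2, 3); L <- runif(1)
    ne <- neff_forward(f, n_s, L)
    es <- eps_s_from_eps_eff(f, complex(real = ne^2, imaginary = 0), L)
    expect_equal(Im(es[1]), 0, tolerance = 1e-12)
    expect_equal(Re(es[1]), as.numeric(ns_from_neff(f, ne, L))^2,
                 tolerance = 1e-12)
  }
})

test_that("complex solver satisfies the complex AB-EMA residual", {
  set.seed(5)
  for (i in 1:50) {
    f <- runif(1, 0.02, 0.8); L <- runif(1)
    E <- complex(real = runif(1, 1.1, 9), imaginary = -runif(1, 0, 0.5))
    S <- eps_s_from_eps_eff(f, E, L)[1]
    res <- f * (1 - E) / (E + L * (1 - E)) +
      (1 - f) * (S - E) / (E + L * (S - E))
    expect_lt(Mod(res), 1e-10)
  }
  expect_equal(eps_s_from_eps_eff(0, 2.5 + 0.3i, 0.4)[1], 2.5 + 0.3i)
})
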