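test_that("flat-tablet porosity matches hand arithmetic and scaling laws", {
  # V = pi D^2 H / 4 = 0.23562 cm^3; M/(V rho) = 0.83382
  expect_equal(as.numeric(porosity_flat(0.300, 1.0, 0.30, 1.527)),
               1 - 0.3 / (pi * 0.3 / 4 * 1.527), tolerance = 1e-12)
  expect_equal(round(as.numeric(porosity_flat(0.300, 1.0, 0.30, 1.527)), 4),
               0.1662)
  # fully dense: zero porosity
  V <- pi * 1^2 * 0.3 / 4
  expect_equal(as.numeric(porosity_flat(V * 1.527, 1.0, 0.30, 1.527)), 0)
  # doubling thickness at fixed mass halves the solid fraction
  f1 <- as.numeric(porosity_flat(0.2, 1.0, 0.30, 1.527))
  f2 <- as.numeric(porosity_flat(0.2, 1.0, 0.60, 1.527))
  expect_equal(1 - f2, (1 - f1) / 2, tolerance = 1e-12)
  # unit invariance: mg/mm inputs give the same fraction as g/cm
  expect_equal(as.numeric(porosity_flat(300, 10, 3.0, 1.527)),
               as.numeric(porosity_flat(0.300, 1.0, 0.30, 1.527)),
               tolerance = 1e-12)
  expect_error(porosity_flat(-1, 1, 1, 1), "positive")
  expect_warning(porosity_flat(10, 1.0, 0.30, 1.527), "outside")
})

test_that("biconvex porosity matches an independent cap-volume oracle", {
  M <- 0.330; D <- 1.0; H <- 0.40; h <- 0.105; C <- 1.2; rho <- 1.527
  cap <- pi * h^2 * (3 * C - h) / 3            # one spherical cap
  V <- pi * D^2 * (H - 2 * h) / 4 + 2 * cap
  expect_equal(as.numeric(porosity_biconvex(M, D, H, h, C, rho)),
               1 - M / (V * rho), tolerance = 1e-12)
  # h = 0 reduces to the flat-faced formula
  expect_equal(as.numeric(porosity_biconvex(M, D, H, 0, C, rho)),
               as.numeric(porosity_flat(M, D, H, rho)))
  # and the reduction is continuous in h
  eps <- 1e-9
  expect_equal(as.numeric(porosity_biconvex(M, D, H, eps, C, rho)),
               as.numeric(porosity_flat(M, D, H, rho)), tolerance = 1e-6)
  expect_error(porosity_biconvex(M, D, 0.2, 0.105, C, rho), "twice")
  expect_error(porosity_biconvex(M, D, H, 0.105, 0.05, rho), "curvature")
})

test_that("band averaging is inclusive, order-invariant and validated", {
  sp <- data.frame(frequency_THz = seq(0.1, 1.2, by = 0.1),
                   n_eff = rep(1.7, 12))
  expect_equal(average_neff_band(sp), 1.7)
  sp$n_eff <- seq_along(sp$n_eff)  # linear: mean = band-centre value
  expect_equal(average_neff_band(sp), mean(4:8))   # 0.4..0.8 inclusive
  shuffled <- sp[sample(nrow(sp)), ]
  expect_equal(average_neff_band(shuffled), average_neff_band(sp))
  expect_error(average_neff_band(sp, 2.0, 3.0), "no spectral samples")
})

test_that("tablet tables round-trip and auto-compute porosity", {
  d <- data.frame(
    id = c("t1", "t2", "t3"),
    shape = c("flat", "flat", "biconvex"),
    mass_mg = c(300, 305, 330),
    diameter_mm = 10,
    thickness_mm = c(3.0, 3.1, 4.0),
    punch_depth_mm = c(NA, NA, 1.05),
    curvature_radius_mm = c(NA, NA, 12),
    true_density_g_cm3 = 1.527,
    n_eff = c(1.65, 1.66, 1.60))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_tablet_table(d, path)
  r <- read_tablet_table(path)
  expect_equal(nrow(r), 3)
  expect_equal(r$porosity[1],
               as.numeric(porosity_flat(300, 10, 3.0, 1.527)),
               tolerance = 1e-9)
  expect_equal(r$porosity[3],
               as.numeric(porosity_biconvex(330, 10, 4.0, 1.05, 12, 1.527)),
               tolerance = 1e-9)
  # write -> read preserves every numeric column
  write_tablet_table(r, path)
  r2 <- read_tablet_table(path)
  expect_equal(r2$porosity, r$porosity, tolerance = 1e-9)
  expect_equal(r2$n_eff, r$n_eff, tolerance = 1e-9)
  set <- tablet_set_from_table(r, material = "MCC")
  expect_s3_class(set, "tablet_set")
  expect_equal(nrow(set$samples), 3)
})

test_that("malformed tablet tables are rejected with line numbers", {
  d <- data.frame(
    id = c("a", "b"), shape = c("flat", "biconvex"),
    mass_mg = c(300, "heavy"), diameter_mm = 10, thickness_mm = 3,
    true_density_g_cm3 = 1.527, n_eff = 1.6)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  utils::write.csv(d, path, row.names = FALSE)
  expect_error(read_tablet_table(path), "line 3.*non-numeric mass_mg")
  # biconvex row without punch geometry
  d$mass_mg <- c(300, 400)
  utils::write.csv(d, path, row.names = FALSE)
  expect_error(read_tablet_table(path), "punch_depth")
  # missing mandatory column
  utils::write.csv(d[, -3], path, row.names = FALSE)
  expect_error(read_tablet_table(path), "misses column")
})

test_that("spectrum files are validated and band-averaged end to end", {
  sp <- data.frame(frequency_THz = seq(0.2, 1.0, by = 0.05),
                   n_eff = 1.7 + 0.01 * seq(0, 16))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  utils::write.csv(sp, path, row.names = FALSE)
  r <- read_spectrum(path)
  expect_equal(average_neff_band(r), mean(sp$n_eff[sp$frequency_THz >= 0.4 &
                                                     sp$frequency_THz <= 0.8]))
  bad <- sp[c(2, 1, 3:nrow(sp)), ]
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_spectrum(path), "increasing")
})
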