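# Deterministic synthetic-data generators and the three error-analysis
# studies: material absorption, porosity-dependent pore shape, and radial
# density distribution in biconvex tablets. The studies double as
# experiments and as fixtures for the test suite; they are noiseless by
# design, so repeated runs are bit-identical.

#' Generate a synthetic AB-EMA-consistent tablet set
#'
#' Computes the effective refractive index of every porosity through the
#' AB-EMA forward model with a constant or linearly porosity-dependent
#' depolarisation factor, recording the generating parameters in the set.
#'
#' @param n_s solid refractive index, > 1.
#' @param L_model scalar depolarisation factor or a [linear_l()] model;
#'   must evaluate inside \[0, 1\] at every porosity.
#' @param porosities porosity fractions, each in \[0, 1).
#' @param material set label.
#' @return a [tablet_set()] with `true_ns`/`true_L` populated.
#' @examples
#' gen_set(1.86, linear_l(0.5, 0.275), seq(0.05, 0.5, by = 0.05))
#' @export
gen_set <- function(n_s, L_model, porosities, material = "simulated") {
  Lf <- eval_l(L_model, porosities)
  if (any(Lf < 0) || any(Lf > 1))
    stop("L(f) leaves [0, 1] over the requested porosities", call. = FALSE)
  ne <- neff_forward(porosities, n_s, Lf)
  tablet_set(porosities, ne, material = material,
             true_ns = n_s, true_L = L_model)
}

#' Absorption error study
#'
#' Quantifies the error committed by neglecting material absorption in
#' the AB-EMA. Over a grid of absorption coefficients, effective indices,
#' porosities, frequencies and pore shapes, the extinction coefficient
#' \eqn{\kappa_{eff} = c\,\alpha_{eff}/(4\pi\nu)} is folded into the
#' complex permittivity, the complex AB-EMA is solved for the solid
#' permittivity, and its real refractive index \eqn{n_{s,c}} is compared
#' with the purely real inversion \eqn{n_s}: the reported quantity is the
#' relative error \eqn{|n_{s,c} - n_s| / n_{s,c}}. Cells whose real-model
#' solution is non-physical are flagged, not dropped, keeping the report
#' rectangular.
#'
#' @param alphas absorption coefficients, cm^-1 (default 0-50 step 1).
#' @param neffs effective refractive indices (default 1-5 step 0.1).
#' @param porosities porosities (default 0.05-0.25 step 0.05).
#' @param frequencies frequencies in THz (default 0.2 and 1).
#' @param aspects pore aspect ratios defining the L values (default 5, 1,
#'   1/5, i.e. prolate, spherical, oblate).
#' @return object of class `absorption_study`: a tidy grid data frame
#'   (one row per cell) with `rel_error` and a `flag` column.
#' @export
absorption_study <- function(alphas = seq(0, 50, by = 1),
                             neffs = seq(1, 5, by = 0.1),
                             porosities = seq(0.05, 0.25, by = 0.05),
                             frequencies = c(0.2, 1),
                             aspects = c(5, 1, 1/5)) {
  grid <- expand.grid(alpha = alphas, n_eff = neffs, f = porosities,
                      frequency = frequencies, aspect = aspects,
                      KEEP.OUT.ATTRS = FALSE)
  grid$L <- depolarisation_from_aspect(grid$aspect)
  grid$kappa <- kappa_from_alpha(grid$alpha, grid$frequency)
  # real-model inversion (absorption ignored)
  ns_real <- ns_from_neff(grid$f, grid$n_eff, grid$L, warn = FALSE)
  nonphys <- attr(ns_real, "nonphysical")
  # complex inversion with eps_eff = (n - i kappa)^2
  eps_eff <- complex(real = grid$n_eff, imaginary = -grid$kappa)^2
  eps_s <- eps_s_from_eps_eff(grid$f, eps_eff, grid$L)
  nk <- .nk_from_eps(eps_s)
  grid$ns_real <- as.numeric(ns_real)
  grid$ns_complex <- Re(nk)
  grid$kappa_s <- -Im(nk)
  grid$flag <- nonphys | attr(eps_s, "degenerate") | grid$ns_complex <= 1
  grid$rel_error <- ifelse(grid$flag, NA_real_,
                           abs(grid$ns_complex - grid$ns_real) /
                             grid$ns_complex)
  structure(list(grid = grid), class = "absorption_study")
}

#' @export
print.absorption_study <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<absorption_study> %d grid cells (%d flagged)\n",
              nrow(g), sum(g$flag)))
  ok <- !g$flag
  by_l <- tapply(g$rel_error[ok], round(g$L[ok], 3), stats::median)
  cat("median relative n_s error by L:\n")
  print(signif(by_l, 3))
  invisible(x)
}

#' Pore-shape gradient study
#'
#' Simulates 51 tablet sets (porosities 0.05-0.5 step 0.05, solid index
#' 1.86) whose depolarisation factor varies linearly with porosity: the L
#' value of the highest-porosity sample steps from 0 to 1 and that of the
#' lowest-porosity sample from 1 to 0, both in increments of 0.02, giving
#' gradients from -2.222 to +2.222 in steps of 0.0889 with the
#' porosity-averaged L fixed at 0.5. Every set is fitted with the
#' constant-L grid search and the fit quality, parameter errors and
#' per-porosity residuals are recorded, together with a failure flag for
#' sets where no grid L is physical.
#'
#' @param l_step grid resolution of the embedded AB-EMA fit.
#' @return object of class `poreshape_study` with `summary` (one row per
#'   set: `a1`, `a2`, `L_min`, `L_max`, `L_fit`, `ns_fit`, `adj_r2`,
#'   `rmse_f_percent`, `rel_error_ns`, `failed`) and `residuals` (long
#'   format: `a1`, `f`, `residual_f`).
#' @export
poreshape_study <- function(l_step = 0.001) {
  f <- seq(0.05, 0.5, by = 0.05)
  ns_true <- 1.86
  rows <- vector("list", 51)
  res <- vector("list", 51)
  for (k in 0:50) {
    L_hi <- 0.02 * k           # L at the highest porosity (0.5)
    L_lo <- 1 - 0.02 * k       # L at the lowest porosity (0.05)
    a1 <- (L_hi - L_lo) / (max(f) - min(f))
    a2 <- L_lo - a1 * min(f)
    model <- linear_l(a1, a2)
    set <- gen_set(ns_true, model, f)
    fit <- fit_abema(set, l_step = l_step)
    Lf <- eval_l(model, f)
    if (!fit$failed) {
      rel <- relative_error_ns(fit, ns_true)$rel_error
      rows[[k + 1]] <- data.frame(
        a1 = a1, a2 = a2, L_min = min(Lf), L_max = max(Lf),
        L_fit = fit$L_fit, ns_fit = fit$ns_fit, adj_r2 = fit$adj_r2,
        rmse_f_percent = fit$rmse_f_percent, rel_error_ns = rel,
        n_grid_excluded = fit$n_grid_excluded, failed = FALSE)
      res[[k + 1]] <- data.frame(a1 = a1, f = f,
                                 residual_f = fit$per_sample$residual_f)
    } else {
      rows[[k + 1]] <- data.frame(
        a1 = a1, a2 = a2, L_min = min(Lf), L_max = max(Lf),
        L_fit = NA_real_, ns_fit = NA_real_, adj_r2 = NA_real_,
        rmse_f_percent = NA_real_, rel_error_ns = NA_real_,
        n_grid_excluded = fit$n_grid_excluded, failed = TRUE)
    }
  }
  structure(list(summary = do.call(rbind, rows),
                 residuals = do.call(rbind, res),
                 porosities = f, ns_true = ns_true),
            class = "poreshape_study")
}

#' @export
print.poreshape_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<poreshape_study> %d sets, gradients %.4f to %.4f\n",
              nrow(s), min(s$a1), max(s$a1)))
  ok <- !s$failed
  cat(sprintf("  fitted: %d; adj R^2 range %.4f - %.4f; max RMSE %.2f%%\n",
              sum(ok), min(s$adj_r2[ok]), max(s$adj_r2[ok]),
              max(s$rmse_f_percent[ok])))
  invisible(x)
}

#' Density-distribution study for biconvex tablets
#'
#' The terahertz beam probes the axial centre column of a tablet, whereas
#' the nominal porosity derives from the whole tablet's mass and
#' dimensions; under radial density distribution the two differ. This
#' study generates three sets over nominal porosities 0.05-0.5 (step
#' 0.05, solid index 1.86, spherical pores L = 1/3): even distribution,
#' and centre porosity a relative `deviation` above/below nominal. The
#' effective index is computed at the centre porosity but fitted against
#' the nominal porosity, exposing the bias in the fitted pore shape.
#'
#' @param deviation relative centre-porosity deviation in \[0, 0.5\]
#'   (default 0.10).
#' @param l_step grid resolution of the embedded AB-EMA fit.
#' @return object of class `density_study` with `summary` (per set:
#'   `set`, `L_fit`, `ns_fit`, `adj_r2`, `rmse_f_percent`), the three
#'   fits, and the three [tablet_set()]s.
#' @export
density_study <- function(deviation = 0.10, l_step = 0.001) {
  stopifnot(is.numeric(deviation), length(deviation) == 1)
  if (deviation < 0 || deviation > 0.5)
    stop("`deviation` must lie in [0, 0.5]", call. = FALSE)
  f <- seq(0.05, 0.5, by = 0.05)
  ns_true <- 1.86; L_true <- 1/3
  centre <- list(even = f, higher = (1 + deviation) * f,
                 lower = (1 - deviation) * f)
  if (any(unlist(centre) >= 1))
    stop("centre porosity reaches 1; reduce `deviation`", call. = FALSE)
  sets <- lapply(centre, function(fc) {
    ne <- neff_forward(fc, ns_true, L_true)
    tablet_set(f, ne, true_ns = ns_true, true_L = L_true)
  })
  fits <- lapply(sets, fit_abema, l_step = l_step)
  summary <- data.frame(
    set = names(fits),
    L_fit = vapply(fits, `[[`, numeric(1), "L_fit"),
    ns_fit = vapply(fits, `[[`, numeric(1), "ns_fit"),
    adj_r2 = vapply(fits, `[[`, numeric(1), "adj_r2"),
    rmse_f_percent = vapply(fits, `[[`, numeric(1), "rmse_f_percent"),
    row.names = NULL)
  structure(list(summary = summary, fits = fits, sets = sets,
                 deviation = deviation, ns_true = ns_true, L_true = L_true),
            class = "density_study")
}

#' @export
print.density_study <- function(x, ...) {
  cat(sprintf("<density_study> centre porosity deviation +/- %g%%\n",
              100 * x$deviation))
  print(transform(x$summary, L_fit = round(L_fit, 3),
                  adj_r2 = round(adj_r2, 4)), row.names = FALSE)
  invisible(x)
}

#' Demonstration sets for the bounds-for-L analysis
#'
#' Three simulated sets (porosities 0.05-0.5 step 0.05, solid index 1.86)
#' with linear pore-shape trends: Set 1 rising (a1 = 0.5, a2 = 0.275),
#' Set 2 falling (a1 = -0.5, a2 = 0.55) and Set 3 constant (a1 = 0,
#' a2 = 0.5). Set 3 is identical to a constant L = 0.5 set.
#'
#' @return named list of three [tablet_set()]s.
#' @export
lbounds_demo_sets <- function() {
  f <- seq(0.05, 0.5, by = 0.05)
  list(set1 = gen_set(1.86, linear_l(0.5, 0.275), f, material = "set1"),
       set2 = gen_set(1.86, linear_l(-0.5, 0.55), f, material = "set2"),
       set3 = gen_set(1.86, linear_l(0, 0.5), f, material = "set3"))
}
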