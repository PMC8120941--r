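# Grid-search AB-EMA fit, shared-n_s joint fit across sets, modified
# AB-EMA with a linear pore-shape trend, porosity prediction and
# goodness-of-fit metrics.
#
# The fit criterion follows the standard terahertz-porosity protocol: scan
# the depolarisation factor, invert the AB-EMA per sample for the solid
# index it implies, and keep the L for which those per-sample solid
# indices scatter least (smallest standard deviation); the fitted solid
# index is their mean. On noiseless model-consistent data the objective
# reaches exactly zero at the generating parameters.

# Matrix of implied n_s^2 for every sample (rows) x grid L (cols).
.ns2_matrix <- function(f, e, Ls) {
  n <- length(f); m <- length(Ls)
  D1 <- matrix(e, n, m) + outer(1 - e, Ls)
  A <- matrix(f * (1 - e), n, m) / D1
  den <- sweep(A, 2, Ls, `*`) + matrix(1 - f, n, m)
  matrix(e, n, m) - A * matrix(e, n, m) / den
}

# Column statistics for the std-of-n_s objective; Inf where any sample is
# non-physical (n_s^2 <= 1 or non-finite).
.grid_objective <- function(ns2) {
  n <- nrow(ns2)
  bad <- colSums(!is.finite(ns2) | ns2 <= 1) > 0
  ns <- sqrt(pmax(ns2, 0))
  sums <- colSums(ns)
  ss <- colSums(ns^2)
  v <- pmax(ss - sums^2 / n, 0) / (n - 1)
  obj <- sqrt(v)
  obj[bad] <- Inf
  list(obj = obj, bad = bad, sums = sums, ss = ss)
}

.new_abema_fit <- function(model_kind, ns_fit, L_fit, coef = NULL,
                           per_sample = NULL, objective = NA_real_,
                           adj_r2 = NA_real_, rmse_f_percent = NA_real_,
                           failed = FALSE, n_grid_excluded = NA_integer_) {
  structure(list(model_kind = model_kind, ns_fit = ns_fit, L_fit = L_fit,
                 coef = coef, per_sample = per_sample, objective = objective,
                 adj_r2 = adj_r2, rmse_f_percent = rmse_f_percent,
                 failed = failed, n_grid_excluded = n_grid_excluded),
            class = "abema_fit")
}

#' Grid-search AB-EMA fit of a tablet set
#'
#' Scans the depolarisation factor over `{0, l_step, ..., 1}`; at each
#' grid value the AB-EMA is inverted in closed form for the solid index
#' implied by every sample, and the grid value minimising the standard
#' deviation of those per-sample solid indices wins (ties go to the
#' smallest L). The fitted solid index is the mean of the per-sample
#' values at the winning L. Grid values at which any sample implies a
#' non-physical solid index (\eqn{n_s^2 \le 1}) are excluded; if the
#' whole grid is excluded the fit reports failure.
#'
#' @param set a [tablet_set()] with >= 3 samples over >= 2 distinct
#'   porosities.
#' @param l_step grid resolution for L (default 0.001).
#' @return an object of class `abema_fit` with fields `ns_fit`, `L_fit`,
#'   per-sample table (`f`, `n_eff`, `ns`, `f_pred`, `residual_f`),
#'   `objective` (std of per-sample n_s), `adj_r2`, `rmse_f_percent` and a
#'   `failed` flag.
#' @examples
#' set <- gen_set(1.86, 0.5, seq(0.05, 0.5, by = 0.05))
#' fit <- fit_abema(set)
#' fit$L_fit    # 0.5 recovered exactly
#' @export
fit_abema <- function(set, l_step = 0.001) {
  s <- .sorted_samples(set)
  if (nrow(s) < 3 || length(unique(s$f)) < 2)
    stop("need >= 3 samples spanning >= 2 distinct porosities", call. = FALSE)
  Ls <- seq(0, 1, by = l_step)
  ns2 <- .ns2_matrix(s$f, s$n_eff^2, Ls)
  g <- .grid_objective(ns2)
  if (all(g$bad))
    return(.new_abema_fit("abema", NA_real_, NA_real_, failed = TRUE,
                          n_grid_excluded = sum(g$bad)))
  i <- which.min(g$obj)            # first minimum = smallest L on ties
  L_fit <- Ls[i]
  ns_i <- sqrt(ns2[, i])
  fit <- .new_abema_fit("abema", mean(ns_i), L_fit, objective = g$obj[i],
                        n_grid_excluded = sum(g$bad))
  .finish_fit(fit, s, ns_i)
}

# attach per-sample table and goodness metrics
.finish_fit <- function(fit, s, ns_i) {
  f_pred <- predict_porosity(fit, s$n_eff)
  fit$per_sample <- data.frame(f = s$f, n_eff = s$n_eff, ns = ns_i,
                               f_pred = as.numeric(f_pred),
                               residual_f = as.numeric(f_pred) - s$f)
  gof <- goodness(fit, tablet_set(s$f, s$n_eff))
  fit$adj_r2 <- gof$adj_r2
  fit$rmse_f_percent <- gof$rmse_f_percent
  fit
}

#' @export
print.abema_fit <- function(x, ...) {
  if (x$failed) {
    cat("<abema_fit> FAILED: every grid L implied a non-physical n_s\n")
    return(invisible(x))
  }
  if (x$model_kind == "mabema") {
    cat(sprintf("<abema_fit> mAB-EMA: n_s = %.4f, L(f) = %.4f f + %.4f\n",
                x$ns_fit, x$coef[["a1"]], x$coef[["a2"]]))
  } else {
    cat(sprintf("<abema_fit> AB-EMA: n_s = %.4f, L = %.3f\n",
                x$ns_fit, x$L_fit))
  }
  cat(sprintf("  objective (std n_s) = %.3g, adj R^2 = %.5f, RMSE(f) = %.3f%%\n",
              x$objective, x$adj_r2, x$rmse_f_percent))
  invisible(x)
}

#' Joint AB-EMA fit of several sets sharing one solid index
#'
#' Tablet sets of the same material must share the solid refractive
#' index even when their microstructures (and hence depolarisation
#' factors) differ. This fit selects one L per set and a single global
#' solid index minimising the pooled sum of squared deviations of every
#' per-sample implied solid index from the global value. For a single set
#' it reduces to [fit_abema()] up to tie-breaking. Sets of two are solved
#' by exhaustive grid search; larger collections by coordinate descent
#' over the per-set grids.
#'
#' @param sets list of [tablet_set()] objects.
#' @param l_step grid resolution for each per-set L.
#' @param max_iter coordinate-descent iteration cap (> 2 sets).
#' @return list with `ns_fit` (shared), `L_fit` (per set), per-set
#'   `abema_fit` objects evaluated at the joint solution, and the pooled
#'   `objective`.
#' @export
fit_abema_shared <- function(sets, l_step = 0.001, max_iter = 50) {
  stopifnot(is.list(sets), length(sets) >= 1,
            all(vapply(sets, inherits, logical(1), "tablet_set")))
  Ls <- seq(0, 1, by = l_step)
  K <- length(sets)
  pre <- lapply(sets, function(set) {
    s <- .sorted_samples(set)
    ns2 <- .ns2_matrix(s$f, s$n_eff^2, Ls)
    g <- .grid_objective(ns2)
    sums <- g$sums; ss <- g$ss
    sums[g$bad] <- NA; ss[g$bad] <- NA
    list(s = s, ns2 = ns2, sums = sums, ss = ss, n = nrow(s), bad = g$bad)
  })
  if (any(vapply(pre, function(p) all(p$bad), logical(1))))
    stop("a set admits no physical grid L; cannot fit jointly", call. = FALSE)
  N <- sum(vapply(pre, `[[`, numeric(1), "n"))
  pooled <- function(idx) {
    St <- sum(vapply(seq_len(K), function(k) pre[[k]]$sums[idx[k]], 1))
    Qt <- sum(vapply(seq_len(K), function(k) pre[[k]]$ss[idx[k]], 1))
    Qt - St^2 / N
  }
  if (K == 1) {
    obj <- pre[[1]]$ss - pre[[1]]$sums^2 / N
    idx <- which.min(obj)
  } else if (K == 2) {
    Q <- outer(pre[[1]]$ss, pre[[2]]$ss, `+`)
    S <- outer(pre[[1]]$sums, pre[[2]]$sums, `+`)
    M <- Q - S^2 / N
    i <- arrayInd(which.min(M), dim(M))
    idx <- c(i[1], i[2])
  } else {
    idx <- vapply(pre, function(p) which.min(p$ss - p$sums^2 / p$n),
                  integer(1))
    for (iter in seq_len(max_iter)) {
      prev <- idx
      for (k in seq_len(K)) {
        So <- sum(vapply(setdiff(seq_len(K), k),
                         function(j) pre[[j]]$sums[idx[j]], 1))
        Qo <- sum(vapply(setdiff(seq_len(K), k),
                         function(j) pre[[j]]$ss[idx[j]], 1))
        obj_k <- (Qo + pre[[k]]$ss) - (So + pre[[k]]$sums)^2 / N
        idx[k] <- which.min(obj_k)
      }
      if (identical(idx, prev)) break
    }
  }
  ns_shared <- sum(vapply(seq_len(K), function(k) pre[[k]]$sums[idx[k]], 1)) / N
  fits <- lapply(seq_len(K), function(k) {
    p <- pre[[k]]
    ns_i <- sqrt(p$ns2[, idx[k]])
    fit <- .new_abema_fit("abema", ns_shared, Ls[idx[k]],
                          objective = stats::sd(ns_i),
                          n_grid_excluded = sum(p$bad))
    .finish_fit(fit, p$s, ns_i)
  })
  list(ns_fit = ns_shared, L_fit = Ls[idx], fits = fits,
       objective = pooled(idx))
}

#' Modified AB-EMA fit with a linear pore-shape trend
#'
#' Replaces the constant depolarisation factor by the linear model
#' \eqn{L(f) = a_1 f + a_2} and minimises the same std-of-n_s objective
#' over \eqn{(a_1, a_2)}, subject to \eqn{0 \le a_1 f + a_2 \le 1} at
#' every sample porosity. A coarse feasibility-constrained grid search
#' (steps 0.02 in \eqn{a_1}, 0.005 in \eqn{a_2}) seeds a Nelder-Mead
#' refinement; the constant-L solution (\eqn{a_1 = 0}) is always among
#' the candidates, so the modified fit can never do worse than
#' [fit_abema()] on the same set.
#'
#' @param set a [tablet_set()] with >= 4 samples.
#' @param a1_range search interval for the gradient (default \[-2.5, 2.5\]).
#' @param l_step grid step of the embedded constant-L fit.
#' @param refine run the Nelder-Mead refinement (default `TRUE`).
#' @return an `abema_fit` with `model_kind = "mabema"` and `coef`
#'   holding `a1`, `a2`.
#' @export
fit_mabema <- function(set, a1_range = c(-2.5, 2.5), l_step = 0.001,
                       refine = TRUE) {
  s <- .sorted_samples(set)
  if (nrow(s) < 4) stop("need >= 4 samples for the mAB-EMA", call. = FALSE)
  f <- s$f; e <- s$n_eff^2; n <- length(f)
  obj_fun <- function(par) {
    Lf <- par[1] * f + par[2]
    if (any(Lf < 0) || any(Lf > 1)) return(Inf)
    ns2 <- .ns2_closed(f, e, Lf)
    if (any(!is.finite(ns2)) || any(ns2 <= 1)) return(Inf)
    stats::sd(sqrt(ns2))
  }
  a1g <- seq(a1_range[1], a1_range[2], by = 0.02)
  a2g <- seq(0, 1, by = 0.005)
  # feasible (a1, a2) combinations at the sample porosities only
  fmin <- min(f); fmax <- max(f)
  grid <- expand.grid(a1 = a1g, a2 = a2g)
  lo_end <- grid$a1 * fmin + grid$a2
  hi_end <- grid$a1 * fmax + grid$a2
  feas <- lo_end >= 0 & lo_end <= 1 & hi_end >= 0 & hi_end <= 1
  grid <- grid[feas, , drop = FALSE]
  if (nrow(grid) == 0) stop("infeasible constraint set", call. = FALSE)
  vals <- vapply(seq_len(nrow(grid)),
                 function(i) obj_fun(c(grid$a1[i], grid$a2[i])), numeric(1))
  # scalar fit as nested candidate
  scalar <- fit_abema(set, l_step = l_step)
  cand <- list()
  if (any(is.finite(vals))) {
    i <- which.min(vals)
    cand <- c(cand, list(c(grid$a1[i], grid$a2[i])))
  }
  if (!scalar$failed) cand <- c(cand, list(c(0, scalar$L_fit)))
  if (length(cand) == 0)
    return(.new_abema_fit("mabema", NA_real_, NA_real_, failed = TRUE))
  best <- NULL
  for (p0 in cand) {
    v0 <- obj_fun(p0)
    p1 <- p0; v1 <- v0
    if (refine && is.finite(v0) && v0 > 0) {
      op <- stats::optim(p0, obj_fun, method = "Nelder-Mead",
                         control = list(reltol = 1e-12, maxit = 2000))
      if (is.finite(op$value) && op$value < v1) { p1 <- op$par; v1 <- op$value }
    }
    if (is.null(best) || v1 < best$v) best <- list(p = p1, v = v1)
  }
  Lf <- best$p[1] * f + best$p[2]
  ns_i <- sqrt(.ns2_closed(f, e, Lf))
  fit <- .new_abema_fit("mabema", mean(ns_i), NA_real_,
                        coef = c(a1 = best$p[1], a2 = best$p[2]),
                        objective = best$v)
  .finish_fit(fit, s, ns_i)
}

#' Predict porosity from an effective refractive index
#'
#' Inverts a fitted AB-EMA calibration. For the constant-L model this is
#' the closed-form linear inversion; for the modified AB-EMA the scalar
#' equation in f (L depends on f) is solved by bracketed root-finding on
#' \[0, 1\]. Indices without a root in \[0, 1\] are clamped to the nearest
#' endpoint and flagged in the `"clamped"` attribute.
#'
#' @param fit an `abema_fit`.
#' @param n_eff effective refractive indices (vectorised).
#' @return porosity fractions with logical attribute `"clamped"`.
#' @export
predict_porosity <- function(fit, n_eff) {
  stopifnot(inherits(fit, "abema_fit"))
  if (fit$failed) stop("cannot predict from a failed fit", call. = FALSE)
  ns <- fit$ns_fit
  if (fit$model_kind == "abema") {
    clamped <- n_eff > ns | n_eff < 1
    ne <- pmin(pmax(n_eff, 1), ns)
    out <- porosity_from_neff(ne, ns, fit$L_fit)
  } else {
    a1 <- fit$coef[["a1"]]; a2 <- fit$coef[["a2"]]
    one <- function(ne) {
      g <- function(f) neff_forward(f, ns, min(max(a1 * f + a2, 0), 1)) - ne
      g0 <- g(0); g1 <- g(1)
      if (g0 * g1 > 0) return(if (abs(g0) < abs(g1)) c(0, TRUE) else c(1, TRUE))
      r <- stats::uniroot(g, c(0, 1), tol = 1e-12)
      c(r$root, FALSE)
    }
    m <- vapply(n_eff, one, numeric(2))
    out <- m[1, ]; clamped <- as.logical(m[2, ])
  }
  attr(out, "clamped") <- clamped
  out
}

#' Goodness-of-fit metrics of an AB-EMA calibration
#'
#' The adjusted coefficient of determination is computed on the measured
#' effective indices against the fitted model curve,
#' \eqn{R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - p - 1)} with p = 2 fitted
#' parameters for the constant-L model and p = 3 for the modified AB-EMA.
#' The root-mean-squared error is reported for the independent variable -
#' the porosity - in percentage points, since in tablet characterisation
#' the calibration is used to predict porosity from the measured index.
#'
#' @param fit an `abema_fit`.
#' @param set the [tablet_set()] the fit was computed on.
#' @return list with `adj_r2`, `r2`, `rmse_f_percent` and per-sample
#'   porosity `residuals`; `adj_r2` is `NA` (flagged) when n <= p + 1.
#' @export
goodness <- function(fit, set) {
  stopifnot(inherits(fit, "abema_fit"), inherits(set, "tablet_set"))
  if (fit$failed) stop("fit failed; no goodness metrics", call. = FALSE)
  s <- .sorted_samples(set)
  p <- if (fit$model_kind == "mabema") 3 else 2
  Lf <- if (fit$model_kind == "mabema")
    pmin(pmax(fit$coef[["a1"]] * s$f + fit$coef[["a2"]], 0), 1)
  else fit$L_fit
  ne_hat <- neff_forward(s$f, fit$ns_fit, Lf)
  ss_res <- sum((s$n_eff - ne_hat)^2)
  ss_tot <- sum((s$n_eff - mean(s$n_eff))^2)
  r2 <- 1 - ss_res / ss_tot
  n <- nrow(s)
  adj <- if (n > p + 1) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  f_pred <- as.numeric(predict_porosity(fit, s$n_eff))
  res <- f_pred - s$f
  list(adj_r2 = adj, r2 = r2,
       rmse_f_percent = sqrt(mean(res^2)) * 100, residuals = res)
}

#' Relative error of the fitted solid refractive index
#'
#' @param fit an `abema_fit`.
#' @param ns_true reference solid index, > 1.
#' @return list with the overall relative error `|ns_fit - ns_true| /
#'   ns_true` (fraction), the signed error, and the per-sample relative
#'   errors of the implied solid indices.
#' @export
relative_error_ns <- function(fit, ns_true) {
  stopifnot(inherits(fit, "abema_fit"), is.numeric(ns_true), ns_true > 1)
  if (fit$failed) stop("fit failed; no n_s estimate", call. = FALSE)
  list(rel_error = abs(fit$ns_fit - ns_true) / ns_true,
       signed = (fit$ns_fit - ns_true) / ns_true,
       per_sample = abs(fit$per_sample$ns - ns_true) / ns_true)
}
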