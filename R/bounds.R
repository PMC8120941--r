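# Wiener bounds, the solid-index margins from the lowest-porosity sample,
# the derived per-sample bounds for the depolarisation factor, bound
# tangents and AB-EMA fit validation.

#' Wiener bounds of the effective refractive index
#'
#' The serial/parallel capacitor extremes of effective medium theory:
#' \eqn{n_{eff,l}^2 = 1/(f + (1-f)/n_s^2)} (serial, AB-EMA at L = 1) and
#' \eqn{n_{eff,u}^2 = f + (1-f)\,n_s^2} (parallel, AB-EMA at L = 0). Any
#' measured effective index of a two-phase compact must lie between them.
#'
#' @param f porosity in \[0, 1\] (vectorised).
#' @param n_s solid refractive index, >= 1.
#' @return list with components `lower` and `upper`.
#' @export
wiener_bounds <- function(f, n_s) {
  stopifnot(is.numeric(f), is.numeric(n_s), length(n_s) == 1)
  if (any(f < 0) || any(f > 1)) stop("`f` must lie in [0, 1]", call. = FALSE)
  if (n_s < 1) stop("`n_s` must be >= 1", call. = FALSE)
  s <- n_s^2
  list(lower = sqrt(s / (f * s + 1 - f)), upper = sqrt(f + (1 - f) * s))
}

#' Multicomponent Wiener bounds
#'
#' Generalisation to J solid components with within-solid fractions `x`
#' (summing to 1) and refractive indices `n`; each solid occupies volume
#' fraction (1 - f) x_j. A single component reduces exactly to
#' [wiener_bounds()]. Note these multicomponent bounds do not conform with
#' the two-phase AB-EMA and are not used by the bounds-for-L machinery.
#'
#' @param f porosity in \[0, 1\].
#' @param x solid-phase fractions, summing to 1 (tolerance 1e-9).
#' @param n refractive indices of the solid components, each >= 1.
#' @return list with components `lower` and `upper`.
#' @export
wiener_bounds_multi <- function(f, x, n) {
  stopifnot(is.numeric(f), length(f) == 1, is.numeric(x), is.numeric(n),
            length(x) == length(n))
  if (f < 0 || f > 1) stop("`f` must lie in [0, 1]", call. = FALSE)
  if (abs(sum(x) - 1) > 1e-9)
    stop("solid fractions `x` must sum to 1", call. = FALSE)
  if (any(n < 1)) stop("all `n` must be >= 1", call. = FALSE)
  list(lower = sqrt(1 / (f + (1 - f) * sum(x / n^2))),
       upper = sqrt(f + (1 - f) * sum(x * n^2)))
}

#' Margins for the solid refractive index from the lowest-porosity sample
#'
#' If the lowest-porosity sample had extreme pore shapes (L = 1 serial or
#' L = 0 parallel), its measured effective index pins down the largest and
#' smallest solid index compatible with the data:
#' \eqn{n_{s,u}^2 = (1 - f_1) / (1/n_{eff,1}^2 - f_1)} and
#' \eqn{n_{s,l}^2 = (n_{eff,1}^2 - f_1) / (1 - f_1)}. Whenever the data
#' obey the AB-EMA, the true solid index lies between the margins. The
#' anchor is the sample with strictly minimal porosity; ties are broken by
#' the larger effective index (tighter margins).
#'
#' @param set a [tablet_set()].
#' @return object of class `ns_margins` with fields `ns_l`, `ns_u`, `f1`,
#'   `neff1` and a logical `upper_defined` flag (the upper margin is
#'   undefined when \eqn{1/n_{eff,1}^2 \le f_1}).
#' @export
ns_margins <- function(set) {
  s <- .sorted_samples(set)
  if (nrow(s) < 1) stop("`set` must contain at least one sample", call. = FALSE)
  f1 <- s$f[1]
  cand <- s[s$f == f1, , drop = FALSE]
  neff1 <- max(cand$n_eff)
  e1 <- neff1^2
  ns_l <- sqrt(max((e1 - f1) / (1 - f1), 0))
  upper_defined <- 1 / e1 > f1
  ns_u <- if (upper_defined) sqrt((1 - f1) / (1 / e1 - f1)) else Inf
  structure(list(ns_l = ns_l, ns_u = ns_u, f1 = f1, neff1 = neff1,
                 upper_defined = upper_defined),
            class = "ns_margins")
}

#' @export
print.ns_margins <- function(x, ...) {
  cat(sprintf("n_s margins [%.4f, %s] from anchor f1 = %.4f, n_eff,1 = %.4f\n",
              x$ns_l, if (is.finite(x$ns_u)) sprintf("%.4f", x$ns_u) else "Inf",
              x$f1, x$neff1))
  invisible(x)
}

# Unclamped closed-form L for a sample against a given n_s; NA when n_s
# is not usable (<= 1 or infinite).
.l_raw <- function(e, f, n_s) {
  if (!is.finite(n_s) || n_s <= 1) return(rep(NA_real_, length(e)))
  s <- n_s^2
  hi <- f + (1 - f) * s
  e * (hi - e) / ((e - 1) * (s - e))
}

#' Per-sample bounds for the depolarisation factor
#'
#' Substitutes the two solid-index margins of [ns_margins()] into the
#' closed-form single-sample inversion of the AB-EMA, producing for every
#' sample an interval \[L_l, L_u\] that the true depolarisation factor
#' must occupy. The anchor (lowest-porosity) sample carries no shape
#' information and yields (0, 1) by construction. Values falling outside
#' \[0, 1\] (possible for noisy data whose effective index crosses a
#' margin's Wiener bound) are clamped and flagged.
#'
#' Also records the finite-difference tangents of both bounds over the two
#' highest-porosity samples; on AB-EMA-consistent data with a linear
#' pore-shape trend both tangents converge to the trend's gradient as the
#' bounds tighten with porosity.
#'
#' @param set a [tablet_set()] with at least two distinct porosities.
#' @param margins optionally, precomputed [ns_margins()].
#' @return object of class `l_bounds`: a per-sample table (`f`, `n_eff`,
#'   `L_l`, `L_u`, clamping flags, anchor flag), the margins, and the
#'   bound tangents.
#' @export
l_bounds <- function(set, margins = NULL) {
  s <- .sorted_samples(set)
  if (length(unique(s$f)) < 2)
    stop("`set` needs >= 2 samples with distinct porosities", call. = FALSE)
  if (is.null(margins)) margins <- ns_margins(set)
  e <- s$n_eff^2
  raw_l <- .l_raw(e, s$f, margins$ns_l)
  raw_u <- .l_raw(e, s$f, margins$ns_u)
  anchor <- s$f == margins$f1   # porosities are unique within a set
  L_l <- pmin(pmax(raw_l, 0), 1)
  L_u <- pmin(pmax(raw_u, 0), 1)
  clamped_l <- !is.na(raw_l) & (raw_l < 0 | raw_l > 1)
  clamped_u <- !is.na(raw_u) & (raw_u < 0 | raw_u > 1)
  # the anchor bounds are (0, 1) exactly by construction of the margins
  L_l[anchor] <- 0
  L_u[anchor] <- 1
  clamped_l[anchor] <- clamped_u[anchor] <- FALSE
  L_u[is.na(raw_u)] <- 1                          # undefined upper margin
  L_l[is.na(raw_l)] <- 0                          # degenerate lower margin
  tab <- data.frame(f = s$f, n_eff = s$n_eff, L_l = L_l, L_u = L_u,
                    clamped_l = clamped_l, clamped_u = clamped_u,
                    anchor = anchor)
  out <- structure(list(table = tab, margins = margins, tangents = NULL),
                   class = "l_bounds")
  out$tangents <- bound_tangents(out)
  out
}

#' Tangents of the depolarisation bounds at the high-porosity end
#'
#' Finite-difference slopes dL/df of the lower and upper bound over the
#' two highest-porosity samples. Steep, converging tangents indicate a
#' pore shape that changes with porosity, i.e. data the constant-L AB-EMA
#' cannot represent.
#'
#' @param bounds an [l_bounds()] result.
#' @return named numeric vector `c(lower = , upper = )`.
#' @export
bound_tangents <- function(bounds) {
  stopifnot(inherits(bounds, "l_bounds"))
  tab <- bounds$table[!bounds$table$anchor, , drop = FALSE]
  if (nrow(tab) < 2)
    stop("need >= 2 non-anchor samples for bound tangents", call. = FALSE)
  k <- order(tab$f)
  top <- tab[k[(nrow(tab) - 1):nrow(tab)], ]
  df <- diff(top$f)
  c(lower = diff(top$L_l) / df, upper = diff(top$L_u) / df)
}

#' @export
print.l_bounds <- function(x, ...) {
  cat("<l_bounds> per-sample depolarisation bounds\n")
  print(x$margins)
  print(x$table[, c("f", "L_l", "L_u", "anchor")], row.names = FALSE)
  cat(sprintf("tangents (two highest porosities): lower %.4f, upper %.4f\n",
              x$tangents[["lower"]], x$tangents[["upper"]]))
  invisible(x)
}

#' @export
as.data.frame.l_bounds <- function(x, ...) x$table

#' Validate an AB-EMA fit against the depolarisation bounds
#'
#' A fitted pore-shape trajectory that escapes the per-sample bounds is
#' physically impossible, and bounds converging onto a steep gradient
#' indicate that a constant pore shape cannot describe the data. Both
#' conditions mark the constant-L AB-EMA fit invalid; for the modified
#' AB-EMA (which models the gradient) only the containment check applies.
#'
#' @param fit an [fit_abema()] or [fit_mabema()] result.
#' @param bounds the [l_bounds()] of the same set.
#' @param tangent_threshold gradient magnitude above which the bounds are
#'   considered to converge onto a "steep" pore-shape trend; the verdict
#'   compares the mean of the two bound tangents against it, since before
#'   convergence the individual tangents are steep even for constant-L
#'   data over a narrow porosity range (default 0.25 per unit porosity;
#'   the choice is a documented convention, not a literature value).
#' @param tol numerical slack for the containment comparison.
#' @return object of class `abema_validity` with the per-sample table,
#'   the offending porosities and an overall `valid` verdict.
#' @export
validate_fit <- function(fit, bounds, tangent_threshold = 0.25, tol = 1e-9) {
  stopifnot(inherits(fit, "abema_fit"), inherits(bounds, "l_bounds"))
  tab <- bounds$table
  Lf <- if (fit$model_kind == "mabema")
    fit$coef[["a1"]] * tab$f + fit$coef[["a2"]] else rep(fit$L_fit, nrow(tab))
  within <- Lf >= tab$L_l - tol & Lf <= tab$L_u + tol
  within[tab$anchor] <- TRUE
  steep <- if (fit$model_kind == "abema")
    abs(mean(bounds$tangents)) > tangent_threshold else FALSE
  res <- data.frame(f = tab$f, L_fit = Lf, L_l = tab$L_l, L_u = tab$L_u,
                    within = within, anchor = tab$anchor)
  structure(list(table = res,
                 violations = tab$f[!within],
                 steep_tangent = steep,
                 tangent_threshold = tangent_threshold,
                 valid = all(within) && !steep),
            class = "abema_validity")
}

#' @export
print.abema_validity <- function(x, ...) {
  cat(sprintf("AB-EMA fit validity: %s\n",
              if (x$valid) "valid" else "INVALID"))
  if (length(x$violations))
    cat("  L_fit outside bounds at porosities:",
        paste(format(x$violations), collapse = ", "), "\n")
  if (x$steep_tangent)
    cat(sprintf("  bound tangents exceed |%.2f| per unit porosity\n",
                x$tangent_threshold))
  invisible(x)
}
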