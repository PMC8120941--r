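# TabletSet container: an ordered collection of (porosity, n_eff) samples
# for one material/geometry, optionally carrying the generating ground
# truth for simulated sets.

#' Linear pore-shape model L(f) = a1 f + a2
#'
#' Describes a depolarisation factor that changes linearly with porosity,
#' as used by the modified AB-EMA and the pore-shape simulation study.
#'
#' @param a1 gradient of L with porosity (per unit porosity).
#' @param a2 intercept, the depolarisation factor extrapolated to f = 0.
#' @return an object of class `linear_l`.
#' @examples
#' m <- linear_l(0.5, 0.275)
#' eval_l(m, c(0.05, 0.5))
#' @export
linear_l <- function(a1, a2) {
  stopifnot(is.numeric(a1), is.numeric(a2), length(a1) == 1, length(a2) == 1)
  structure(list(a1 = a1, a2 = a2), class = "linear_l")
}

#' Evaluate a pore-shape model at given porosities
#'
#' @param L a scalar depolarisation factor or a [linear_l()] model.
#' @param f porosities at which to evaluate.
#' @return depolarisation factors, one per porosity.
#' @export
eval_l <- function(L, f) {
  if (inherits(L, "linear_l")) L$a1 * f + L$a2 else rep_len(L, length(f))
}

#' @export
print.linear_l <- function(x, ...) {
  cat(sprintf("L(f) = %g f + %g\n", x$a1, x$a2))
  invisible(x)
}

#' Construct a set of tablet porosity/index observations
#'
#' @param porosity porosity fractions, each in \[0, 1).
#' @param n_eff effective refractive indices, each >= 1.
#' @param material free-text material label.
#' @param true_ns optional generating solid index (synthetic sets).
#' @param true_L optional generating depolarisation factor: a scalar or a
#'   [linear_l()] model.
#' @param label optional per-sample labels.
#' @return an object of class `tablet_set`.
#' @export
tablet_set <- function(porosity, n_eff, material = "", true_ns = NULL,
                       true_L = NULL, label = NULL) {
  stopifnot(is.numeric(porosity), is.numeric(n_eff),
            length(porosity) == length(n_eff))
  if (any(porosity < 0) || any(porosity >= 1))
    stop("porosities must lie in [0, 1)", call. = FALSE)
  if (any(n_eff < 1))
    stop("`n_eff` must be >= 1", call. = FALSE)
  if (anyDuplicated(round(porosity / 1e-9)))
    stop("porosities must be unique (at 1e-9 resolution)", call. = FALSE)
  if (is.null(label)) label <- as.character(seq_along(porosity))
  structure(
    list(samples = data.frame(f = porosity, n_eff = n_eff,
                              label = as.character(label),
                              stringsAsFactors = FALSE),
         material = material, true_ns = true_ns, true_L = true_L),
    class = "tablet_set")
}

#' @export
print.tablet_set <- function(x, ...) {
  cat(sprintf("<tablet_set> %d samples%s\n", nrow(x$samples),
              if (nzchar(x$material)) paste0(" [", x$material, "]") else ""))
  cat(sprintf("  porosity %.3f - %.3f, n_eff %.4f - %.4f\n",
              min(x$samples$f), max(x$samples$f),
              min(x$samples$n_eff), max(x$samples$n_eff)))
  if (!is.null(x$true_ns))
    cat(sprintf("  generated with n_s = %g\n", x$true_ns))
  invisible(x)
}

#' @export
as.data.frame.tablet_set <- function(x, ...) x$samples

# samples sorted by increasing porosity
.sorted_samples <- function(set) {
  stopifnot(inherits(set, "tablet_set"))
  s <- set$samples
  s[order(s$f), , drop = FALSE]
}
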