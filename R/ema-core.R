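# Closed-form solvers for the anisotropic Bruggeman effective medium
# approximation (AB-EMA) of a two-phase air/solid compact, plus the
# spheroid-shape and absorption/extinction conversions.
#
# Throughout, the AB-EMA for a porous two-component system reads
#
#   f (1 - e)/(e + L(1 - e)) + (1 - f)(s - e)/(e + L(s - e)) = 0
#
# with e = n_eff^2, s = n_s^2, porosity f and depolarisation factor L.
# The equation is linear in f, linear in s, linear in L and quadratic in e,
# so every single-unknown inversion has a closed form.

#' Speed of light in vacuum (m s^-1)
#' @noRd
.C_MPS <- 299792458

#' Depolarisation factor of a spheroidal pore from its aspect ratio
#'
#' Converts the polar-to-equatorial aspect ratio p:q of a spheroidal
#' inclusion (polar axis parallel to the wavevector) into the
#' depolarisation factor \eqn{L = 1 / (1 + 1.6\,x + 0.4\,x^2)} used by the
#' anisotropic Bruggeman model. A sphere (aspect 1) gives \eqn{L = 1/3};
#' prolate, needle-like pores (aspect \eqn{\to\infty}) give \eqn{L \to 0}
#' and flat oblate pores (aspect \eqn{\to 0}) give \eqn{L \to 1}.
#'
#' @param aspect positive polar-to-equatorial semi-axis ratio p:q.
#' @return depolarisation factor in (0, 1), vectorised over `aspect`.
#' @seealso [aspect_from_depolarisation()] for the inverse.
#' @examples
#' depolarisation_from_aspect(1)    # 1/3, spherical pore
#' depolarisation_from_aspect(5)    # ~0.053, prolate
#' depolarisation_from_aspect(1/5)  # ~0.75, oblate
#' @export
depolarisation_from_aspect <- function(aspect) {
  stopifnot(is.numeric(aspect))
  if (any(!is.finite(aspect)) || any(aspect <= 0))
    stop("`aspect` must be a finite, strictly positive ratio", call. = FALSE)
  1 / (1 + 1.6 * aspect + 0.4 * aspect^2)
}

#' Aspect ratio of a spheroidal pore from its depolarisation factor
#'
#' Inverts the shape mapping of [depolarisation_from_aspect()] by taking the
#' unique positive root of \eqn{0.4 x^2 + 1.6 x + 1 - 1/L = 0}. The
#' endpoints L = 0 and L = 1 correspond to infinitely elongated and
#' infinitely flat spheroids and have no finite aspect ratio.
#'
#' @param L depolarisation factor, strictly inside (0, 1).
#' @return positive aspect ratio p:q, vectorised over `L`.
#' @examples
#' aspect_from_depolarisation(1/3)   # 1, sphere
#' aspect_from_depolarisation(0.04)  # 6
#' @export
aspect_from_depolarisation <- function(L) {
  stopifnot(is.numeric(L))
  if (any(!is.finite(L)) || any(L <= 0) || any(L >= 1))
    stop("`L` must lie strictly inside (0, 1)", call. = FALSE)
  # 0.4 x^2 + 1.6 x + (1 - 1/L) = 0, positive root
  (-1.6 + sqrt(2.56 - 1.6 * (1 - 1 / L))) / 0.8
}

#' Convert an absorption coefficient to an extinction coefficient
#'
#' \eqn{\kappa = c\,\alpha / (4\pi\nu)} with the absorption coefficient
#' given in cm^-1 and the frequency in THz (converted internally to SI).
#'
#' @param alpha absorption coefficient in cm^-1, non-negative.
#' @param frequency frequency in THz, strictly positive.
#' @return dimensionless extinction coefficient, vectorised.
#' @seealso [alpha_from_kappa()]
#' @export
kappa_from_alpha <- function(alpha, frequency) {
  stopifnot(is.numeric(alpha), is.numeric(frequency))
  if (any(alpha < 0)) stop("`alpha` must be non-negative", call. = FALSE)
  if (any(frequency <= 0)) stop("`frequency` must be positive", call. = FALSE)
  .C_MPS * (alpha * 100) / (4 * pi * frequency * 1e12)
}

#' @rdname kappa_from_alpha
#' @param kappa dimensionless extinction coefficient, non-negative.
#' @export
alpha_from_kappa <- function(kappa, frequency) {
  stopifnot(is.numeric(kappa), is.numeric(frequency))
  if (any(kappa < 0)) stop("`kappa` must be non-negative", call. = FALSE)
  if (any(frequency <= 0)) stop("`frequency` must be positive", call. = FALSE)
  kappa * 4 * pi * frequency * 1e12 / .C_MPS / 100
}

#' Effective refractive index predicted by the AB-EMA
#'
#' Solves the AB-EMA forward for the effective index of a porous compact
#' with porosity `f`, solid index `n_s` and depolarisation factor `L`. The
#' equation is rearranged to a quadratic in \eqn{n_{eff}^2}; the physical
#' root is the one bracketed by the Wiener bounds, which coincide with the
#' model at L = 0 (upper) and L = 1 (lower). The endpoints are evaluated
#' through the Wiener closed forms directly to avoid a degenerate
#' quadratic.
#'
#' @param f porosity in \[0, 1\] (vectorised).
#' @param n_s intrinsic refractive index of the solid, > 1.
#' @param L depolarisation factor in \[0, 1\]; scalar or of the length of
#'   `f`.
#' @return effective refractive index, same length as `f`.
#' @examples
#' neff_forward(0.15, 1.86, 1/3)
#' neff_forward(c(0, 1), 1.86, 0.5)  # limits n_s and 1
#' @export
neff_forward <- function(f, n_s, L) {
  stopifnot(is.numeric(f), is.numeric(n_s), is.numeric(L))
  if (length(n_s) != 1 || !is.finite(n_s) || n_s <= 1)
    stop("`n_s` must be a single value > 1", call. = FALSE)
  if (any(f < 0) || any(f > 1)) stop("`f` must lie in [0, 1]", call. = FALSE)
  if (any(L < 0) || any(L > 1)) stop("`L` must lie in [0, 1]", call. = FALSE)
  n <- max(length(f), length(L))
  f <- rep_len(f, n); L <- rep_len(L, n)
  s <- n_s^2
  lo <- s / (f * s + 1 - f)       # lower Wiener bound squared (L = 1)
  hi <- f + (1 - f) * s           # upper Wiener bound squared (L = 0)
  e <- ifelse(L == 0, hi, ifelse(L == 1, lo, NA_real_))
  mid <- is.na(e)
  if (any(mid)) {
    fm <- f[mid]; Lm <- L[mid]
    a <- -(1 - Lm)
    b <- (1 - Lm) * (fm + (1 - fm) * s) - Lm * (fm * s + 1 - fm)
    cc <- Lm * s
    # numerically stable quadratic roots (a -> 0 as L -> 1)
    sgn <- ifelse(b >= 0, 1, -1)
    q <- -(b + sgn * sqrt(pmax(b^2 - 4 * a * cc, 0))) / 2
    r1 <- q / a
    r2 <- cc / q
    lom <- lo[mid]; him <- hi[mid]
    tol <- 1e-9 * him
    in1 <- r1 >= lom - tol & r1 <= him + tol
    in2 <- r2 >= lom - tol & r2 <= him + tol
    if (any(!(in1 | in2)))
      stop("internal error: no AB-EMA root inside the Wiener bracket",
           call. = FALSE)
    e[mid] <- ifelse(in1, r1, r2)
  }
  sqrt(e)
}

# Raw closed-form n_s^2 from (f, n_eff^2, L); no physicality checks.
# Linear in s: A + (1-f)(s-e)/(e + L(s-e)) = 0 with A = f(1-e)/(e + L(1-e))
# gives s = e - A e / (A L + 1 - f).
.ns2_closed <- function(f, e, L) {
  A <- f * (1 - e) / (e + L * (1 - e))
  e - A * e / (A * L + 1 - f)
}

#' Intrinsic solid refractive index implied by a single sample
#'
#' Closed-form inversion of the AB-EMA for \eqn{n_s} given one
#' (porosity, effective index) observation and a depolarisation factor.
#' Values with \eqn{n_s^2 \le 1} are non-physical (the solid would be less
#' polarisable than air); these are returned as `NA` and flagged in the
#' `"nonphysical"` attribute rather than silently passed on.
#'
#' @param f porosity, < 1 (vectorised).
#' @param n_eff measured effective refractive index, >= 1.
#' @param L depolarisation factor in \[0, 1\].
#' @param warn warn when non-physical results occur (default `TRUE`).
#' @return implied \eqn{n_s} values; `NA` where non-physical, with a
#'   logical attribute `"nonphysical"`.
#' @export
ns_from_neff <- function(f, n_eff, L, warn = TRUE) {
  stopifnot(is.numeric(f), is.numeric(n_eff), is.numeric(L))
  if (any(f >= 1)) stop("`f` must be strictly below 1", call. = FALSE)
  if (any(n_eff < 1)) stop("`n_eff` must be >= 1", call. = FALSE)
  if (any(L < 0) || any(L > 1)) stop("`L` must lie in [0, 1]", call. = FALSE)
  n <- max(length(f), length(n_eff), length(L))
  f <- rep_len(f, n); e <- rep_len(n_eff, n)^2; L <- rep_len(L, n)
  s2 <- .ns2_closed(f, e, L)
  bad <- !is.finite(s2) | s2 <= 1
  if (any(bad) && warn)
    warning(sum(bad), " non-physical n_s value(s) (n_s^2 <= 1) set to NA",
            call. = FALSE)
  out <- ifelse(bad, NA_real_, sqrt(pmax(s2, 0)))
  attr(out, "nonphysical") <- bad
  out
}

#' Complex solid permittivity from the complex AB-EMA
#'
#' Solves the full complex AB-EMA (permittivity form) for the solid-phase
#' permittivity \eqn{\tilde\varepsilon_s}. The equation is linear-fractional
#' in \eqn{\tilde\varepsilon_s}, so the solution is closed-form; with a
#' purely real effective permittivity it reduces exactly to
#' [ns_from_neff()] squared. The sign convention is
#' \eqn{\tilde\varepsilon = (n - i\kappa)^2} with \eqn{n > 0},
#' \eqn{\kappa \ge 0}.
#'
#' @param f porosity, < 1.
#' @param eps_eff complex (or real) effective permittivity.
#' @param L depolarisation factor in \[0, 1\].
#' @return complex solid permittivity; `NA` where the linear solve is
#'   degenerate, flagged via attribute `"degenerate"`.
#' @export
eps_s_from_eps_eff <- function(f, eps_eff, L) {
  stopifnot(is.numeric(f), is.numeric(L))
  if (any(f >= 1)) stop("`f` must be strictly below 1", call. = FALSE)
  n <- max(length(f), length(eps_eff), length(L))
  f <- rep_len(f, n); E <- rep_len(as.complex(eps_eff), n); L <- rep_len(L, n)
  A <- f * (1 - E) / (E + L * (1 - E))
  den <- A * L + 1 - f
  bad <- Mod(den) < 1e-300 | !is.finite(Re(den)) | !is.finite(Im(den))
  out <- E - A * E / den
  out[bad] <- NA_complex_
  attr(out, "degenerate") <- bad
  out
}

# Complex refractive index n - i*kappa from a complex permittivity,
# on the branch with positive real part.
.nk_from_eps <- function(eps) {
  r <- sqrt(eps)
  ifelse(Re(r) < 0, -r, r)
}

#' Porosity implied by an effective refractive index
#'
#' The AB-EMA is linear in the porosity for fixed \eqn{n_{eff}},
#' \eqn{n_s} and L, giving the exact closed form used for porosity
#' prediction from a calibrated model.
#'
#' @param n_eff effective refractive index in \[1, n_s\] (vectorised).
#' @param n_s solid refractive index, > 1.
#' @param L depolarisation factor in \[0, 1\].
#' @return porosity fraction; round-trips with [neff_forward()].
#' @export
porosity_from_neff <- function(n_eff, n_s, L) {
  stopifnot(is.numeric(n_eff), is.numeric(n_s), is.numeric(L))
  if (length(n_s) != 1 || n_s <= 1)
    stop("`n_s` must be a single value > 1", call. = FALSE)
  tol <- 1e-9 * n_s
  if (any(n_eff < 1 - tol) || any(n_eff > n_s + tol))
    stop("`n_eff` must lie within [1, n_s]", call. = FALSE)
  e <- pmin(pmax(n_eff, 1), n_s)^2
  s <- n_s^2
  A0 <- (1 - e) / (e + L * (1 - e))
  B <- (s - e) / (e + L * (s - e))
  out <- ifelse(e == s, 0, B / (B - A0))
  pmin(pmax(out, 0), 1)
}

#' Depolarisation factor implied by a single sample
#'
#' The AB-EMA is linear in L for a fixed (porosity, effective index,
#' solid index) triple:
#' \eqn{L = e\,(f + (1-f)s - e) / ((e - 1)(s - e))} with
#' \eqn{e = n_{eff}^2}, \eqn{s = n_s^2}. An effective index at the upper
#' or lower Wiener bound returns exactly 0 or 1; outside the bounds the
#' triple is inconsistent with the model and a domain error is raised.
#'
#' @param n_eff effective refractive index (vectorised).
#' @param n_s solid refractive index, > 1.
#' @param f porosity, 0 < f < 1.
#' @param tol relative tolerance for snapping to the Wiener endpoints.
#' @return depolarisation factor in \[0, 1\].
#' @export
depolarisation_from_sample <- function(n_eff, n_s, f, tol = 1e-9) {
  stopifnot(is.numeric(n_eff), is.numeric(n_s), is.numeric(f))
  if (length(n_s) != 1 || n_s <= 1)
    stop("`n_s` must be a single value > 1", call. = FALSE)
  if (any(f <= 0) || any(f >= 1))
    stop("`f` must lie strictly inside (0, 1)", call. = FALSE)
  n <- max(length(n_eff), length(f))
  e <- rep_len(n_eff, n)^2; f <- rep_len(f, n)
  s <- n_s^2
  lo <- s / (f * s + 1 - f)
  hi <- f + (1 - f) * s
  atol <- tol * s
  if (any(e < lo - atol) || any(e > hi + atol))
    stop("`n_eff` lies outside the Wiener bounds for (f, n_s)",
         call. = FALSE)
  L <- e * (hi - e) / ((e - 1) * (s - e))
  L[e >= hi - atol] <- 0
  L[e <= lo + atol] <- 1
  pmin(pmax(L, 0), 1)
}
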