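# Tablet-geometry porosity, spectral band averaging and CSV/JSON I/O.

#' Porosity of a flat-faced cylindrical tablet
#'
#' \eqn{f = 1 - 4M / (\pi D^2 H \rho_{true})}. Inputs must use a
#' consistent unit system: grams with centimetres, or equivalently
#' milligrams with millimetres, both against a true density in g cm^-3
#' (the mg/mm^3-to-g/cm^3 factors cancel).
#'
#' @param mass tablet mass (g with cm, or mg with mm).
#' @param diameter tablet diameter (cm or mm).
#' @param thickness face-to-face tablet thickness (cm or mm).
#' @param true_density true (fully dense) density of the blend, g cm^-3.
#' @return porosity fraction; values outside \[0, 1) indicate
#'   inconsistent inputs and are flagged via attribute `"inconsistent"`.
#' @examples
#' porosity_flat(0.300, 1.0, 0.30, 1.527)  # g / cm
#' porosity_flat(300, 10, 3.0, 1.527)      # the same tablet in mg / mm
#' @export
porosity_flat <- function(mass, diameter, thickness, true_density) {
  stopifnot(is.numeric(mass), is.numeric(diameter), is.numeric(thickness),
            is.numeric(true_density))
  if (any(mass <= 0) || any(diameter <= 0) || any(thickness <= 0) ||
      any(true_density <= 0))
    stop("all inputs must be strictly positive", call. = FALSE)
  f <- 1 - 4 * mass / (pi * diameter^2 * thickness * true_density)
  bad <- f < 0 | f >= 1
  if (any(bad))
    warning(sum(bad), " porosity value(s) outside [0, 1); ",
            "check input units/consistency", call. = FALSE)
  attr(f, "inconsistent") <- bad
  f
}

#' Porosity of a biconvex tablet
#'
#' The tablet volume is a cylinder of height \eqn{H - 2h} plus two
#' spherical caps of depth h cut from a sphere of curvature radius C,
#' each of volume \eqn{\pi h^2 (3C - h) / 3}:
#' \deqn{f = 1 - M / \{[\tfrac{1}{4}\pi D^2 (H - 2h) +
#'   \tfrac{2}{3}\pi h^2 (3C - h)]\,\rho_{true}\}.}
#' At h = 0 this reduces to [porosity_flat()]. The same unit conventions
#' apply.
#'
#' @inheritParams porosity_flat
#' @param thickness total face-to-face height H including both caps.
#' @param punch_depth cap (punch) depth h; must satisfy H > 2h.
#' @param curvature_radius punch radius of curvature C; must exceed h.
#' @return porosity fraction, flagged as for [porosity_flat()].
#' @export
porosity_biconvex <- function(mass, diameter, thickness, punch_depth,
                              curvature_radius, true_density) {
  stopifnot(is.numeric(punch_depth), is.numeric(curvature_radius))
  if (any(punch_depth < 0)) stop("`punch_depth` must be >= 0", call. = FALSE)
  if (any(thickness <= 2 * punch_depth))
    stop("`thickness` must exceed twice the punch depth", call. = FALSE)
  if (any(punch_depth > 0 & curvature_radius <= punch_depth))
    stop("`curvature_radius` must exceed the punch depth", call. = FALSE)
  if (any(mass <= 0) || any(diameter <= 0) || any(true_density <= 0))
    stop("all inputs must be strictly positive", call. = FALSE)
  vol <- pi * diameter^2 * (thickness - 2 * punch_depth) / 4 +
    2 * pi * punch_depth^2 * (3 * curvature_radius - punch_depth) / 3
  f <- 1 - mass / (vol * true_density)
  bad <- f < 0 | f >= 1
  if (any(bad))
    warning(sum(bad), " porosity value(s) outside [0, 1); ",
            "check input units/consistency", call. = FALSE)
  attr(f, "inconsistent") <- bad
  f
}

#' Band-average an effective refractive index spectrum
#'
#' Arithmetic mean of the effective index over all spectral samples with
#' frequency inside the closed band \[f_lo, f_hi\]. The default band of
#' 0.4-0.8 THz is the range conventionally used for tablet porosity
#' analysis, where most excipients are weakly absorbing.
#'
#' @param spectrum data frame with columns `frequency_THz` and `n_eff`
#'   (e.g. from [read_spectrum()]).
#' @param f_lo,f_hi band edges in THz, both inclusive.
#' @return scalar band-averaged effective index.
#' @export
average_neff_band <- function(spectrum, f_lo = 0.4, f_hi = 0.8) {
  stopifnot(is.data.frame(spectrum),
            all(c("frequency_THz", "n_eff") %in% names(spectrum)))
  sel <- spectrum$frequency_THz >= f_lo & spectrum$frequency_THz <= f_hi
  if (!any(sel))
    stop(sprintf("no spectral samples inside [%g, %g] THz", f_lo, f_hi),
         call. = FALSE)
  mean(spectrum$n_eff[sel])
}

#' Read a spectrum CSV
#'
#' Expected columns: `frequency_THz`, `n_eff` and optionally `alpha_cm`.
#' Frequencies must be strictly increasing.
#'
#' @param path path to a CSV file.
#' @return data frame with the validated columns.
#' @export
read_spectrum <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frequency_THz", "n_eff")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("spectrum file misses column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.unsorted(d$frequency_THz, strictly = TRUE))
    stop("frequencies must be strictly increasing", call. = FALSE)
  d
}

.TABLET_COLS <- c("id", "shape", "mass_mg", "diameter_mm", "thickness_mm",
                  "true_density_g_cm3", "n_eff")

#' Read a tablet table CSV
#'
#' Expected columns: `id`, `shape` (`flat` or `biconvex`), `mass_mg`,
#' `diameter_mm`, `thickness_mm`, `true_density_g_cm3`, `n_eff`, plus
#' `punch_depth_mm` and `curvature_radius_mm` for biconvex rows and an
#' optional precomputed `porosity`. Porosity is derived from the geometry
#' when absent. Malformed rows are reported with their line numbers.
#'
#' @param path path to a CSV file (comma separated, dot decimal, header
#'   row mandatory).
#' @return data frame of validated records with a `porosity` column.
#' @export
read_tablet_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.TABLET_COLS, names(d))
  if (length(miss))
    stop("tablet table misses column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  line <- seq_len(nrow(d)) + 1L   # header is line 1
  problems <- character(0)
  note <- function(i, msg)
    problems <<- c(problems, sprintf("line %d (%s): %s", line[i],
                                     as.character(d$id[i]), msg))
  num_cols <- c("mass_mg", "diameter_mm", "thickness_mm",
                "true_density_g_cm3", "n_eff")
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(d[[cl]]))
    for (i in which(is.na(v))) note(i, paste("non-numeric", cl))
    for (i in which(!is.na(v) & v <= 0)) note(i, paste("non-positive", cl))
    d[[cl]] <- v
  }
  bad_shape <- !(d$shape %in% c("flat", "biconvex"))
  for (i in which(bad_shape)) note(i, "shape must be 'flat' or 'biconvex'")
  bic <- d$shape == "biconvex" & !bad_shape
  for (cl in c("punch_depth_mm", "curvature_radius_mm")) {
    if (!cl %in% names(d)) d[[cl]] <- NA_real_
    d[[cl]] <- suppressWarnings(as.numeric(d[[cl]]))
    for (i in which(bic & (is.na(d[[cl]]) | d[[cl]] <= 0)))
      note(i, paste("biconvex row needs positive", cl))
  }
  if (length(problems))
    stop("malformed tablet table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  if (!"porosity" %in% names(d)) d$porosity <- NA_real_
  needs <- is.na(d$porosity)
  flat <- needs & d$shape == "flat"
  if (any(flat))
    d$porosity[flat] <- as.numeric(porosity_flat(
      d$mass_mg[flat], d$diameter_mm[flat], d$thickness_mm[flat],
      d$true_density_g_cm3[flat]))
  bicn <- needs & d$shape == "biconvex"
  if (any(bicn))
    d$porosity[bicn] <- as.numeric(porosity_biconvex(
      d$mass_mg[bicn], d$diameter_mm[bicn], d$thickness_mm[bicn],
      d$punch_depth_mm[bicn], d$curvature_radius_mm[bicn],
      d$true_density_g_cm3[bicn]))
  if (any(d$porosity < 0 | d$porosity >= 1))
    stop("computed porosity outside [0, 1); inconsistent geometry/mass",
         call. = FALSE)
  d
}

#' Write a tablet table CSV
#'
#' Inverse of [read_tablet_table()]; values survive a write/read round
#' trip to better than 1e-9.
#'
#' @param records data frame of tablet records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tablet_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a tablet set from a tablet table
#'
#' @param records data frame from [read_tablet_table()].
#' @param material label for the resulting set.
#' @return a [tablet_set()].
#' @export
tablet_set_from_table <- function(records, material = "") {
  tablet_set(records$porosity, records$n_eff, material = material,
             label = records$id)
}

#' Write an analysis result to disk
#'
#' Fit results are serialised to JSON; depolarisation-bound results to
#' CSV (columns `f`, `L_l`, `L_u`) with the validity information, when
#' present, in a JSON sidecar; plain data frames to CSV.
#'
#' @param x an `abema_fit`, `l_bounds`, `abema_validity` or data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) UseMethod("write_report")

#' @export
write_report.abema_fit <- function(x, path) {
  out <- list(model_kind = x$model_kind, ns_fit = x$ns_fit,
              L_fit = x$L_fit, coef = as.list(x$coef),
              objective = x$objective, adj_r2 = x$adj_r2,
              rmse_f_percent = x$rmse_f_percent, failed = x$failed,
              per_sample = x$per_sample)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @export
write_report.l_bounds <- function(x, path) {
  utils::write.csv(x$table[, c("f", "L_l", "L_u")], path, row.names = FALSE)
  invisible(path)
}

#' @export
write_report.abema_validity <- function(x, path) {
  out <- list(valid = x$valid, violations = x$violations,
              steep_tangent = x$steep_tangent,
              tangent_threshold = x$tangent_threshold, table = x$table)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @export
write_report.data.frame <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
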