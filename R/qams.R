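# Single-marker quantification (QAMS): relative correction factors,
# relative retention times, external-standard calibration, content
# conversion, method agreement and recovery.

#' Relative correction factor
#'
#' `f = (A_s/C_s) / (A_i/C_i)`: the ratio of the internal standard's
#' response factor to the analyte's, estimated from a paired observation
#' of both compounds at known concentrations.
#'
#' @param a_s,c_s Peak area and concentration (mg/mL) of the internal
#'   standard.
#' @param a_i,c_i Peak area and concentration (mg/mL) of the analyte.
#' @return The relative correction factor (dimensionless, > 0).
#' @export
correction_factor <- function(a_s, c_s, a_i, c_i) {
  if (any(c(a_s, c_s, a_i, c_i) <= 0)) {
    stop("areas and concentrations must be strictly positive", call. = FALSE)
  }
  (a_s / c_s) / (a_i / c_i)
}

#' Aggregate per-condition values into mean and RSD
#'
#' @param values Numeric vector of per-condition values (length >= 2 for
#'   an RSD; a single value returns RSD `NA`).
#' @return List with `mean` and `rsd_pct` (`100 * sd / mean`, n-1
#'   denominator).
#' @export
aggregate_conditions <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to aggregate", call. = FALSE)
  m <- mean(values)
  list(mean = m,
       rsd_pct = if (length(values) >= 2L) 100 * stats::sd(values) / m
                 else NA_real_)
}

#' Fit an external-standard calibration line
#'
#' Ordinary least squares of area on concentration with free intercept.
#'
#' @param concentration Standard concentrations (mg/mL), at least two
#'   distinct values.
#' @param area Corresponding peak areas.
#' @return Object of class `calibration_curve`: list with `slope`,
#'   `intercept`, `r_squared` and the calibrated `range` of
#'   concentrations.
#' @export
fit_calibration <- function(concentration, area) {
  stopifnot(length(concentration) == length(area), length(concentration) >= 2L)
  if (length(unique(concentration)) < 2L) {
    stop("calibration needs at least two distinct concentrations",
         call. = FALSE)
  }
  fit <- stats::lm(area ~ concentration)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((area - mean(area))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 range = range(concentration),
                 n = length(concentration)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> area = %.6g * conc %+.6g, r^2 = %.6f (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Extraction stoichiometry
#'
#' Sample mass extracted into a known solvent volume; defaults follow
#' the analysed material's preparation (0.2 g of dried leaf in 25 mL of
#' 70% methanol, with solvent loss compensated).
#'
#' @param sample_mass_g Sample mass in g.
#' @param extract_volume_ml Extract volume in mL.
#' @return List used by the `quantify_*` functions.
#' @export
extraction_spec <- function(sample_mass_g = 0.2, extract_volume_ml = 25) {
  stopifnot(sample_mass_g > 0, extract_volume_ml > 0)
  list(sample_mass_g = sample_mass_g, extract_volume_ml = extract_volume_ml)
}

.to_mg_per_g <- function(conc_mg_ml, ext) {
  conc_mg_ml * ext$extract_volume_ml / ext$sample_mass_g
}

#' Quantify by the external standard method
#'
#' Inverts the calibration line (`C = (A - intercept)/slope`) and
#' converts the extract concentration to content per g of material.
#' Negative inverse predictions are clipped to zero with a warning;
#' areas outside the calibrated response range warn but are still
#' inverted.
#'
#' @param area Analyte peak area(s).
#' @param curve A [fit_calibration()] curve.
#' @param ext An [extraction_spec()].
#' @return Content in mg/g.
#' @export
quantify_esm <- function(area, curve, ext = extraction_spec()) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("calibration slope is zero", call. = FALSE)
  resp_range <- curve$intercept + curve$slope * curve$range
  if (any(area < min(resp_range) | area > max(resp_range))) {
    warning("area outside the calibrated response range", call. = FALSE)
  }
  conc <- (area - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warning("negative inverse prediction clipped to zero", call. = FALSE)
    conc <- pmax(conc, 0)
  }
  .to_mg_per_g(conc, ext)
}

#' Quantify by the single-marker method (QAMS)
#'
#' `C_i = f * C_s * A_i / A_s`, with the internal standard concentration
#' `C_s` taken from its own calibration, then converted to mg/g.
#'
#' @param a_i Analyte peak area(s).
#' @param a_s Internal standard peak area (> 0).
#' @param c_s Internal standard concentration in the extract (mg/mL).
#' @param f Relative correction factor of the analyte (> 0).
#' @param ext An [extraction_spec()].
#' @return Content in mg/g.
#' @export
quantify_qams <- function(a_i, a_s, c_s, f, ext = extraction_spec()) {
  if (a_s <= 0) stop("internal standard area must be positive", call. = FALSE)
  if (f <= 0) stop("correction factor must be positive", call. = FALSE)
  .to_mg_per_g(f * c_s * a_i / a_s, ext)
}

#' Identify analyte peaks by relative retention time
#'
#' Assigns each template analyte the detected peak with the nearest
#' relative retention time, accepting the match only when the relative
#' deviation is within tolerance. Raises an error when two template
#' analytes claim the same observed peak.
#'
#' @param rrt Named numeric vector of observed peak RRTs (names are peak
#'   identifiers).
#' @param template Named numeric vector of expected analyte RRTs.
#' @param tolerance Maximum relative RRT deviation (default 0.02).
#' @return Data frame with `analyte`, `peak`, `rrt_observed`,
#'   `rrt_expected`, `rel_dev`; unassigned analytes have `peak` `NA`.
#' @export
identify_by_rrt <- function(rrt, template, tolerance = 0.02) {
  stopifnot(length(rrt) > 0L, length(template) > 0L,
            !is.null(names(rrt)), !is.null(names(template)))
  rows <- lapply(names(template), function(analyte) {
    expect <- template[[analyte]]
    rel_dev <- abs(rrt - expect) / expect
    i <- which.min(rel_dev)
    if (rel_dev[i] <= tolerance) {
      data.frame(analyte = analyte, peak = names(rrt)[i],
                 rrt_observed = unname(rrt[i]), rrt_expected = expect,
                 rel_dev = unname(rel_dev[i]), stringsAsFactors = FALSE)
    } else {
      data.frame(analyte = analyte, peak = NA_character_,
                 rrt_observed = NA_real_, rrt_expected = expect,
                 rel_dev = NA_real_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  assigned <- out$peak[!is.na(out$peak)]
  dup <- assigned[duplicated(assigned)]
  if (length(dup) > 0L) {
    claimants <- out$analyte[!is.na(out$peak) & out$peak %in% dup]
    stop("ambiguous RRT assignment: peak(s) ",
         paste(unique(dup), collapse = ", "), " claimed by ",
         paste(claimants, collapse = ", "), call. = FALSE)
  }
  out
}

#' Relative deviation between two concentration estimates
#'
#' The method-agreement metric between external-standard and
#' single-marker results: `RD% = |c1 - c2| / (c1 + c2) * 100`. The
#' conventional form relative to the first estimate
#' (`|c1 - c2| / c1 * 100`) is available via `method`.
#'
#' @param c_esm,c_qams Concentrations (mg/g); their sum must be > 0.
#' @param method `"sum"` (default) or `"reference"`.
#' @return Relative deviation in percent.
#' @export
relative_deviation <- function(c_esm, c_qams, method = c("sum", "reference")) {
  method <- match.arg(method)
  if (any(c_esm + c_qams <= 0)) {
    stop("relative deviation undefined for a zero pair", call. = FALSE)
  }
  if (method == "sum") {
    100 * abs(c_esm - c_qams) / (c_esm + c_qams)
  } else {
    100 * abs(c_esm - c_qams) / c_esm
  }
}

#' Mean content per region and analyte
#'
#' @param results Data frame with columns `region`, `compound` and a
#'   value column (default `esm_mg_g`).
#' @param value Name of the value column to average.
#' @return Data frame with `region`, `compound`, `mean_mg_g`, `n`.
#' @export
summarize_by_region <- function(results, value = "esm_mg_g") {
  stopifnot(all(c("region", "compound", value) %in% names(results)))
  keep <- !is.na(results[[value]])
  if (!any(keep)) stop("no values to summarize", call. = FALSE)
  results <- results[keep, , drop = FALSE]
  agg <- stats::aggregate(results[[value]],
                          by = list(region = results$region,
                                    compound = results$compound),
                          FUN = mean)
  n <- stats::aggregate(results[[value]],
                        by = list(region = results$region,
                                  compound = results$compound),
                        FUN = length)
  out <- data.frame(region = agg$region, compound = agg$compound,
                    mean_mg_g = agg$x, n = n$x, stringsAsFactors = FALSE)
  out[order(out$compound, out$region), , drop = FALSE]
}

#' Per-batch total content
#'
#' Sums the analyte concentrations per batch, excluding the internal
#' standard (the published totals cover the seven analytes only).
#'
#' @param results Long data frame with `batch`, `compound` and a value
#'   column.
#' @param value Name of the value column.
#' @param exclude Compounds excluded from the total (default the
#'   internal standard and any pre-computed `total` rows).
#' @return Data frame with `batch` and `total`.
#' @export
total_content <- function(results, value = "esm_mg_g",
                          exclude = c("isochlorogenic_acid_C", "total")) {
  stopifnot(all(c("batch", "compound", value) %in% names(results)))
  keep <- !(results$compound %in% exclude) & !is.na(results[[value]])
  agg <- stats::aggregate(results[[value]][keep],
                          by = list(batch = results$batch[keep]), FUN = sum)
  data.frame(batch = agg$batch, total = agg$x, stringsAsFactors = FALSE)
}

#' Spike recovery
#'
#' `100 * (measured_spiked - measured_base) / added`.
#'
#' @param measured_spiked,measured_base Measured amounts (mg) with and
#'   without the spike.
#' @param added Spiked amount (mg, > 0).
#' @return Recovery in percent.
#' @export
spike_recovery <- function(measured_spiked, measured_base, added) {
  if (any(added <= 0)) stop("spiked amount must be positive", call. = FALSE)
  100 * (measured_spiked - measured_base) / added
}
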