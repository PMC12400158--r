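# Accessors for the packaged reference tables: per-condition relative
# correction factors, per-condition relative retention times, and the
# 18-batch ESM/QAMS concentration table.

.read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "herbqc")
  stopifnot(nchar(path) > 0L)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.pivot_conditions <- function(df) {
  analytes <- setdiff(names(df), c("factor", "level"))
  out <- do.call(rbind, lapply(analytes, function(a) {
    data.frame(factor = df$factor, level = df$level, analyte = a,
               value = df[[a]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Published per-condition relative correction factors
#'
#' The 19 validation conditions (7 multi-point correction levels, 3
#' column batches, 3 instruments, 3 column temperatures, 3 flow rates)
#' with the relative correction factor f of each analyte against the
#' isochlorogenic acid C internal standard.
#'
#' @param long If `TRUE`, return a long data frame with columns
#'   `factor`, `level`, `analyte`, `value`; otherwise the printed wide
#'   layout (one column per analyte).
#' @return Data frame of correction factors.
#' @export
aaf_correction_factors <- function(long = FALSE) {
  df <- .read_extdata("aaf_correction_factors.csv")
  if (long) .pivot_conditions(df) else df
}

#' Published per-condition relative retention times
#'
#' Same 19 validation conditions as [aaf_correction_factors()], holding
#' the relative retention time (analyte retention time over internal
#' standard retention time) of each analyte.
#'
#' @inheritParams aaf_correction_factors
#' @return Data frame of relative retention times.
#' @export
aaf_relative_retention <- function(long = FALSE) {
  df <- .read_extdata("aaf_relative_retention.csv")
  if (long) .pivot_conditions(df) else df
}

#' Published 18-batch ESM/QAMS quantification table
#'
#' Concentrations (mg per g of dried leaf) of the internal standard and
#' seven analytes in 18 batches from two production regions (`HN`
#' Henan, `HB` Hubei), determined by the external standard method (ESM)
#' and by single-marker quantification (QAMS), with the printed relative
#' deviation between the two. `compound == "total"` rows carry the
#' printed per-batch totals over the seven analytes; the internal
#' standard rows have no QAMS value.
#'
#' @param include_totals Keep the `total` rows (default `TRUE`).
#' @return Long data frame with columns `batch`, `region`, `compound`,
#'   `esm_mg_g`, `qams_mg_g`, `rd_pct`.
#' @export
aaf_batch_quantification <- function(include_totals = TRUE) {
  df <- .read_extdata("aaf_batch_quantification.csv")
  if (!include_totals) df <- df[df$compound != "total", , drop = FALSE]
  df
}
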