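# Readers/writers for the pipeline's CSV formats, configuration
# validation and the umbrella pipeline runner.

#' Write a peak table to CSV
#'
#' Layout: header `batch_id`, `region`, then one column per common peak.
#'
#' @param ptable A [peak_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(ptable, path) {
  stopifnot(inherits(ptable, "peak_table"))
  df <- data.frame(batch_id = ptable$batch_ids, region = ptable$regions,
                   ptable$areas, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a peak table from CSV
#'
#' Strict validation: every common-peak cell must be present and
#' non-negative; offending cells are reported by batch and peak label.
#'
#' @param path CSV path with columns `batch_id`, `region`, then peak
#'   columns.
#' @param reference_peak Label of the reference peak (default `"11"`).
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path, reference_peak = "11") {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("batch_id", "region")
  if (!all(need %in% names(df))) {
    stop("peak table CSV must have columns batch_id, region", call. = FALSE)
  }
  peak_cols <- setdiff(names(df), need)
  if (length(peak_cols) == 0L) stop("no peak columns found", call. = FALSE)
  areas <- vapply(df[peak_cols],
                  function(col) suppressWarnings(as.numeric(col)),
                  numeric(nrow(df)))
  areas <- matrix(areas, nrow = nrow(df),
                  dimnames = list(NULL, peak_cols))
  bad <- which(is.na(areas) | areas < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("invalid area for batch '", df$batch_id[bad[1, 1]],
         "', peak '", peak_cols[bad[1, 2]], "' (missing or negative)",
         call. = FALSE)
  }
  peak_table(areas, df$batch_id, peak_cols, regions = df$region,
             reference_peak = reference_peak)
}

#' Write a chromatogram as two-column CSV
#'
#' @param chrom A [chromatogram()].
#' @param path Output path (`time_min`, `intensity`).
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  utils::write.csv(data.frame(time_min = chrom$times,
                              intensity = chrom$intensities),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a chromatogram from two-column CSV
#'
#' @param path CSV path with columns `time_min`, `intensity`.
#' @param batch_id Optional batch label to attach.
#' @return A [chromatogram()].
#' @export
read_chromatogram <- function(path, batch_id = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_min", "intensity") %in% names(df))) {
    stop("chromatogram CSV must have columns time_min, intensity",
         call. = FALSE)
  }
  chromatogram(df$time_min, df$intensity, batch_id = batch_id)
}

#' Validated pipeline configuration
#'
#' Unknown keys are rejected; every stage reads its parameters from
#' here.
#'
#' @param seed Master seed for all stochastic stages.
#' @param n_per_region Batches per region.
#' @param bio_cv Between-batch CV of the planted contents.
#' @param noise_cv Analytic CV of the simulated areas.
#' @param scaling Chemometric scaling (see [preprocess()]).
#' @param n_orthogonal Orthogonal OPLS-DA components.
#' @param cv_folds Cross-validation folds.
#' @param n_perm Label permutations.
#' @param internal_standard Peak id of the internal standard.
#' @param rrt_tolerance Relative RRT matching tolerance.
#' @param ... Rejected; present so misspelled keys fail loudly.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 0, n_per_region = 9, bio_cv = 0.08,
                            noise_cv = 0.05, scaling = "autoscale",
                            n_orthogonal = 1, cv_folds = 7, n_perm = 200,
                            internal_standard = "11",
                            rrt_tolerance = 0.02, ...) {
  extra <- list(...)
  if (length(extra) > 0L) {
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  }
  info <- default_peak_info()
  if (!internal_standard %in% info$peak_id) {
    stop("internal_standard must be one of the common peak ids",
         call. = FALSE)
  }
  structure(list(seed = seed, n_per_region = n_per_region,
                 bio_cv = bio_cv, noise_cv = noise_cv, scaling = scaling,
                 n_orthogonal = n_orthogonal, cv_folds = cv_folds,
                 n_perm = n_perm, internal_standard = internal_standard,
                 rrt_tolerance = rrt_tolerance),
            class = "pipeline_config")
}

.log_line <- function(con, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
  writeLines(line, con)
  message(line)
}

#' Run the full pipeline on synthetic data
#'
#' Simulate -> fingerprint (detect, match, QC) -> chemometrics (PCA,
#' OPLS-DA, VIP, permutation, markers) -> QAMS (calibration, f, ESM vs
#' QAMS, region summary), writing every intermediate CSV and a run log
#' under `out_dir`. Reruns with the same configuration reproduce
#' identical tables.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named list of the written file paths plus the
#'   fitted models.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  con <- file(log_path, "w")
  on.exit(close(con))
  .log_line(con, "pipeline start; seed=", config$seed)

  # --- simulate ------------------------------------------------------
  sim <- simulate_batch_set(default_region_effects(cv = config$bio_cv),
                            n_per_region = config$n_per_region,
                            noise_cv = config$noise_cv,
                            seed = config$seed)
  write_peak_table(sim$table, file.path(out_dir, "peak_table_true.csv"))
  utils::write.csv(sim$truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  .log_line(con, "simulated ", length(sim$table$batch_ids), " batches x ",
            length(sim$table$peak_ids), " peaks")

  # --- fingerprint ---------------------------------------------------
  template <- chrom_template()
  match_template <- rrt_template(
    stats::setNames(default_peak_info()$rrt, default_peak_info()$peak_id),
    reference_peak = config$internal_standard,
    reference_time = template$retention_times[
      match(config$internal_standard, template$peak_ids)],
    tolerance = config$rrt_tolerance)
  peaks_per_batch <- list()
  for (b in sim$table$batch_ids) {
    tb <- sim$truth[sim$truth$batch == b, , drop = FALSE]
    chrom <- simulate_chromatogram(tb, template)
    peaks_per_batch[[b]] <- detect_peaks(chrom, min_height = 1)
  }
  regions <- stats::setNames(sim$table$regions, sim$table$batch_ids)
  matched <- match_peaks(peaks_per_batch, match_template, regions = regions)
  if (nrow(attr(matched, "unmatched")) > 0L) {
    .log_line(con, "WARNING: ", nrow(attr(matched, "unmatched")),
              " unmatched (batch, peak) pairs")
  }
  write_peak_table(matched, file.path(out_dir, "peak_table_matched.csv"))
  sim_scores <- similarity_to_mean(matched)
  utils::write.csv(data.frame(batch = names(sim_scores),
                              similarity = sim_scores),
                   file.path(out_dir, "similarity.csv"), row.names = FALSE)
  .log_line(con, "matched common peaks; min similarity ",
            sprintf("%.4f", min(sim_scores)))

  # --- chemometrics --------------------------------------------------
  X <- preprocess(matched, scaling = config$scaling)
  pca <- pca_fit(X, n_components = 2)
  opls <- oplsda(X, matched$regions, n_orthogonal = config$n_orthogonal,
                 cv_folds = config$cv_folds)
  perm <- permutation_test(X, matched$regions, n_perm = config$n_perm,
                           seed = config$seed,
                           n_orthogonal = config$n_orthogonal,
                           cv_folds = config$cv_folds)
  markers <- select_markers(matched, opls)
  utils::write.csv(data.frame(batch = rownames(pca$scores), pca$scores),
                   file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
  utils::write.csv(s_plot(opls, X), file.path(out_dir, "s_plot.csv"),
                   row.names = FALSE)
  utils::write.csv(markers, file.path(out_dir, "markers.csv"),
                   row.names = FALSE)
  utils::write.csv(perm$permutations,
                   file.path(out_dir, "permutations.csv"),
                   row.names = FALSE)
  .log_line(con, sprintf(
    "OPLS-DA R2X=%.3f R2Y=%.3f Q2=%.3f; %d marker(s); perm intercepts R2=%.3f Q2=%.3f",
    opls$R2X_cum, opls$R2Y, opls$Q2, sum(markers$selected),
    perm$r2_intercept, perm$q2_intercept))

  # --- QAMS ----------------------------------------------------------
  qams <- qams_analysis(matched, seed = config$seed,
                        internal_standard = config$internal_standard)
  utils::write.csv(qams$results, file.path(out_dir, "qams_results.csv"),
                   row.names = FALSE)
  utils::write.csv(qams$region_summary,
                   file.path(out_dir, "qams_region_summary.csv"),
                   row.names = FALSE)
  .log_line(con, sprintf("QAMS max RD %.4f%%", max(qams$results$rd_pct)))
  .log_line(con, "pipeline done")
  invisible(list(dir = out_dir, table = matched, pca = pca, opls = opls,
                 permutation = perm, markers = markers, qams = qams))
}

#' ESM and QAMS quantification of a matched peak table
#'
#' Builds noise-free calibration curves for the eight quantified
#' compounds, derives each analyte's relative correction factor from the
#' calibration responses, quantifies every batch by both the external
#' standard method and the single-marker method, and reports the
#' relative deviation between the two.
#'
#' @param ptable A matched [peak_table()].
#' @param seed Seed for the calibration simulation.
#' @param internal_standard Peak id of the internal standard (default
#'   `"11"`, isochlorogenic acid C).
#' @param calib_noise_cv Analytic CV of the calibration areas (default
#'   0: exact curves).
#' @param ext [extraction_spec()].
#' @return List with `results` (long data frame `batch`, `region`,
#'   `compound`, `esm_mg_g`, `qams_mg_g`, `rd_pct`), `curves`,
#'   `correction_factors` and `region_summary`.
#' @export
qams_analysis <- function(ptable, seed = 0, internal_standard = "11",
                          calib_noise_cv = 0, ext = extraction_spec()) {
  stopifnot(inherits(ptable, "peak_table"))
  info <- default_peak_info()
  quant_peaks <- c("1", "2", "3", "4", "8", "15", "17")
  stopifnot(internal_standard %in% ptable$peak_ids,
            all(quant_peaks %in% ptable$peak_ids))
  compound_of <- stats::setNames(info$compound, info$peak_id)
  # calibration curves (one per quantified compound, incl. the standard)
  curves <- list()
  fs <- numeric(0)
  for (p in c(internal_standard, quant_peaks)) {
    cal <- simulate_calibration(compound_of[[p]], noise_cv = calib_noise_cv,
                                seed = seed + as.integer(p))
    curves[[p]] <- fit_calibration(cal$concentration, cal$area)
  }
  is_curve <- curves[[internal_standard]]
  for (p in quant_peaks) {
    # f from the calibration responses at each shared level
    f_lv <- (is_curve$slope) / (curves[[p]]$slope)
    fs[p] <- f_lv
  }
  rows <- list()
  for (b in ptable$batch_ids) {
    a_s <- ptable$areas[b, internal_standard]
    c_s <- (a_s - is_curve$intercept) / is_curve$slope
    for (p in quant_peaks) {
      a_i <- ptable$areas[b, p]
      esm <- quantify_esm(a_i, curves[[p]], ext)
      qams <- quantify_qams(a_i, a_s, c_s, fs[[p]], ext)
      rows[[length(rows) + 1L]] <- data.frame(
        batch = b, region = ptable$regions[match(b, ptable$batch_ids)],
        compound = compound_of[[p]], esm_mg_g = esm, qams_mg_g = qams,
        rd_pct = relative_deviation(esm, qams), stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  list(results = results, curves = curves, correction_factors = fs,
       region_summary = summarize_by_region(results))
}
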