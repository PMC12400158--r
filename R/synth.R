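# Synthetic-data generation: batch peak tables with planted region
# effects, chromatograms, calibration series and MS2 spectra. The
# defaults emulate the study material: 18 batches of dried mugwort leaf
# (9 from Henan "HN", 9 from Hubei "HB"), 18 common fingerprint peaks,
# isochlorogenic acid C as reference/internal standard, and seven
# marker compounds with region-dependent abundance.

# lognormal multiplicative factor with unit mean and given CV
.lnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Default common-peak roster
#'
#' One row per common fingerprint peak (1-18 in elution order):
#' compound name, template relative retention time (reference peak 11,
#' isochlorogenic acid C, at RRT 1), detector response factor (area per
#' mg/mL of extract), default region mean contents (mg/g) and whether
#' the peak is one of the seven planted region markers (peaks 2, 8, 9,
#' 10, 11, 12, 17). Published per-condition mean RRTs and mean contents
#' are used where available; the remaining RRTs are interpolated along
#' the elution order and the remaining means are representative values.
#' Response factors of the eight quantified compounds are set so that
#' relative correction factors against the internal standard land at the
#' published magnitudes (0.6-1.3).
#'
#' @return Data frame with columns `peak_id`, `compound`, `rrt`,
#'   `response_factor`, `mean_HN`, `mean_HB`, `marker`.
#' @export
default_peak_info <- function() {
  data.frame(
    peak_id = as.character(1:18),
    compound = c("neochlorogenic_acid", "chlorogenic_acid",
                 "cryptochlorogenic_acid", "caffeic_acid", "schaftoside",
                 "neoschaftoside", "rutin", "isochlorogenic_acid_B",
                 "dicaffeoylquinic_acid_1_5", "isochlorogenic_acid_A",
                 "isochlorogenic_acid_C", "tricaffeoylquinic_acid_3_4_5",
                 "apigenin", "diosmetin", "jaceosidin", "centaureidin",
                 "eupatilin", "pectolinarigenin"),
    rrt = c(0.219, 0.348, 0.397, 0.454, 0.550, 0.620, 0.700, 0.891,
            0.930, 0.960, 1.000, 1.080, 1.170, 1.280, 1.390, 1.470,
            1.554, 1.630),
    response_factor = c(1000 / 1.222, 1000 / 1.178, 1000 / 1.272,
                        1000 / 0.667, 900, 880, 1100, 1000 / 1.006,
                        950, 980, 1000, 920, 1200, 1150, 1000 / 1.165,
                        1050, 1000 / 1.053, 1000),
    mean_HN = c(0.402, 2.2012, 0.4136, 0.0848, 0.60, 0.40, 0.80, 2.20,
                1.10, 1.60, 3.4368, 0.50, 0.30, 0.25, 0.5926, 0.35,
                1.053, 0.45),
    mean_HB = c(0.402, 1.2302, 0.4136, 0.0848, 0.60, 0.40, 0.80, 1.35,
                0.65, 0.90, 2.6914, 1.00, 0.30, 0.25, 0.5926, 0.35,
                1.997, 0.45),
    marker = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
               TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
               TRUE, FALSE),
    stringsAsFactors = FALSE)
}

#' Region-effect specification for one compound
#'
#' @param compound_id Compound (or peak) label.
#' @param region_means Named numeric vector: mean content (mg/g) per
#'   region, strictly positive.
#' @param cv Between-batch relative standard deviation within a region
#'   (fraction, >= 0).
#' @param distribution Only `"lognormal"` is implemented.
#' @return Object of class `region_effect_spec`.
#' @export
region_effect_spec <- function(compound_id, region_means, cv = 0.08,
                               distribution = "lognormal") {
  stopifnot(is.numeric(region_means), length(region_means) >= 1L,
            !is.null(names(region_means)), all(region_means > 0),
            cv >= 0, identical(distribution, "lognormal"))
  structure(list(compound_id = compound_id, region_means = region_means,
                 cv = cv, distribution = distribution),
            class = "region_effect_spec")
}

#' Default region-effect specifications
#'
#' One [region_effect_spec()] per common peak, with the
#' [default_peak_info()] region means and a common between-batch CV.
#'
#' @param cv Between-batch CV within a region (default 0.08).
#' @return Named list of `region_effect_spec` objects (names are peak
#'   ids).
#' @export
default_region_effects <- function(cv = 0.08) {
  info <- default_peak_info()
  specs <- lapply(seq_len(nrow(info)), function(i) {
    region_effect_spec(info$compound[i],
                       c(HN = info$mean_HN[i], HB = info$mean_HB[i]),
                       cv = cv)
  })
  names(specs) <- info$peak_id
  specs
}

#' Simulate a multi-batch common-peak area table
#'
#' Draws per-batch true contents from each compound's region-dependent
#' lognormal distribution, converts them to extract concentrations via
#' the extraction stoichiometry, and maps them to areas through fixed
#' per-compound response factors with multiplicative lognormal analytic
#' noise. Identical seeds give identical output.
#'
#' @param spec Named list of [region_effect_spec()] objects keyed by
#'   peak id (default [default_region_effects()]); all specs must cover
#'   the same regions.
#' @param n_per_region Batches per region (>= 2, default 9).
#' @param noise_cv Analytic CV of the area noise (default 0.05).
#' @param seed Integer seed (default 0).
#' @param ext [extraction_spec()] used for the mg/g to mg/mL conversion.
#' @return List with `table` (a [peak_table()]) and `truth` (long data
#'   frame `batch`, `region`, `peak_id`, `compound`, `true_mg_g`).
#' @export
simulate_batch_set <- function(spec = default_region_effects(),
                               n_per_region = 9, noise_cv = 0.05,
                               seed = 0, ext = extraction_spec()) {
  stopifnot(n_per_region >= 2, noise_cv >= 0, length(spec) > 0L,
            !is.null(names(spec)))
  info <- default_peak_info()
  regions <- names(spec[[1]]$region_means)
  for (s in spec) {
    if (!identical(names(s$region_means), regions)) {
      stop("all region_effect_specs must cover the same regions",
           call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  batch_ids <- unlist(lapply(regions, function(r) {
    paste0(r, seq_len(n_per_region))
  }))
  batch_regions <- rep(regions, each = n_per_region)
  peak_ids <- names(spec)
  rf <- stats::setNames(info$response_factor, info$peak_id)
  areas <- matrix(NA_real_, length(batch_ids), length(peak_ids),
                  dimnames = list(batch_ids, peak_ids))
  truth <- list()
  for (p in peak_ids) {
    s <- spec[[p]]
    mu <- s$region_means[batch_regions]
    conc <- mu * .lnoise(length(mu), s$cv)
    resp <- if (p %in% names(rf)) rf[[p]] else 1000
    extract_conc <- conc * ext$sample_mass_g / ext$extract_volume_ml
    areas[, p] <- extract_conc * resp * .lnoise(length(mu), noise_cv)
    truth[[p]] <- data.frame(batch = batch_ids, region = batch_regions,
                             peak_id = p, compound = s$compound_id,
                             true_mg_g = conc, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(table = peak_table(areas, batch_ids, peak_ids,
                          regions = batch_regions,
                          reference_peak = "11"),
       truth = truth)
}

#' Chromatogram simulation template
#'
#' @param peak_ids Ordered peak labels.
#' @param retention_times Apex times in minutes, strictly increasing.
#' @param reference_peak Label of the reference peak (must be in
#'   `peak_ids`).
#' @param peak_width_sigma Gaussian peak sigma in minutes (> 0).
#' @param baseline_level Flat baseline intensity.
#' @param tailing Fractional broadening of the trailing flank (0 gives a
#'   symmetric Gaussian; 0.2 gives a visibly tailing peak).
#' @return Object of class `chrom_template`.
#' @export
chrom_template <- function(peak_ids = default_peak_info()$peak_id,
                           retention_times = default_peak_info()$rrt * 12,
                           reference_peak = "11",
                           peak_width_sigma = 0.05,
                           baseline_level = 5,
                           tailing = 0) {
  stopifnot(length(peak_ids) == length(retention_times),
            all(diff(retention_times) > 0),
            reference_peak %in% peak_ids,
            peak_width_sigma > 0, tailing >= 0)
  structure(list(peak_ids = as.character(peak_ids),
                 retention_times = retention_times,
                 reference_peak = reference_peak,
                 peak_width_sigma = peak_width_sigma,
                 baseline_level = baseline_level,
                 tailing = tailing),
            class = "chrom_template")
}

#' Simulate an HPLC-UV chromatogram for one batch
#'
#' Sums (optionally tailing) Gaussian peaks on a flat baseline. Peak
#' areas are the batch's true contents mapped through the same response
#' factors as [simulate_batch_set()], so detection, matching and
#' quantification close the loop on the ground truth.
#'
#' @param truth Data frame for one batch as produced in the `truth`
#'   component of [simulate_batch_set()] (columns `peak_id`,
#'   `true_mg_g`; zero rows give a flat baseline).
#' @param template A [chrom_template()].
#' @param noise_sd Additive Gaussian detector noise SD (default 0).
#' @param step Sampling step in minutes; must be < sigma/5 (default
#'   sigma/10).
#' @param seed Seed for the detector noise.
#' @param ext [extraction_spec()] for the content-to-concentration
#'   conversion.
#' @return A [chromatogram()].
#' @export
simulate_chromatogram <- function(truth, template, noise_sd = 0,
                                  step = NULL, seed = 0,
                                  ext = extraction_spec()) {
  stopifnot(inherits(template, "chrom_template"))
  sigma <- template$peak_width_sigma
  if (is.null(step)) step <- sigma / 10
  if (step >= sigma / 5) {
    stop("sampling step must be finer than sigma/5 to resolve peaks",
         call. = FALSE)
  }
  info <- default_peak_info()
  rf <- stats::setNames(info$response_factor, info$peak_id)
  t_max <- max(template$retention_times) + 20 * sigma
  times <- seq(0, t_max, by = step)
  y <- rep(template$baseline_level, length(times))
  sig_l <- sigma
  sig_r <- sigma * (1 + template$tailing)
  if (nrow(truth) > 0L) {
    stopifnot(all(truth$peak_id %in% template$peak_ids))
    for (k in seq_len(nrow(truth))) {
      p <- truth$peak_id[k]
      tc <- template$retention_times[match(p, template$peak_ids)]
      resp <- if (p %in% names(rf)) rf[[p]] else 1000
      area <- truth$true_mg_g[k] * ext$sample_mass_g /
        ext$extract_volume_ml * resp
      h <- area / ((sig_l + sig_r) / 2 * sqrt(2 * pi))
      left <- times < tc
      y[left] <- y[left] + h * exp(-(times[left] - tc)^2 / (2 * sig_l^2))
      y[!left] <- y[!left] + h * exp(-(times[!left] - tc)^2 / (2 * sig_r^2))
    }
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    y <- y + stats::rnorm(length(y), sd = noise_sd)
  }
  batch <- if ("batch" %in% names(truth) && nrow(truth) > 0L) {
    truth$batch[1]
  } else {
    NULL
  }
  chromatogram(times, y, batch_id = batch)
}

#' Simulate an MS2 spectrum of a library compound
#'
#' Emits the rule library's diagnostic ions at their reference relative
#' abundances (perturbed by multiplicative lognormal noise) at
#' theoretical m/z values, plus the quasi-molecular ion.
#'
#' @param compound_id Compound present in the rule library.
#' @param polarity `"negative"` or `"positive"`.
#' @param abundance_noise_cv CV of the abundance noise (default 0).
#' @param seed Integer seed.
#' @param library A `fragment_rules` library.
#' @return An [ms2_spectrum()].
#' @export
simulate_ms2 <- function(compound_id, polarity = "negative",
                         abundance_noise_cv = 0, seed = 0,
                         library = default_fragment_rules()) {
  if (!compound_id %in% names(library)) {
    stop("compound '", compound_id, "' not in the rule library",
         call. = FALSE)
  }
  rule <- library[[compound_id]]
  ions <- if (polarity == "negative") rule$negative_ions else rule$positive_ions
  set.seed(as.integer(seed))
  rel <- ions$rel * .lnoise(nrow(ions), abundance_noise_cv)
  ms2_spectrum(theoretical_mz(rule$formula, polarity), polarity,
               mz = ions$mz, intensity = rel, id = compound_id)
}

#' Simulate an external-standard calibration series
#'
#' Areas are the compound's response factor times concentration with
#' multiplicative lognormal noise; at zero noise the fitted line is
#' exact.
#'
#' @param compound_id A compound of [default_peak_info()] (or any label,
#'   which then uses a response factor of 1000).
#' @param levels Concentrations in mg/mL (>= 5 positive values; default
#'   a 7-level series spanning 0.25-16 times the compound's typical
#'   extract concentration).
#' @param noise_cv Analytic CV (default 0).
#' @param seed Integer seed.
#' @return Data frame with `concentration` and `area`; the compound and
#'   its true response factor are attached as attributes.
#' @export
simulate_calibration <- function(compound_id, levels = NULL, noise_cv = 0,
                                 seed = 0) {
  info <- default_peak_info()
  i <- match(compound_id, info$compound)
  resp <- if (is.na(i)) 1000 else info$response_factor[i]
  if (is.null(levels)) {
    typical <- if (is.na(i)) 0.02 else {
      mean(c(info$mean_HN[i], info$mean_HB[i])) * 0.2 / 25
    }
    levels <- typical * c(0.25, 0.5, 1, 2, 4, 8, 16)
  }
  stopifnot(length(levels) >= 5L, all(levels > 0), noise_cv >= 0)
  set.seed(as.integer(seed))
  area <- resp * levels * .lnoise(length(levels), noise_cv)
  out <- data.frame(concentration = levels, area = area)
  attr(out, "compound") <- compound_id
  attr(out, "response_factor") <- resp
  out
}
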