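# Chromatographic peak detection, integration, QC metrics (asymmetry,
# resolution), RRT-based peak matching across batches and fingerprint
# similarity.

#' Construct a chromatogram
#'
#' @param times Time grid in minutes, strictly increasing.
#' @param intensities Detector response, same length as `times`.
#' @param batch_id Optional batch label.
#' @param wavelength_nm Detection wavelength (default 325 nm).
#' @return Object of class `chromatogram`.
#' @export
chromatogram <- function(times, intensities, batch_id = NULL,
                         wavelength_nm = 325) {
  stopifnot(is.numeric(times), is.numeric(intensities),
            length(times) == length(intensities), length(times) >= 2L)
  if (any(diff(times) <= 0)) {
    stop("time grid must be strictly increasing", call. = FALSE)
  }
  structure(list(times = as.numeric(times),
                 intensities = as.numeric(intensities),
                 batch_id = batch_id, wavelength_nm = wavelength_nm),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram%s> %d points, %.2f-%.2f min, %g nm\n",
              if (is.null(x$batch_id)) "" else paste0(" ", x$batch_id),
              length(x$times), min(x$times), max(x$times), x$wavelength_nm))
  invisible(x)
}

.baseline_level <- function(chrom, baseline = NULL) {
  if (is.null(baseline)) stats::median(chrom$intensities) else baseline
}

#' Detect and integrate chromatographic peaks
#'
#' Identifies local maxima exceeding the height and prominence
#' thresholds above a flat baseline (estimated as the median intensity
#' unless given). Peak bounds are set at the flanking valleys or at the
#' baseline crossing, whichever comes first; areas are trapezoidal
#' integrals of the baseline-subtracted trace between the bounds.
#' Adjacent peaks whose connecting valley stays above 50% of the lower
#' apex are flagged `unresolved`.
#'
#' @param chrom A [chromatogram()].
#' @param min_height Minimum apex height above baseline (> 0).
#' @param min_prominence Minimum prominence above the higher flanking
#'   valley (default `min_height / 2`).
#' @param baseline Baseline level; default median intensity.
#' @return Data frame (class `chrom_peaks`) with one row per peak:
#'   `apex_time`, `height`, `area`, `left`, `right`, `fwhm`,
#'   `unresolved`, `assigned_id`.
#' @export
detect_peaks <- function(chrom, min_height, min_prominence = min_height / 2,
                         baseline = NULL) {
  stopifnot(inherits(chrom, "chromatogram"), min_height > 0)
  t <- chrom$times
  y <- chrom$intensities - .baseline_level(chrom, baseline)
  n <- length(y)
  eps <- 1e-3  # fraction of apex height treated as baseline crossing
  apexes <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
  apexes <- apexes[y[apexes] >= min_height]
  rows <- list()
  for (i in apexes) {
    lo <- i
    while (lo > 1L && y[lo - 1L] <= y[lo] && y[lo - 1L] > eps * y[i]) {
      lo <- lo - 1L
    }
    if (lo > 1L && y[lo - 1L] <= eps * y[i]) lo <- lo - 1L
    hi <- i
    while (hi < n && y[hi + 1L] <= y[hi] && y[hi + 1L] > eps * y[i]) {
      hi <- hi + 1L
    }
    if (hi < n && y[hi + 1L] <= eps * y[i]) hi <- hi + 1L
    prominence <- y[i] - max(y[lo], y[hi], 0)
    if (prominence < min_prominence) next
    area <- pracma::trapz(t[lo:hi], pmax(y[lo:hi], 0))
    half <- .cross_times(t, y, i, lo, hi, 0.5 * y[i])
    rows[[length(rows) + 1L]] <- data.frame(
      apex_time = t[i], height = y[i], area = area,
      left = t[lo], right = t[hi],
      fwhm = if (anyNA(half)) NA_real_ else half[2] - half[1],
      unresolved = FALSE, assigned_id = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    out <- data.frame(apex_time = numeric(0), height = numeric(0),
                      area = numeric(0), left = numeric(0),
                      right = numeric(0), fwhm = numeric(0),
                      unresolved = logical(0),
                      assigned_id = character(0), stringsAsFactors = FALSE)
    class(out) <- c("chrom_peaks", class(out))
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$apex_time), , drop = FALSE]
  rownames(out) <- NULL
  # flag apex pairs whose valley does not drop below half the lower apex
  if (nrow(out) >= 2L) {
    for (k in seq_len(nrow(out) - 1L)) {
      sel <- t >= out$apex_time[k] & t <= out$apex_time[k + 1L]
      valley <- min(y[sel])
      if (valley > 0.5 * min(out$height[k], out$height[k + 1L])) {
        out$unresolved[c(k, k + 1L)] <- TRUE
      }
    }
  }
  class(out) <- c("chrom_peaks", class(out))
  out
}

# Interpolated times at which the trace crosses `level` on each side of
# apex index i, restricted to [lo, hi]; NA when the level is not crossed.
.cross_times <- function(t, y, i, lo, hi, level) {
  left <- NA_real_
  if (i > lo) for (j in seq(i, lo + 1L)) {
    if (y[j - 1L] <= level && y[j] > level) {
      left <- t[j - 1L] + (t[j] - t[j - 1L]) * (level - y[j - 1L]) /
        (y[j] - y[j - 1L])
      break
    }
  }
  right <- NA_real_
  if (i < hi) {
    for (j in seq(i, hi - 1L)) {
      if (y[j] > level && y[j + 1L] <= level) {
        right <- t[j] + (t[j + 1L] - t[j]) * (y[j] - level) /
          (y[j] - y[j + 1L])
        break
      }
    }
  }
  c(left, right)
}

#' Peak asymmetry factor at 10% height
#'
#' `As = b / a`, the back over front half-width at 10% of peak height
#' above baseline (the pharmacopoeial convention).
#'
#' @param chrom The [chromatogram()] the peak was detected in.
#' @param peak One row of a [detect_peaks()] result.
#' @param baseline Baseline level; default median intensity.
#' @return Asymmetry factor (1 for a symmetric peak, > 1 for tailing).
#' @export
asymmetry_factor <- function(chrom, peak, baseline = NULL) {
  stopifnot(inherits(chrom, "chromatogram"))
  t <- chrom$times
  y <- chrom$intensities - .baseline_level(chrom, baseline)
  i <- which.min(abs(t - peak$apex_time))
  lo <- which.min(abs(t - peak$left))
  hi <- which.min(abs(t - peak$right))
  crossings <- .cross_times(t, y, i, lo, hi, 0.1 * y[i])
  if (anyNA(crossings)) {
    stop("10% height level not crossed inside the peak bounds",
         call. = FALSE)
  }
  a <- t[i] - crossings[1]
  b <- crossings[2] - t[i]
  if (a <= 0 || b <= 0) {
    stop("degenerate half-widths at 10% height", call. = FALSE)
  }
  b / a
}

#' Chromatographic resolution between two peaks
#'
#' `Rs = 2 (t2 - t1) / (w1 + w2)` with baseline widths `w = 4 sigma`
#' estimated from the half-height width (`sigma = FWHM / 2.355`,
#' Gaussian assumption).
#'
#' @param p1,p2 Rows of a [detect_peaks()] result with `p1` eluting
#'   first.
#' @return Resolution (dimensionless; >= 1.5 conventionally means
#'   baseline separation).
#' @export
resolution <- function(p1, p2) {
  if (p1$apex_time > p2$apex_time) {
    stop("p1 must elute before p2", call. = FALSE)
  }
  if (is.na(p1$fwhm) || is.na(p2$fwhm) || p1$fwhm <= 0 || p2$fwhm <= 0) {
    stop("peak width estimate unavailable", call. = FALSE)
  }
  w1 <- 4 * p1$fwhm / 2.355
  w2 <- 4 * p2$fwhm / 2.355
  2 * (p2$apex_time - p1$apex_time) / (w1 + w2)
}

#' Relative retention times of assigned peaks
#'
#' `RRT_i = t_i / t_s` with the reference (internal standard) peak
#' mapping to exactly 1. Invariant under any uniform rescaling of the
#' time axis.
#'
#' @param peaks A [detect_peaks()] result with `assigned_id` filled for
#'   the peaks of interest.
#' @param reference_id Identifier of the reference peak.
#' @return Named numeric vector of RRTs for all assigned peaks.
#' @export
compute_rrt <- function(peaks, reference_id) {
  assigned <- peaks[!is.na(peaks$assigned_id), , drop = FALSE]
  ref <- assigned[assigned$assigned_id == reference_id, , drop = FALSE]
  if (nrow(ref) != 1L) {
    stop("reference peak '", reference_id, "' not assigned exactly once",
         call. = FALSE)
  }
  rrt <- assigned$apex_time / ref$apex_time
  stats::setNames(rrt, assigned$assigned_id)
}

#' Construct an RRT matching template
#'
#' @param entries Named numeric vector: expected RRT per common-peak
#'   label; the reference peak must be present with RRT exactly 1.
#' @param reference_peak Label of the reference peak.
#' @param reference_time Expected absolute retention time of the
#'   reference peak (minutes).
#' @param tolerance Maximum relative RRT deviation for a match
#'   (default 0.02).
#' @param reference_window Relative window around `reference_time`
#'   within which the largest peak is taken as the reference
#'   (default 0.05).
#' @return Object of class `rrt_template`.
#' @export
rrt_template <- function(entries, reference_peak, reference_time,
                         tolerance = 0.02, reference_window = 0.05) {
  stopifnot(!is.null(names(entries)), all(entries > 0),
            reference_peak %in% names(entries),
            reference_time > 0, tolerance > 0)
  if (abs(entries[[reference_peak]] - 1) > 1e-12) {
    stop("reference peak must have RRT exactly 1", call. = FALSE)
  }
  structure(list(entries = entries, reference_peak = reference_peak,
                 reference_time = reference_time, tolerance = tolerance,
                 reference_window = reference_window),
            class = "rrt_template")
}

#' Construct a batches x common-peaks area table
#'
#' @param areas Numeric matrix, one row per batch, one column per common
#'   peak; `NA` marks an unmatched cell.
#' @param batch_ids,peak_ids Row and column labels.
#' @param regions Region label per batch (optional, `NA` otherwise).
#' @param reference_peak Label of the reference (normalisation) peak.
#' @return Object of class `peak_table`.
#' @export
peak_table <- function(areas, batch_ids, peak_ids,
                       regions = rep(NA_character_, length(batch_ids)),
                       reference_peak = NULL) {
  areas <- as.matrix(areas)
  stopifnot(nrow(areas) == length(batch_ids),
            ncol(areas) == length(peak_ids),
            length(regions) == length(batch_ids))
  if (any(areas < 0, na.rm = TRUE)) {
    stop("peak areas must be non-negative", call. = FALSE)
  }
  dimnames(areas) <- list(batch_ids, peak_ids)
  structure(list(areas = areas, batch_ids = as.character(batch_ids),
                 peak_ids = as.character(peak_ids),
                 regions = as.character(regions),
                 reference_peak = reference_peak),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %d batches x %d peaks", nrow(x$areas),
              ncol(x$areas)))
  if (!all(is.na(x$regions))) {
    tab <- table(x$regions)
    cat(" (", paste(names(tab), tab, sep = ":", collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Match detected peaks across batches into a common-peak table
#'
#' Per batch the reference peak is the largest-area peak within the
#' template's relative window around the expected reference retention
#' time; all peaks are then expressed as RRTs, and each template entry
#' is assigned the peak minimising the absolute RRT deviation, accepted
#' when the relative deviation is within tolerance. Equidistant
#' candidates are broken towards the larger area (deterministic). Two
#' template entries claiming the same observed peak raise an error
#' naming both.
#'
#' @param peaks_per_batch Named list: one [detect_peaks()] result per
#'   batch.
#' @param template An [rrt_template()].
#' @param regions Optional named character vector of region labels per
#'   batch.
#' @return A [peak_table()] with `NA` for unmatched cells; the
#'   `unmatched` attribute lists (batch, peak) pairs that found no
#'   acceptable candidate.
#' @export
match_peaks <- function(peaks_per_batch, template, regions = NULL) {
  stopifnot(inherits(template, "rrt_template"), length(peaks_per_batch) > 0L,
            !is.null(names(peaks_per_batch)))
  batch_ids <- names(peaks_per_batch)
  peak_ids <- names(template$entries)
  areas <- matrix(NA_real_, nrow = length(batch_ids),
                  ncol = length(peak_ids),
                  dimnames = list(batch_ids, peak_ids))
  unmatched <- list()
  for (b in batch_ids) {
    pk <- peaks_per_batch[[b]]
    if (nrow(pk) == 0L) {
      stop("batch '", b, "' has no detected peaks", call. = FALSE)
    }
    in_win <- abs(pk$apex_time - template$reference_time) <=
      template$reference_window * template$reference_time
    if (!any(in_win)) {
      stop("no reference peak candidate in batch '", b, "'", call. = FALSE)
    }
    ref_i <- which(in_win)[which.max(pk$area[in_win])]
    rrt <- pk$apex_time / pk$apex_time[ref_i]
    claims <- integer(0)
    for (p in peak_ids) {
      expect <- template$entries[[p]]
      dev <- abs(rrt - expect)
      best <- which(dev == min(dev))
      if (length(best) > 1L) best <- best[which.max(pk$area[best])]
      if (dev[best] / expect <= template$tolerance) {
        if (best %in% claims) {
          other <- names(claims)[match(best, claims)]
          stop("ambiguous match in batch '", b, "': template entries '",
               other, "' and '", p, "' claim the peak at ",
               sprintf("%.3f", pk$apex_time[best]), " min", call. = FALSE)
        }
        claims <- c(claims, best)
        names(claims)[length(claims)] <- p
        areas[b, p] <- pk$area[best]
      } else {
        unmatched[[length(unmatched) + 1L]] <-
          data.frame(batch = b, peak = p, stringsAsFactors = FALSE)
      }
    }
  }
  reg <- if (is.null(regions)) rep(NA_character_, length(batch_ids))
         else unname(regions[batch_ids])
  out <- peak_table(areas, batch_ids, peak_ids, regions = reg,
                    reference_peak = template$reference_peak)
  attr(out, "unmatched") <- if (length(unmatched) > 0L) {
    do.call(rbind, unmatched)
  } else {
    data.frame(batch = character(0), peak = character(0))
  }
  out
}

#' Fingerprint similarity between two common-peak profiles
#'
#' Cosine (congruence) coefficient by default; Pearson correlation as an
#' alternative.
#'
#' @param profile,reference Non-negative area vectors of equal length
#'   (>= 2), not all zero.
#' @param method `"cosine"` (default) or `"correlation"`.
#' @return Similarity score; cosine lies in `[0, 1]` for non-negative
#'   profiles.
#' @export
similarity <- function(profile, reference,
                       method = c("cosine", "correlation")) {
  method <- match.arg(method)
  stopifnot(length(profile) == length(reference), length(profile) >= 2L)
  if (any(profile < 0, na.rm = TRUE) || any(reference < 0, na.rm = TRUE)) {
    stop("profiles must be non-negative", call. = FALSE)
  }
  if (all(profile == 0) || all(reference == 0)) {
    stop("similarity undefined for a zero profile", call. = FALSE)
  }
  if (method == "cosine") {
    sum(profile * reference) /
      sqrt(sum(profile^2) * sum(reference^2))
  } else {
    stats::cor(profile, reference)
  }
}

#' Per-batch similarity to the mean fingerprint
#'
#' The reference profile is the per-peak mean across batches.
#'
#' @param ptable A [peak_table()] without missing cells.
#' @param method Passed to [similarity()].
#' @return Named numeric vector: one score per batch.
#' @export
similarity_to_mean <- function(ptable, method = "cosine") {
  stopifnot(inherits(ptable, "peak_table"))
  if (anyNA(ptable$areas)) {
    stop("peak table has unmatched cells", call. = FALSE)
  }
  ref <- colMeans(ptable$areas)
  scores <- apply(ptable$areas, 1L, similarity, reference = ref,
                  method = method)
  stats::setNames(scores, ptable$batch_ids)
}
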