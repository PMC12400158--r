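# MS2 spectrum container and MGF (Mascot generic format) round trip.

#' Construct a centroided MS2 spectrum
#'
#' Relative abundances are rescaled so the base peak is exactly 100%.
#'
#' @param precursor_mz Precursor m/z (> 0).
#' @param polarity `"negative"` or `"positive"`.
#' @param mz Fragment m/z values (> 0).
#' @param intensity Fragment intensities or relative abundances; any
#'   positive scale is accepted and rescaled to percent of base peak.
#' @param id Optional spectrum identifier.
#' @return Object of class `ms2_spectrum`: list with `precursor_mz`,
#'   `polarity`, `id` and a `peaks` data frame (`mz`, `rel`).
#' @export
ms2_spectrum <- function(precursor_mz, polarity = c("negative", "positive"),
                         mz, intensity, id = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1L,
            precursor_mz > 0)
  stopifnot(length(mz) == length(intensity), length(mz) >= 1L,
            all(mz > 0), all(intensity > 0))
  rel <- 100 * intensity / max(intensity)
  ord <- order(mz)
  structure(list(precursor_mz = precursor_mz,
                 polarity = polarity,
                 id = id,
                 peaks = data.frame(mz = mz[ord], rel = rel[ord])),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum%s> precursor m/z %.5f [%s], %d fragment(s)\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              x$precursor_mz, x$polarity, nrow(x$peaks)))
  invisible(x)
}

#' Read MS2 spectra from an MGF file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS` and
#' `CHARGE` headers followed by `mz intensity` lines. Intensities are
#' rescaled to percent of base peak. Charge strings ending in `-`
#' (e.g. `1-`) give negative polarity, otherwise positive.
#'
#' @param path MGF file path.
#' @return List of [ms2_spectrum()] objects (empty list for an empty file).
#' @export
read_mgf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (line == "BEGIN IONS") {
      title <- NULL; pepmass <- NULL; polarity <- "positive"
      mz <- numeric(0); int <- numeric(0)
      j <- i + 1L
      repeat {
        if (j > length(lines)) {
          stop("unterminated MGF block starting at line ", i, call. = FALSE)
        }
        l <- trimws(lines[j])
        if (l == "END IONS") break
        if (grepl("^TITLE=", l)) {
          title <- sub("^TITLE=", "", l)
        } else if (grepl("^PEPMASS=", l)) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", l), "\\s+")[[1]][1])
        } else if (grepl("^CHARGE=", l)) {
          if (grepl("-\\s*$", l)) polarity <- "negative"
        } else if (grepl("^[0-9]", l)) {
          parts <- suppressWarnings(as.numeric(strsplit(l, "[ \t]+")[[1]]))
          if (length(parts) < 2L || anyNA(parts[1:2])) {
            stop("malformed peak line ", j, " in ", path, call. = FALSE)
          }
          mz <- c(mz, parts[1]); int <- c(int, parts[2])
        }
        j <- j + 1L
      }
      if (is.null(pepmass) || is.na(pepmass)) {
        stop("MGF block starting at line ", i, " lacks PEPMASS", call. = FALSE)
      }
      spectra[[length(spectra) + 1L]] <-
        ms2_spectrum(pepmass, polarity, mz, int, id = title)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  spectra
}

#' Write MS2 spectra to an MGF file
#'
#' @param spectra A single [ms2_spectrum()] or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "ms2_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(spectra)) {
    sp <- spectra[[k]]
    stopifnot(inherits(sp, "ms2_spectrum"))
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$id %||% paste0("spectrum_", k)), con)
    writeLines(sprintf("PEPMASS=%.5f", sp$precursor_mz), con)
    writeLines(paste0("CHARGE=1", if (sp$polarity == "negative") "-" else "+"),
               con)
    writeLines(sprintf("%.5f %.4f", sp$peaks$mz, sp$peaks$rel), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}
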