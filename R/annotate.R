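# Rule-based MS2 annotation of caffeoylquinic acids (CQAs) and
# flavonoids: neutral-loss chains, retro Diels-Alder (RDA) ions,
# glycoside ring cleavages and relative-abundance isomer rules.

# Exact anion masses of the anchor ions, derived from formulas.
.cqa_anchor <- function() {
  c(quinate   = theoretical_mz("C7H12O6", "negative"),   # m/z 191
    caffeate  = theoretical_mz("C9H8O4",  "negative"),   # m/z 179
    dehydr    = theoretical_mz("C7H10O5", "negative"),   # m/z 173
    decarb    = theoretical_mz("C8H8O2",  "negative"),   # m/z 135
    mono      = theoretical_mz("C16H18O9", "negative"),  # m/z 353
    caffeoyl  = monoisotopic_mass("C9H6O3"))
}

# RDA evidence table: A-ring fragment species of the aglycones in scope
# (quercetin-type 1,2A and its -CO ion; luteolin/apigenin-type 1,3A,
# 0,2A, 0,4A).
.rda_formulas <- c("C8H4O5", "C7H4O4", "C8H6O3", "C6H4O2")

.match_mz <- function(peaks_mz, target, tol_ppm) {
  d <- abs(peaks_mz - target)
  i <- which.min(d)
  if (length(i) == 0L || d[i] > target * tol_ppm * 1e-6) return(NA_integer_)
  i
}

# Relative abundance of the most intense peak inside a +-0.01 Da window
# around a nominal-mass anchor; 0 when absent.
.abundance_near <- function(spec, target, window = 0.01) {
  sel <- abs(spec$peaks$mz - target) <= window
  if (!any(sel)) return(0)
  max(spec$peaks$rel[sel])
}

.base_peak_mz <- function(spec) {
  spec$peaks$mz[which.max(spec$peaks$rel)]
}

#' Classify a spectrum as a caffeoylquinic acid
#'
#' Establishes the caffeoylation degree (1-3) by detecting the
#' neutral-loss chain `[M-H]- -> ... -> quinate (m/z 191.0561)` through
#' successive losses of the caffeoyl residue (162.03169 Da), supported
#' by at least one of the caffeate (179.0350), dehydrated quinate
#' (173.0455) or decarboxylated caffeate (135.0452) ions.
#'
#' @param spec An [ms2_spectrum()]; must be negative mode (ester-bond
#'   fragments of CQAs are informative only there).
#' @param tol_ppm Mass tolerance in ppm (default 10).
#' @return List with `class` (`"monoCQA"`, `"diCQA"`, `"triCQA"` or
#'   `"none"`), `degree` (0 when not a CQA) and a `matched` data frame
#'   of (expected, observed, ppm) rows.
#' @export
classify_cqa <- function(spec, tol_ppm = 10) {
  stopifnot(inherits(spec, "ms2_spectrum"))
  if (spec$polarity != "negative") {
    stop("CQA classification requires negative-mode spectra; ",
         "reacquire in negative ion mode", call. = FALSE)
  }
  a <- .cqa_anchor()
  none <- list(class = "none", degree = 0L,
               matched = data.frame(expected = numeric(0),
                                    observed = numeric(0),
                                    ppm = numeric(0)))
  # degree from the precursor: [M-H]- = quinate + n * caffeoyl
  deg <- NA_integer_
  for (n in 1:3) {
    expect <- a[["quinate"]] + n * a[["caffeoyl"]]
    if (abs(spec$precursor_mz - expect) <= expect * tol_ppm * 1e-6) {
      deg <- n
      break
    }
  }
  if (is.na(deg)) return(none)
  # the chain ions quinate + j*caffeoyl, j = 0..deg-1, must all be present
  matched <- list()
  for (j in 0:(deg - 1L)) {
    expect <- a[["quinate"]] + j * a[["caffeoyl"]]
    i <- .match_mz(spec$peaks$mz, expect, tol_ppm)
    if (is.na(i)) return(none)
    obs <- spec$peaks$mz[i]
    matched[[length(matched) + 1L]] <-
      data.frame(expected = expect, observed = obs,
                 ppm = ppm_error(obs, expect))
  }
  support <- FALSE
  for (s in c("caffeate", "decarb", "dehydr")) {
    i <- .match_mz(spec$peaks$mz, a[[s]], tol_ppm)
    if (!is.na(i)) {
      support <- TRUE
      obs <- spec$peaks$mz[i]
      matched[[length(matched) + 1L]] <-
        data.frame(expected = a[[s]], observed = obs,
                   ppm = ppm_error(obs, a[[s]]))
    }
  }
  if (!support) return(none)
  list(class = c("monoCQA", "diCQA", "triCQA")[deg], degree = deg,
       matched = do.call(rbind, matched))
}

#' Discriminate CQA positional isomers by relative abundance
#'
#' Applies the published base-peak/relative-abundance rules. Degree 1:
#' base peak at m/z 173 identifies cryptochlorogenic acid; base peak at
#' 191 with the 179 ion at >= 20% of base identifies neochlorogenic
#' acid, at <= 10% chlorogenic acid. Degree 2: base peak at 191
#' identifies 1,5-di-O-caffeoylquinic acid; base peak at 353 with the
#' 173 ion at >= 35% isochlorogenic acid B, in [10, 35) isochlorogenic
#' acid C, at <= 5% isochlorogenic acid A. Abundances falling in the
#' guard bands return `"ambiguous"` rather than a guess. Degree 3 has a
#' single in-scope isomer.
#'
#' @param spec An [ms2_spectrum()] already classified as a CQA.
#' @param degree Caffeoylation degree from [classify_cqa()].
#' @return Isomer label, or `"ambiguous"`.
#' @export
discriminate_cqa_isomer <- function(spec, degree) {
  stopifnot(inherits(spec, "ms2_spectrum"), degree %in% 1:3)
  a <- .cqa_anchor()
  base <- .base_peak_mz(spec)
  near <- function(x, target) abs(x - target) <= 0.01
  if (degree == 3L) return("3,4,5-tricaffeoylquinic")
  if (degree == 1L) {
    if (near(base, a[["dehydr"]])) return("cryptochlorogenic")
    if (near(base, a[["quinate"]])) {
      ab179 <- .abundance_near(spec, a[["caffeate"]])
      if (ab179 >= 20) return("neochlorogenic")
      if (ab179 <= 10) return("chlorogenic")
    }
    return("ambiguous")
  }
  # degree 2
  if (near(base, a[["quinate"]])) return("1,5-dicaffeoylquinic")
  if (near(base, a[["mono"]])) {
    ab173 <- .abundance_near(spec, a[["dehydr"]])
    if (ab173 >= 35) return("isochlorogenic B")
    if (ab173 >= 10) return("isochlorogenic C")
    if (ab173 <= 5)  return("isochlorogenic A")
  }
  "ambiguous"
}

#' Classify a flavonoid spectrum
#'
#' Distinguishes flavonoid C-glycosides (two or more of the 60/90/120 Da
#' sugar cross-ring cleavage losses, or sums thereof, from the
#' quasi-molecular ion; the aglycone undergoes no RDA reaction),
#' flavonoid O-glycosides (an intact glycosyl loss - hexosyl 162.0528,
#' deoxyhexosyl 146.0579 or rutinosyl 308.1107 - yielding an aglycone
#' ion that itself shows RDA ions) and bare aglycones (RDA ions only).
#' In positive mode the RDA/ring-cleavage evidence is absent, so
#' O-glycosides are recognised from the glycosyl loss alone and
#' aglycones from the 1,3A+ ion (reduced evidence).
#'
#' @param spec An [ms2_spectrum()].
#' @param tol_ppm Mass tolerance in ppm.
#' @return List of hypothesis lists, each with `class` (`"flavonoid
#'   C-glycoside"`, `"flavonol O-glycoside"`, `"flavone aglycone"` or
#'   `"none"`), `matched` data frame and, for O-glycosides, the
#'   `aglycone_mz`. Contradictory evidence yields both hypotheses with
#'   `ambiguous = TRUE`.
#' @export
classify_flavonoid <- function(spec, tol_ppm = 10) {
  stopifnot(inherits(spec, "ms2_spectrum"))
  losses <- neutral_losses()
  neg <- spec$polarity == "negative"
  match_row <- function(target) {
    i <- .match_mz(spec$peaks$mz, target, tol_ppm)
    if (is.na(i)) return(NULL)
    obs <- spec$peaks$mz[i]
    data.frame(expected = target, observed = obs, ppm = ppm_error(obs, target))
  }
  hypotheses <- list()

  # --- C-glycoside: ring-cleavage losses from [M-H]- (negative only)
  ring_matched <- NULL
  if (neg) {
    ring <- losses[c("ring_60", "ring_90", "ring_120")]
    singles <- ring
    sums <- outer(ring, ring, "+")
    cand <- unique(c(singles, sums[upper.tri(sums, diag = TRUE)]))
    n_single <- 0L
    rows <- list()
    for (l in singles) {
      r <- match_row(spec$precursor_mz - l)
      if (!is.null(r)) { n_single <- n_single + 1L; rows[[length(rows) + 1L]] <- r }
    }
    n_total <- n_single
    for (l in setdiff(cand, singles)) {
      r <- match_row(spec$precursor_mz - l)
      if (!is.null(r)) { n_total <- n_total + 1L; rows[[length(rows) + 1L]] <- r }
    }
    if (n_total >= 2L) {
      ring_matched <- do.call(rbind, rows)
      hypotheses[[length(hypotheses) + 1L]] <-
        list(class = "flavonoid C-glycoside", matched = ring_matched)
    }
  }

  # --- O-glycoside: intact glycosyl loss -> aglycone ion (+ RDA in neg)
  rda_mz <- vapply(.rda_formulas, theoretical_mz, numeric(1),
                   polarity = spec$polarity)
  ogly_matched <- NULL
  for (g in c("hexosyl", "deoxyhexosyl", "rutinosyl")) {
    agl <- spec$precursor_mz - losses[[g]]
    r <- match_row(agl)
    if (is.null(r)) next
    rda_rows <- Filter(Negate(is.null), lapply(rda_mz, match_row))
    if (neg && length(rda_rows) == 0L) next
    ogly_matched <- do.call(rbind, c(list(r), rda_rows))
    hypotheses[[length(hypotheses) + 1L]] <-
      list(class = "flavonol O-glycoside", matched = ogly_matched,
           aglycone_mz = agl, glycosyl = g)
    break
  }

  # --- bare aglycone: RDA ions, no glycosyl or ring losses
  if (is.null(ring_matched) && is.null(ogly_matched)) {
    rda_rows <- Filter(Negate(is.null), lapply(rda_mz, match_row))
    if (length(rda_rows) >= 1L) {
      hypotheses[[length(hypotheses) + 1L]] <-
        list(class = "flavone aglycone", matched = do.call(rbind, rda_rows))
    }
  }

  if (length(hypotheses) == 0L) {
    return(list(list(class = "none",
                     matched = data.frame(expected = numeric(0),
                                          observed = numeric(0),
                                          ppm = numeric(0)))))
  }
  if (!is.null(ring_matched) && !is.null(ogly_matched)) {
    hypotheses <- lapply(hypotheses, function(h) { h$ambiguous <- TRUE; h })
  }
  hypotheses
}

#' Annotate an MS2 spectrum against a rule library
#'
#' Runs the CQA chain/isomer rules and the flavonoid glycoside/RDA rules,
#' then scores every library compound whose class, isomer and precursor
#' formula are compatible with the spectrum. The score is the fraction
#' of the compound's full (negative-mode) diagnostic-ion inventory
#' matched within tolerance, so positive-mode spectra - which lack RDA
#' and ring-cleavage ions - score strictly lower than their
#' negative-mode counterparts. Ties are broken by mean absolute ppm
#' error.
#'
#' @param spec An [ms2_spectrum()].
#' @param library A `fragment_rules` library
#'   (default: [default_fragment_rules()]).
#' @param tol_ppm Mass tolerance in ppm (default 10).
#' @return Data frame of ranked hypotheses with columns `compound_id`,
#'   `class`, `isomer`, `score`, `n_matched`, `mean_abs_ppm`. A spectrum
#'   matching nothing returns a single row with class `"none"` and score
#'   0; a CQA or glycoside whose isomer evidence falls in a guard band
#'   is reported with `compound_id` `NA` and isomer `"ambiguous"`.
#' @export
annotate <- function(spec, library = default_fragment_rules(), tol_ppm = 10) {
  stopifnot(inherits(spec, "ms2_spectrum"), length(library) > 0L)
  if (nrow(spec$peaks) == 0L) stop("empty spectrum", call. = FALSE)

  cqa <- if (spec$polarity == "negative") {
    classify_cqa(spec, tol_ppm)
  } else {
    list(class = "none", degree = 0L)
  }
  isomer <- if (cqa$class != "none") {
    discriminate_cqa_isomer(spec, cqa$degree)
  } else {
    NA_character_
  }
  flav <- classify_flavonoid(spec, tol_ppm)
  flav_classes <- vapply(flav, `[[`, character(1), "class")

  score_compound <- function(rule) {
    ions <- if (spec$polarity == "negative") rule$negative_ions else rule$positive_ions
    denom <- nrow(rule$negative_ions)  # full evidence inventory
    hits <- ppms <- numeric(0)
    for (k in seq_len(nrow(ions))) {
      i <- .match_mz(spec$peaks$mz, ions$mz[k], tol_ppm)
      if (!is.na(i)) {
        hits <- c(hits, spec$peaks$mz[i])
        ppms <- c(ppms, abs(ppm_error(spec$peaks$mz[i], ions$mz[k])))
      }
    }
    list(score = length(hits) / denom, n = length(hits),
         mean_abs_ppm = if (length(ppms)) mean(ppms) else NA_real_)
  }

  rows <- list()
  for (rule in library) {
    prec_expect <- theoretical_mz(rule$formula, spec$polarity)
    prec_ok <- abs(spec$precursor_mz - prec_expect) <=
      prec_expect * tol_ppm * 1e-6
    if (!prec_ok) next
    eligible <- if (rule$class %in% c("monoCQA", "diCQA", "triCQA")) {
      rule$class == cqa$class && !is.na(isomer) &&
        identical(rule$isomer, isomer)
    } else {
      rule$class %in% flav_classes
    }
    if (!eligible) next
    sc <- score_compound(rule)
    rows[[length(rows) + 1L]] <- data.frame(
      compound_id = rule$id, class = rule$class,
      isomer = rule$isomer %||% NA_character_,
      score = sc$score, n_matched = sc$n, mean_abs_ppm = sc$mean_abs_ppm,
      stringsAsFactors = FALSE)
  }

  if (length(rows) == 0L) {
    # class-level (but compound-less) outcomes: ambiguous isomer, or nothing
    cls <- if (cqa$class != "none") cqa$class
           else if (any(flav_classes != "none")) flav_classes[1]
           else "none"
    iso <- if (cqa$class != "none") isomer else NA_character_
    return(data.frame(compound_id = NA_character_, class = cls,
                      isomer = iso, score = 0, n_matched = 0L,
                      mean_abs_ppm = NA_real_, stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(-out$score, out$mean_abs_ppm), , drop = FALSE]
}
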