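# Exact-mass arithmetic for small-molecule fragment annotation.
# Monoisotopic atomic masses (CODATA/IUPAC); restricted to CHNOS, which
# covers every phenylpropanoid and flavonoid handled here.

.MONO_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

#' Mass of a proton in Da
#'
#' Used to convert neutral monoisotopic masses to singly charged
#' quasi-molecular ions (`[M-H]-` / `[M+H]+`).
#' @export
PROTON_MASS <- 1.007276

#' Parse an elemental formula
#'
#' @param formula Character scalar such as `"C16H18O9"`. Only C, H, N, O
#'   and S are supported. The empty string parses to an empty formula.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  if (nchar(formula) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  tokens <- tokens[nchar(tokens) > 0L]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("cannot parse formula: '", formula, "'", call. = FALSE)
  }
  elems <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  bad <- setdiff(elems, names(.MONO_MASS))
  if (length(bad) > 0L) {
    stop("unknown element(s) in formula '", formula, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- tapply(counts, factor(elems, levels = names(.MONO_MASS)), sum)
  out <- out[!is.na(out)]
  stats::setNames(as.integer(out), names(out))
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula Character formula (see [parse_formula()]); the empty
#'   string has mass 0.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")     # 18.01056
#' monoisotopic_mass("C9H6O3")  # caffeoyl residue, 162.03169
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  if (length(counts) == 0L) return(0)
  sum(.MONO_MASS[names(counts)] * counts)
}

#' Theoretical m/z of a singly charged quasi-molecular ion
#'
#' Negative mode yields `[M-H]-` (M minus one proton), positive mode
#' `[M+H]+`.
#'
#' @param formula Neutral elemental formula.
#' @param polarity `"negative"` or `"positive"`.
#' @return Theoretical m/z in Da.
#' @export
theoretical_mz <- function(formula, polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  m <- monoisotopic_mass(formula)
  if (polarity == "negative") {
    if (m <= PROTON_MASS) {
      stop("neutral mass must exceed a proton mass for [M-H]-",
           call. = FALSE)
    }
    m - PROTON_MASS
  } else {
    m + PROTON_MASS
  }
}

#' Mass error in parts per million
#'
#' @param observed,theoretical m/z values; `theoretical` must be > 0.
#' @return Signed ppm error `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  1e6 * (observed - theoretical) / theoretical
}

# Neutral-loss masses used by the fragmentation rules, computed from
# their formulas so that mass additivity is guaranteed by construction.
.LOSS_FORMULAS <- c(
  caffeoyl      = "C9H6O3",   # ester-bond cleavage of caffeoylquinic acids
  water         = "H2O",
  co2           = "CO2",
  co            = "CO",
  ring_60       = "C2H4O2",   # cross-ring cleavages of C-glycoside sugars
  ring_90       = "C3H6O3",
  ring_120      = "C4H8O4",
  hexosyl       = "C6H10O5",  # intact glycosyl losses of O-glycosides
  deoxyhexosyl  = "C6H10O4",
  rutinosyl     = "C12H20O9"
)

#' Neutral-loss mass table
#'
#' Monoisotopic masses of the neutral losses recognised by the
#' annotation rules: the caffeoyl residue (162.03169), water, CO2, CO,
#' the 60/90/120 Da hexose cross-ring cleavages and intact hexosyl,
#' deoxyhexosyl and rutinosyl units.
#'
#' @return Named numeric vector of loss masses in Da.
#' @export
neutral_losses <- function() {
  vapply(.LOSS_FORMULAS, monoisotopic_mass, numeric(1))
}
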