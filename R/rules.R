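# Fragment rule library: loading, validation and theoretical-m/z
# resolution of the per-compound diagnostic ion tables.

.rules_env <- new.env(parent = emptyenv())

#' Load a fragmentation rule library
#'
#' Reads a YAML rule library (see the packaged
#' `extdata/fragment_rules.yaml`) and resolves every diagnostic ion to a
#' theoretical m/z in both polarities. Ions are specified either by the
#' neutral formula of the charged species or as a chain of cumulative
#' neutral losses from the quasi-molecular ion.
#'
#' @param path Path to a YAML rule file; defaults to the packaged
#'   library covering the caffeoylquinic acids and flavonoids of
#'   Artemisiae argyi Folium.
#' @return A list of rule entries (class `fragment_rules`), each with
#'   `id`, `class`, optional `isomer`, `formula`, and per-polarity data
#'   frames `negative_ions` / `positive_ions` holding columns `mz`,
#'   `rel`, `label`.
#' @export
load_fragment_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "fragment_rules.yaml", package = "herbqc")
  }
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  losses <- neutral_losses()
  rules <- lapply(raw, function(entry) {
    stopifnot(!is.null(entry$id), !is.null(entry$class),
              !is.null(entry$formula))
    resolve <- function(ions, polarity) {
      stopifnot(length(ions) > 0L)
      prec <- theoretical_mz(entry$formula, polarity)
      rows <- lapply(ions, function(ion) {
        stopifnot(!is.null(ion$rel), ion$rel > 0, ion$rel <= 100)
        if (!is.null(ion$formula)) {
          mz <- theoretical_mz(ion$formula, polarity)
        } else if (!is.null(ion$losses)) {
          unknown <- setdiff(unlist(ion$losses), names(losses))
          if (length(unknown) > 0L) {
            stop("unknown neutral loss '", unknown[1], "' in rule '",
                 entry$id, "'", call. = FALSE)
          }
          mz <- prec - sum(losses[unlist(ion$losses)])
        } else {
          stop("ion in rule '", entry$id,
               "' has neither formula nor losses", call. = FALSE)
        }
        data.frame(mz = mz, rel = ion$rel,
                   label = ion$label %||% "", stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
    entry$negative_ions <- resolve(entry$negative_ions, "negative")
    entry$positive_ions <- resolve(entry$positive_ions, "positive")
    entry
  })
  names(rules) <- vapply(rules, `[[`, character(1), "id")
  if (anyDuplicated(names(rules))) {
    stop("duplicate compound ids in rule library", call. = FALSE)
  }
  structure(rules, class = "fragment_rules")
}

#' Packaged default rule library (cached)
#'
#' @return The `fragment_rules` object for the packaged library.
#' @export
default_fragment_rules <- function() {
  if (is.null(.rules_env$default)) {
    .rules_env$default <- load_fragment_rules()
  }
  .rules_env$default
}

`%||%` <- function(a, b) if (is.null(a)) b else a
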