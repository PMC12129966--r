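# Packaged configuration assets (YAML/CSV under inst/extdata), loaded once
# per session and cached. All are editable: every loader takes a `path`
# override so a site can swap in its own catalog, cut-points or dictionary.

.asset_cache <- new.env(parent = emptyenv())

asset_path <- function(file) {
  p <- system.file("extdata", file, package = "icutrigger")
  if (!nzchar(p)) stop("packaged asset not found: ", file)
  p
}

cached <- function(key, loader) {
  if (!exists(key, envir = .asset_cache)) {
    assign(key, loader(), envir = .asset_cache)
  }
  get(key, envir = .asset_cache)
}

#' SOFA cut-point table
#'
#' Returns the packaged SOFA cut-points (six organ systems, subscores 0-4)
#' as a named list, one entry per organ.
#'
#' @param path optional path to an alternative YAML cut-point table.
#' @return named list with elements \code{respiratory}, \code{coagulation},
#'   \code{hepatic}, \code{cardiovascular}, \code{neurological}, \code{renal}.
#' @export
sofa_cutpoints <- function(path = NULL) {
  if (!is.null(path)) return(yaml::read_yaml(path))
  cached("sofa", function() yaml::read_yaml(asset_path("sofa_table.yaml")))
}

#' Naranjo question points and score bands
#'
#' @param path optional path to an alternative YAML points table.
#' @return list with \code{questions} (10 entries, yes/no/unknown points)
#'   and \code{categories} (band lower edges).
#' @export
naranjo_points <- function(path = NULL) {
  if (!is.null(path)) return(yaml::read_yaml(path))
  cached("naranjo", function() yaml::read_yaml(asset_path("naranjo_points.yaml")))
}

#' WHO-UMC causality decision table
#'
#' @param path optional path to an alternative YAML rule table.
#' @return list of rules, each with a \code{when} condition set and a
#'   \code{category}; evaluated first-match.
#' @export
who_umc_rules <- function(path = NULL) {
  if (!is.null(path)) return(yaml::read_yaml(path)$rules)
  cached("who_umc", function() yaml::read_yaml(asset_path("who_umc_table.yaml"))$rules)
}

atc_dictionary <- function() {
  cached("atc", function() {
    read.csv(asset_path("atc_dictionary.csv"), stringsAsFactors = FALSE)
  })
}

drug_synonyms <- function() {
  cached("synonyms", function() {
    read.csv(asset_path("drug_synonyms.csv"), stringsAsFactors = FALSE)
  })
}

#' Published reference tables from the calibration study
#'
#' The per-trigger performance table (rates per 100 records and PPV), the
#' ADR characterization counts (severity / mechanism / causality), and the
#' cohort-level counts that the synthetic generator is calibrated to. These
#' are transcriptions of the source surveillance study's printed summary
#' tables and serve as calibration constants and reference points; they are
#' not outputs of this package.
#'
#' @param which one of \code{"performance"}, \code{"characterization"},
#'   \code{"counts"}.
#' @return a data.frame.
#' @export
reference_table <- function(which = c("performance", "characterization", "counts")) {
  which <- match.arg(which)
  file <- switch(which,
    performance = "trigger_performance_reference.csv",
    characterization = "adr_characterization_reference.csv",
    counts = "cohort_counts_reference.csv"
  )
  read.csv(asset_path(file), stringsAsFactors = FALSE)
}
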