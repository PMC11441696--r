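# Drug ontology: canonical anti-myeloma drug list, drug -> class mapping,
# and the exact-set regimen-naming catalogue.

CORE_CLASSES <- c("IMiD", "PI", "anti-CD38", "anti-SLAMF7", "HDACi", "alkylator")
TCE_CLASSES <- c("IMiD", "PI", "anti-CD38")

#' Classify a drug name into an anti-myeloma drug class
#'
#' Total function: canonical names map to their class (`IMiD`, `PI`,
#' `anti-CD38`, `anti-SLAMF7`, `HDACi`, `alkylator`, `steroid`); anything
#' else — supportive drugs, antibiotics, unknown strings — maps to `other`
#' and plays no role in line building or exposure.
#'
#' @param name character vector of drug names (case-insensitive).
#' @param config pipeline configuration (for the drug map).
#' @return character vector of classes, same length as `name`.
#' @export
#' @examples
#' classify_drug(c("daratumumab", "dexamethasone", "rituximab"))
classify_drug <- function(name, config = default_config()) {
  map <- config$drug_map
  cls <- map$class[match(tolower(trimws(name)), map$name)]
  cls[is.na(cls)] <- "other"
  cls
}

# Core anti-myeloma drugs define lines and class exposure; steroids and
# `other` drugs never do, though steroids discriminate catalogue labels
# (Vd-based vs Bor-based).
is_core_drug <- function(name, config = default_config()) {
  classify_drug(name, config) %in% CORE_CLASSES
}

is_steroid <- function(name, config = default_config()) {
  classify_drug(name, config) == "steroid"
}

#' Label a drug combination against the regimen catalogue
#'
#' Exact-set lookup: the observed set of core anti-myeloma drugs plus
#' steroids must equal a catalogue entry's members exactly. A set with an
#' extra unlisted core drug, or a catalogue combination missing its steroid,
#' maps to `"Other"` (the bucket for modified, steroid-uncombined or
#' unapproved regimens). Drugs of class `other` are ignored. The lookup is
#' deterministic and invariant to the order of the input set.
#'
#' @param drug_set character vector of drug names (a set; duplicates fine).
#' @param config pipeline configuration (for the catalogue and drug map).
#' @return a single label string, e.g. `"Rd-based"`, or `"Other"`.
#' @export
#' @examples
#' label_regimen(c("lenalidomide", "dexamethasone")) # "Rd-based"
#' label_regimen("bortezomib")                       # "Bor-based"
#' label_regimen(c("daratumumab", "carfilzomib"))    # "Other" (no steroid)
label_regimen <- function(drug_set, config = default_config()) {
  stopifnot(length(drug_set) >= 1)
  drug_set <- tolower(trimws(drug_set))
  cls <- classify_drug(drug_set, config)
  keep <- sort(unique(drug_set[cls != "other"]))
  if (length(keep) == 0) {
    return("Other")
  }
  key <- paste(keep, collapse = "|")
  keys <- map_chr(config$catalogue$members, paste, collapse = "|")
  hit <- match(key, keys)
  if (is.na(hit)) "Other" else config$catalogue$label[hit]
}

#' The regimen catalogue as a tibble
#'
#' @param config pipeline configuration.
#' @return tibble with `label` and list-column `members`.
#' @export
regimen_catalogue <- function(config = default_config()) {
  config$catalogue
}
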