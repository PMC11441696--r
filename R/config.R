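# Pipeline configuration: a nested list read from YAML. The shipped default
# file is authoritative for the drug map, regimen catalogue and comorbidity
# map; user files override it key-by-key and unknown keys are rejected.

#' Default pipeline configuration
#'
#' Reads the configuration shipped with the package: cohort windows and
#' index drugs, line-transfer parameters (56-day formation window, 90-day
#' gap threshold, 28-day injectable coverage), approval-era boundaries,
#' summary conventions, the anti-myeloma drug map, the exact-set regimen
#' catalogue and the baseline comorbidity prefix map.
#'
#' @return a named list of class `lot_config`.
#' @export
default_config <- function() {
  normalize_config(raw_default_config())
}

raw_default_config <- function() {
  path <- system.file("extdata", "default_config.yaml", package = "myelolot")
  stopifnot(nzchar(path))
  yaml::read_yaml(path)
}

#' Load a pipeline configuration file
#'
#' Reads a YAML file and merges it over the shipped defaults. Top-level and
#' second-level keys not present in the defaults are rejected, so typos fail
#' loudly instead of being silently ignored. `drugs`, `regimens` and
#' `comorbidities` replace the default blocks wholesale when given.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return a `lot_config` list.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) {
    return(default_config())
  }
  base <- raw_default_config()
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  for (k in names(user)) {
    if (k %in% c("drugs", "regimens", "comorbidities")) {
      base[[k]] <- user[[k]]
    } else {
      bad <- setdiff(names(user[[k]]), names(base[[k]]))
      if (length(bad)) {
        abort(paste0("unknown config keys under '", k, "': ",
                     paste(bad, collapse = ", ")))
      }
      base[[k]] <- modifyList(base[[k]], user[[k]])
    }
  }
  normalize_config(base)
}

# Parse dates, coerce the drug/regimen blocks to tibbles, and precompute
# lookups used in inner loops.
normalize_config <- function(cfg) {
  cfg$cohort$study_window_start <- ymd(cfg$cohort$study_window_start)
  cfg$cohort$study_window_end <- ymd(cfg$cohort$study_window_end)
  cfg$cohort$sct_exclusion_start <- ymd(cfg$cohort$sct_exclusion_start)
  cfg$eras$d_vmp_approval <- ymd(paste0(cfg$eras$d_vmp_approval, "-01"))
  cfg$eras$drd_approval <- ymd(paste0(cfg$eras$drd_approval, "-01"))
  cfg$drug_map <- dplyr::bind_rows(lapply(cfg$drugs, as_tibble))
  cfg$catalogue <- tibble(
    label = map_chr(cfg$regimens, "label"),
    members = map(cfg$regimens, ~ sort(unlist(.x$members)))
  )
  if (anyDuplicated(cfg$drug_map$name)) {
    abort("drug map has duplicate drug names")
  }
  keys <- map_chr(cfg$catalogue$members, paste, collapse = "|")
  if (anyDuplicated(keys)) {
    abort("regimen catalogue has duplicate drug sets")
  }
  structure(cfg, class = c("lot_config", "list"))
}

#' @export
print.lot_config <- function(x, ...) {
  cat("<lot_config>\n")
  cat("  study window: ", format(x$cohort$study_window_start), " .. ",
      format(x$cohort$study_window_end), "\n", sep = "")
  cat("  drugs: ", nrow(x$drug_map), " mapped; regimen catalogue: ",
      nrow(x$catalogue), " labels\n", sep = "")
  cat("  line rules: formation window ", x$lines$formation_window_days,
      " d, gap threshold ", x$lines$gap_threshold_days,
      " d, injectable coverage ", x$lines$injectable_coverage_days, " d\n",
      sep = "")
  invisible(x)
}
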