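# Claims data model: the five-record bundle and its delimited-text I/O.
# Column schema is fixed (comma-delimited, UTF-8, header row, ISO-8601
# dates); there is no dialect sniffing. All intervals are inclusive of both
# endpoints. Injectable administrations are stored as single-day records
# (end_date == start_date); their imputed coverage is an episode-engine
# concern, not a data-model one.

BUNDLE_SCHEMA <- list(
  patients = c("patient_id", "sex", "birth_date", "hospital_id"),
  hospitals = c("hospital_id", "bed_size_class", "category"),
  diagnoses = c("patient_id", "icd10_code", "date", "suspected"),
  prescriptions = c("patient_id", "drug", "route", "start_date", "end_date"),
  procedures = c("patient_id", "procedure_code", "date")
)

BUNDLE_DATE_COLS <- list(
  patients = "birth_date", hospitals = character(0), diagnoses = "date",
  prescriptions = c("start_date", "end_date"), procedures = "date"
)

#' Construct a claims bundle
#'
#' Bundles the five record collections (patients, hospitals, diagnoses,
#' prescriptions, procedures) into one validated object. Validation is
#' total: every malformed input raises a diagnosable error naming the table,
#' the column or the offending rows — rows are never silently dropped.
#'
#' @param patients,hospitals,diagnoses,prescriptions,procedures tibbles
#'   following the documented column schema.
#' @param validate run [validate_bundle()] (default `TRUE`).
#' @return an object of class `claims_bundle`.
#' @export
claims_bundle <- function(patients, hospitals, diagnoses, prescriptions,
                          procedures, validate = TRUE) {
  b <- structure(
    list(patients = as_tibble(patients), hospitals = as_tibble(hospitals),
         diagnoses = as_tibble(diagnoses),
         prescriptions = as_tibble(prescriptions),
         procedures = as_tibble(procedures)),
    class = "claims_bundle"
  )
  b <- normalize_bundle(b)
  if (validate) validate_bundle(b)
  b
}

# Deterministic row order so that write -> read is the identity.
normalize_bundle <- function(b) {
  b$patients <- arrange(b$patients, .data$patient_id)
  b$hospitals <- arrange(b$hospitals, .data$hospital_id)
  b$diagnoses <- arrange(b$diagnoses, .data$patient_id, .data$date,
                         .data$icd10_code, .data$suspected)
  b$prescriptions <- arrange(b$prescriptions, .data$patient_id,
                             .data$start_date, .data$drug, .data$end_date,
                             .data$route)
  b$procedures <- arrange(b$procedures, .data$patient_id, .data$date,
                          .data$procedure_code)
  b
}

#' Validate a claims bundle
#'
#' Checks the schema, ID uniqueness and referential integrity, ICD-10
#' syntax, prescription interval ordering, and that each patient's birth
#' date precedes all of their event dates.
#'
#' @param bundle a `claims_bundle`.
#' @return the bundle, invisibly; errors describe every violation found.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "claims_bundle"))
  problems <- character(0)
  for (tb in names(BUNDLE_SCHEMA)) {
    missing <- setdiff(BUNDLE_SCHEMA[[tb]], names(bundle[[tb]]))
    if (length(missing)) {
      problems <- c(problems, paste0(tb, ": missing column(s) ",
                                     paste(missing, collapse = ", ")))
    }
  }
  if (length(problems)) abort(paste(problems, collapse = "\n"))

  if (anyDuplicated(bundle$patients$patient_id)) {
    problems <- c(problems, "patients: duplicate patient_id")
  }
  if (anyDuplicated(bundle$hospitals$hospital_id)) {
    problems <- c(problems, "hospitals: duplicate hospital_id")
  }
  for (tb in c("diagnoses", "prescriptions", "procedures")) {
    orphan <- setdiff(bundle[[tb]]$patient_id, bundle$patients$patient_id)
    if (length(orphan)) {
      problems <- c(problems, paste0(
        tb, ": patient_id not in patients: ",
        paste(utils::head(orphan, 5), collapse = ", ")))
    }
  }
  bad_icd <- !grepl("^[A-Z][0-9]{2}[0-9A-Za-z.]*$", bundle$diagnoses$icd10_code)
  if (any(bad_icd)) {
    problems <- c(problems, paste0(
      "diagnoses: invalid ICD-10 code at row(s) ",
      paste(utils::head(which(bad_icd), 5), collapse = ", ")))
  }
  bad_rx <- bundle$prescriptions$end_date < bundle$prescriptions$start_date
  if (any(bad_rx)) {
    problems <- c(problems, paste0(
      "prescriptions: end_date < start_date at row(s) ",
      paste(utils::head(which(bad_rx), 5), collapse = ", ")))
  }
  bad_route <- !bundle$prescriptions$route %in% c("oral", "injectable")
  if (any(bad_route)) {
    problems <- c(problems, paste0(
      "prescriptions: route must be oral/injectable at row(s) ",
      paste(utils::head(which(bad_route), 5), collapse = ", ")))
  }
  inj <- bundle$prescriptions$route == "injectable"
  if (any(inj & bundle$prescriptions$end_date != bundle$prescriptions$start_date)) {
    problems <- c(problems,
                  "prescriptions: injectable records must have end_date == start_date")
  }
  # birth_date precedes every event date of the patient
  ev <- bind_rows(
    select(bundle$diagnoses, "patient_id", date = "date"),
    select(bundle$prescriptions, "patient_id", date = "start_date"),
    select(bundle$procedures, "patient_id", date = "date")
  )
  if (nrow(ev)) {
    first_ev <- summarise(group_by(ev, .data$patient_id),
                          min_date = min(.data$date), .groups = "drop")
    chk <- left_join(first_ev, bundle$patients, by = "patient_id")
    bad <- !is.na(chk$birth_date) & chk$birth_date >= chk$min_date
    if (any(bad)) {
      problems <- c(problems, paste0(
        "patients: birth_date on/after event dates for ",
        paste(utils::head(chk$patient_id[bad], 5), collapse = ", ")))
    }
  }
  if (length(problems)) abort(paste(problems, collapse = "\n"))
  invisible(bundle)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  for (tb in names(BUNDLE_SCHEMA)) {
    cat(sprintf("  %-13s %6d rows\n", tb, nrow(x[[tb]])))
  }
  invisible(x)
}

bundle_cols <- function(table) {
  dates <- BUNDLE_DATE_COLS[[table]]
  cols <- lapply(BUNDLE_SCHEMA[[table]], function(cn) {
    if (cn %in% dates) readr::col_date(format = "%Y-%m-%d")
    else if (cn == "suspected") readr::col_logical()
    else readr::col_character()
  })
  do.call(readr::cols_only, setNames(cols, BUNDLE_SCHEMA[[table]]))
}

#' Read a claims bundle from CSV tables
#'
#' Reads the five comma-delimited tables and returns a validated bundle.
#' Missing columns, unparseable dates (reported with their line numbers) and
#' orphan patient IDs all raise errors; an empty table with a valid header
#' is a valid empty collection.
#'
#' @param dir directory containing `patients.csv`, `hospitals.csv`,
#'   `diagnoses.csv`, `prescriptions.csv`, `procedures.csv`; alternatively
#'   pass `paths` directly.
#' @param paths optional named list/vector of per-table file paths
#'   (names as above), overriding `dir`.
#' @param quiet suppress per-table row-count messages.
#' @return a validated `claims_bundle`.
#' @export
read_bundle <- function(dir = NULL, paths = NULL, quiet = FALSE) {
  if (is.null(paths)) {
    stopifnot(!is.null(dir))
    paths <- setNames(file.path(dir, paste0(names(BUNDLE_SCHEMA), ".csv")),
                      names(BUNDLE_SCHEMA))
  }
  missing <- !file.exists(unlist(paths[names(BUNDLE_SCHEMA)]))
  if (any(missing)) {
    abort(paste0("missing input file(s): ",
                 paste(unlist(paths)[missing], collapse = ", ")))
  }
  tabs <- list()
  for (tb in names(BUNDLE_SCHEMA)) {
    hdr <- names(readr::read_csv(paths[[tb]], n_max = 0, col_types = readr::cols(),
                                 progress = FALSE, show_col_types = FALSE))
    missing_cols <- setdiff(BUNDLE_SCHEMA[[tb]], hdr)
    if (length(missing_cols)) {
      abort(paste0(tb, ": missing column(s) ",
                   paste(missing_cols, collapse = ", ")))
    }
    x <- suppressWarnings(
      readr::read_csv(paths[[tb]], col_types = bundle_cols(tb),
                      progress = FALSE, show_col_types = FALSE))
    probs <- readr::problems(x)
    if (nrow(probs)) {
      # problems() reports the physical file line (header included)
      abort(paste0(tb, ": unparseable value(s), e.g. line ", probs$row[1],
                   " column '", hdr[probs$col[1]], "' (expected ",
                   probs$expected[1], ")"))
    }
    if (!quiet) inform(paste0("read ", tb, ": ", nrow(x), " rows"))
    tabs[[tb]] <- x
  }
  claims_bundle(tabs$patients, tabs$hospitals, tabs$diagnoses,
                tabs$prescriptions, tabs$procedures)
}

#' Write a claims bundle to CSV tables
#'
#' Writes the five tables with normalized row ordering and ISO-8601 dates so
#' that `read_bundle(write_bundle(b))` reproduces `b` exactly. An empty
#' collection writes a header-only file.
#'
#' @param bundle a validated `claims_bundle`.
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths written, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  validate_bundle(bundle)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) abort(paste0("cannot create directory: ", dir))
  bundle <- normalize_bundle(bundle)
  paths <- setNames(file.path(dir, paste0(names(BUNDLE_SCHEMA), ".csv")),
                    names(BUNDLE_SCHEMA))
  for (tb in names(BUNDLE_SCHEMA)) {
    readr::write_csv(bundle[[tb]][, BUNDLE_SCHEMA[[tb]]], paths[[tb]],
                     progress = FALSE)
  }
  invisible(paths)
}
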