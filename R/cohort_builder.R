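# Cohort construction: index date, the six-step eligibility funnel,
# transplant-group assignment and baseline comorbidity mapping.

FUNNEL_CRITERIA <- c(
  mm_diagnosis = "at least one multiple-myeloma (C90) diagnosis",
  index_date = "index drug prescribed in/after first MM diagnosis month",
  followup_6m = "at least 6 months follow-up after index",
  prior_antimyeloma = "no core anti-myeloma drug before index",
  prior_sct = "no stem-cell transplant before index",
  lookback_record = "at least one record in the 3 years before index"
)

# All dated events of every patient, in one long table.
all_event_dates <- function(bundle) {
  bind_rows(
    select(bundle$diagnoses, "patient_id", date = "date"),
    select(bundle$prescriptions, "patient_id", date = "start_date"),
    select(bundle$prescriptions, "patient_id", date = "end_date"),
    select(bundle$procedures, "patient_id", date = "date")
  )
}

# Qualifying MM diagnoses: prefix match on C90, optionally dropping
# suspected (rule-out) records.
mm_diagnoses <- function(diagnoses, config) {
  d <- diagnoses[startsWith(diagnoses$icd10_code, config$cohort$mm_icd10_prefix), ]
  if (isTRUE(config$cohort$exclude_suspected)) d <- d[!d$suspected, ]
  d
}

#' Compute each patient's index date
#'
#' The index date is the earliest prescription date of an index drug
#' (bortezomib, lenalidomide and/or daratumumab by default) falling in the
#' same calendar month as, or a month after, the patient's first qualifying
#' MM (C90) diagnosis. The month-granular comparison is the default because
#' claims diagnosis onset is recorded at month precision; a day-level
#' comparison is available via `cohort$month_granular_index: false`.
#'
#' @param diagnoses,prescriptions record tables (any number of patients).
#' @param config pipeline configuration.
#' @return tibble with `patient_id`, `first_mm_date`, `index_date`; patients
#'   with no qualifying diagnosis or no qualifying prescription get `NA`.
#' @export
compute_index_date <- function(diagnoses, prescriptions, config = default_config()) {
  mm <- mm_diagnoses(diagnoses, config)
  first_mm <- summarise(group_by(mm, .data$patient_id),
                        first_mm_date = min(.data$date), .groups = "drop")
  rx <- prescriptions[tolower(prescriptions$drug) %in%
                        tolower(config$cohort$index_drugs), ]
  cand <- left_join(rx, first_mm, by = "patient_id")
  cand <- cand[!is.na(cand$first_mm_date), ]
  ok <- if (isTRUE(config$cohort$month_granular_index)) {
    month_floor(cand$start_date) >= month_floor(cand$first_mm_date)
  } else {
    cand$start_date >= cand$first_mm_date
  }
  cand <- cand[ok, ]
  idx <- if (nrow(cand)) {
    summarise(group_by(cand, .data$patient_id),
              index_date = min(.data$start_date), .groups = "drop")
  } else {
    tibble(patient_id = character(0), index_date = as.Date(character(0)))
  }
  left_join(first_mm, idx, by = "patient_id")
}

#' Apply the eligibility funnel
#'
#' Applies, in order: (1) at least one qualifying C90 diagnosis; (2) an
#' index date exists; (3) at least 6 calendar months between index and the
#' last data record; (4) no core (non-steroid) anti-myeloma drug before the
#' index date — prior dexamethasone/prednisone is allowed; (5) no stem-cell
#' transplant between the configured exclusion start and the day before
#' index; (6) at least one record of any type within the 3 years before
#' index. Counts telescope: each criterion's entering count equals the
#' previous entering count minus its exclusions.
#'
#' @param bundle a validated `claims_bundle`.
#' @param config pipeline configuration.
#' @return list with `cohort` (one row per eligible patient: index date,
#'   first MM date, follow-up end, age, age category, sex, hospital,
#'   baseline comorbidity list-column) and `funnel` (criterion,
#'   n_entering, n_excluded).
#' @export
apply_eligibility <- function(bundle, config = default_config()) {
  pts <- bundle$patients
  events <- all_event_dates(bundle)
  idx <- compute_index_date(bundle$diagnoses, bundle$prescriptions, config)
  info <- left_join(select(pts, "patient_id", "sex", "birth_date", "hospital_id"),
                    idx, by = "patient_id")

  # follow-up end: last record of any type on/after index
  fu <- left_join(events, select(info, "patient_id", "index_date"),
                  by = "patient_id")
  fu <- fu[!is.na(fu$index_date) & fu$date >= fu$index_date, ]
  fu <- summarise(group_by(fu, .data$patient_id),
                  followup_end = max(.data$date), .groups = "drop")
  info <- left_join(info, fu, by = "patient_id")

  # prior core anti-myeloma exposure (steroids exempt)
  rx <- bundle$prescriptions
  core <- rx[is_core_drug(rx$drug, config), ]
  prior_core <- left_join(core, select(info, "patient_id", "index_date"),
                          by = "patient_id")
  prior_core <- unique(prior_core$patient_id[
    !is.na(prior_core$index_date) & prior_core$start_date < prior_core$index_date])

  # prior SCT in the exclusion window
  proc <- bundle$procedures[bundle$procedures$procedure_code %in%
                              config$cohort$sct_procedure_codes, ]
  prior_sct <- left_join(proc, select(info, "patient_id", "index_date"),
                         by = "patient_id")
  prior_sct <- unique(prior_sct$patient_id[
    !is.na(prior_sct$index_date) &
      prior_sct$date >= config$cohort$sct_exclusion_start &
      prior_sct$date < prior_sct$index_date])

  # any record in the lookback window before index
  lb <- left_join(events, select(info, "patient_id", "index_date"),
                  by = "patient_id")
  lb <- lb[!is.na(lb$index_date), ]
  lb_ok <- unique(lb$patient_id[
    lb$date >= sub_years(lb$index_date, config$cohort$lookback_record_years) &
      lb$date < lb$index_date])

  pass <- list(
    mm_diagnosis = info$patient_id %in% idx$patient_id,
    index_date = !is.na(info$index_date),
    followup_6m = !is.na(info$followup_end) &
      info$followup_end >= add_months(info$index_date,
                                      config$cohort$followup_min_months),
    prior_antimyeloma = !info$patient_id %in% prior_core,
    prior_sct = !info$patient_id %in% prior_sct,
    lookback_record = info$patient_id %in% lb_ok
  )
  # NA comparisons (no index) only occur for rows already excluded upstream
  pass <- lapply(pass, function(p) { p[is.na(p)] <- FALSE; p })

  alive <- rep(TRUE, nrow(info))
  n_entering <- integer(0); n_excluded <- integer(0)
  for (k in names(FUNNEL_CRITERIA)) {
    n_entering <- c(n_entering, sum(alive))
    drop_now <- alive & !pass[[k]]
    n_excluded <- c(n_excluded, sum(drop_now))
    alive <- alive & pass[[k]]
  }
  funnel <- tibble(criterion = names(FUNNEL_CRITERIA),
                   description = unname(FUNNEL_CRITERIA),
                   n_entering = n_entering, n_excluded = n_excluded)

  cohort <- info[alive, ]
  comorb <- map_baseline_comorbidities(
    bundle$diagnoses, select(cohort, "patient_id", "index_date"), config)
  comorb_sets <- split(comorb$category, comorb$patient_id)
  cohort <- mutate(
    cohort,
    age_at_index = age_at(.data$birth_date, .data$index_date),
    age_category = as.character(age_category(.data$age_at_index)),
    baseline_comorbidities = unname(comorb_sets[.data$patient_id])
  )
  cohort$baseline_comorbidities <-
    lapply(cohort$baseline_comorbidities, function(x) x %||% character(0))
  list(cohort = select(cohort, "patient_id", "index_date",
                       first_mm_diagnosis_date = "first_mm_date",
                       "followup_end", "sex", "hospital_id", "age_at_index",
                       "age_category", "baseline_comorbidities"),
       funnel = funnel)
}

#' Map baseline comorbidities
#'
#' A comorbidity category is present when at least one non-suspected
#' diagnosis whose ICD-10 code matches any of the category's prefixes falls
#' in the baseline window `[index - 6 months, index - 1 day]`.
#'
#' @param diagnoses diagnosis records.
#' @param index_dates tibble with `patient_id` and `index_date`.
#' @param config pipeline configuration (for the prefix map and window).
#' @return long tibble `patient_id`, `category` (one row per present
#'   category; categories are not mutually exclusive).
#' @export
map_baseline_comorbidities <- function(diagnoses, index_dates,
                                       config = default_config()) {
  cmap <- tibble(
    category = rep(names(config$comorbidities),
                   lengths(config$comorbidities)),
    prefix = unlist(config$comorbidities, use.names = FALSE)
  )
  d <- diagnoses[!diagnoses$suspected, ]
  d <- left_join(d, index_dates, by = "patient_id")
  d <- d[!is.na(d$index_date) &
           d$date >= sub_months(d$index_date, config$cohort$baseline_months) &
           d$date < d$index_date, ]
  if (nrow(d) == 0) {
    return(tibble(patient_id = character(0), category = character(0)))
  }
  hits <- map(seq_len(nrow(cmap)), function(i) {
    sel <- startsWith(d$icd10_code, cmap$prefix[i])
    tibble(patient_id = d$patient_id[sel], category = cmap$category[i])
  })
  distinct(arrange(bind_rows(hits), .data$patient_id, .data$category))
}

#' Assign transplant / non-transplant group
#'
#' A patient is in the transplant group when at least one stem-cell
#' transplant procedure falls on/after the index date and on/before the
#' follow-up end; transplants recorded after follow-up end are ignored with
#' a warning. The treatment line containing the transplant date (the latest
#' line starting on/before it) is annotated when `lines` are supplied.
#'
#' @param cohort the eligible-cohort tibble from [apply_eligibility()].
#' @param procedures procedure records.
#' @param lines optional treatment-lines tibble from [build_cohort_lines()].
#' @param config pipeline configuration.
#' @return `cohort` with `group` (`"transplant"`/`"non-transplant"`),
#'   `sct_date` and `sct_line` columns.
#' @export
assign_group <- function(cohort, procedures, lines = NULL,
                         config = default_config()) {
  proc <- procedures[procedures$procedure_code %in%
                       config$cohort$sct_procedure_codes, ]
  proc <- left_join(proc,
                    select(cohort, "patient_id", "index_date", "followup_end"),
                    by = "patient_id")
  proc <- proc[!is.na(proc$index_date) & proc$date >= proc$index_date, ]
  late <- proc$date > proc$followup_end
  if (any(late)) {
    warn(paste0("ignoring ", sum(late),
                " SCT record(s) dated after follow-up end"))
    proc <- proc[!late, ]
  }
  first_sct <- if (nrow(proc)) {
    summarise(group_by(proc, .data$patient_id),
              sct_date = min(.data$date), .groups = "drop")
  } else {
    tibble(patient_id = character(0), sct_date = as.Date(character(0)))
  }
  out <- left_join(cohort, first_sct, by = "patient_id")
  out$group <- ifelse(is.na(out$sct_date), "non-transplant", "transplant")
  out$sct_line <- NA_integer_
  if (!is.null(lines) && nrow(lines)) {
    ln <- left_join(lines, first_sct, by = "patient_id")
    ln <- ln[!is.na(ln$sct_date) & ln$start <= ln$sct_date, ]
    if (nrow(ln)) {
      at <- summarise(group_by(ln, .data$patient_id),
                      sct_line = max(.data$line_number), .groups = "drop")
      out$sct_line <- at$sct_line[match(out$patient_id, at$patient_id)]
    }
  }
  out
}
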