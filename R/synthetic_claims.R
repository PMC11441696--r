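# Synthetic claims generator: emits claims bundles with a ground-truth
# sidecar (true eligibility verdicts, line boundaries, segment labels,
# TCE status) so every pipeline stage can be tested without access to a
# proprietary database. The generator plans trajectories first and then
# realizes them as records — oral drugs as cyclic coverage windows,
# injectables as spaced administrations — so the truth is known by
# construction and is never read by the pipeline.

ORAL_DRUGS <- c("lenalidomide", "pomalidomide", "thalidomide", "ixazomib",
                "melphalan", "panobinostat", "dexamethasone", "prednisone")
INJ_INTERVALS <- c(bortezomib = 7, carfilzomib = 14, daratumumab = 7,
                   isatuximab = 14, elotuzumab = 14)

#' Build a simulation scenario
#'
#' The defaults describe the study conditions the pipeline is meant for:
#' a two-group NDMM cohort (about 7% transplant), elderly non-transplant
#' patients (mean age 75) and younger transplant patients (mean 60),
#' per-line regimen mixes echoing the published marginals, most patients
#' stopping after one or two lines, between-line treatment-free gaps
#' strictly above the 90-day transfer threshold and within-line gaps well
#' below it, a small quadruplet-start rate and a roughly 10% first-line
#' bridging rate along the common triple-class pathways.
#'
#' @param ... overrides for any default field (see the function body for
#'   the full list); unknown names are rejected.
#' @return a validated `lot_scenario` list.
#' @export
scenario_config <- function(...) {
  s <- list(
    n_patients = 500,
    transplant_fraction = 0.072,
    male_fraction = 0.52,
    age = list(
      "non-transplant" = c(mean = 75, sd = 9, min = 37, max = 94),
      "transplant" = c(mean = 60, sd = 8, min = 35, max = 73)
    ),
    line_count_probs = list(
      "non-transplant" = c(0.635, 0.271, 0.067, 0.027),
      "transplant" = c(0.406, 0.391, 0.133, 0.070)
    ),
    p_line5_given_4plus = 0.3,
    regimen_freqs = list(
      "non-transplant" = list(
        c("Rd-based" = 0.247, "Vd-based" = 0.238, "RVd-based" = 0.156,
          "DRd-based" = 0.066, "Bor-based" = 0.039, "DVd-based" = 0.030,
          "VMP-based" = 0.028, "Len-based" = 0.026, "IRd-based" = 0.008,
          "Other" = 0.162),
        c("Rd-based" = 0.220, "Vd-based" = 0.098, "DRd-based" = 0.086,
          "Len-based" = 0.069, "Bor-based" = 0.040, "Pd-based" = 0.038,
          "DVd-based" = 0.033, "Dara-based" = 0.030, "IRd-based" = 0.026,
          "Ixa-based" = 0.025, "Kd-based" = 0.020, "Other" = 0.315),
        c("Rd-based" = 0.147, "Len-based" = 0.077, "Kd-based" = 0.071,
          "Pd-based" = 0.071, "Vd-based" = 0.058, "DRd-based" = 0.038,
          "Dara-based" = 0.038, "IRd-based" = 0.032, "Other" = 0.468),
        c("EPd-based" = 0.089, "Rd-based" = 0.067, "DRd-based" = 0.067,
          "DVd-based" = 0.067, "ERd-based" = 0.067, "RVd-based" = 0.044,
          "Other" = 0.599)
      ),
      "transplant" = list(
        c("RVd-based" = 0.495, "Vd-based" = 0.187, "DVd-based" = 0.084,
          "DRd-based" = 0.037, "Rd-based" = 0.028, "Bor-based" = 0.019,
          "KRd-based" = 0.009, "Other" = 0.141),
        c("Rd-based" = 0.255, "Len-based" = 0.164, "DRd-based" = 0.091,
          "Ixa-based" = 0.091, "SPd-based" = 0.091, "DVd-based" = 0.036,
          "ERd-based" = 0.036, "Other" = 0.236),
        c("Len-based" = 0.133, "Vd-based" = 0.067, "DVd-based" = 0.067,
          "Rd-based" = 0.067, "KRd-based" = 0.067, "Other" = 0.599),
        c("Rd-based" = 0.143, "Len-based" = 0.143, "Pd-based" = 0.143,
          "IRd-based" = 0.143, "SKd-based" = 0.143, "Sd-based" = 0.143,
          "Other" = 0.142)
      )
    ),
    duration_median_months = list(
      "non-transplant" = c(10.9, 7.6, 4.5, 5.3),
      "transplant" = c(11.8, 8.1, 8.2, 4.5)
    ),
    duration_sdlog = 0.6,
    duration_range_days = c(70, 720),
    gap_between_range_days = c(100, 250),
    within_gap_days = 7,
    bridge_probability = 0.10,
    pathway_menu = list(c("Vd-based", "DRd-based"),
                        c("RVd-based", "DRd-based"),
                        c("Rd-based", "DVd-based")),
    pathway_weights = c(0.5, 0.3, 0.2),
    quad_start_probability = 0.012,
    suspected_fraction = 0.10,
    comorbidity_prevalence = c(
      renal_dysfunction = 0.155, liver_dysfunction = 0.067,
      cardiac_dysfunction = 0.230, pulmonary_dysfunction = 0.036,
      vascular_disorder = 0.309, back_pain = 0.157, dementia = 0.005),
    index_month_range = c("2015-01", "2020-12"),
    sct_line_probs = c(0.85, 0.15),
    sct_offset_days = 100,
    ineligible_fractions = c(mm_diagnosis = 0, index_date = 0,
                             followup_6m = 0, prior_antimyeloma = 0,
                             prior_sct = 0, lookback_record = 0),
    hospital_bed_probs = c("<=199" = 0.03, "200-499" = 0.49, ">=500" = 0.48),
    hospital_category_probs = c(university = 0.05, public = 0.83,
                                private = 0.12)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(s))
  if (length(unknown)) {
    abort(paste0("unknown scenario field(s): ", paste(unknown, collapse = ", ")))
  }
  s[names(over)] <- over
  validate_scenario(structure(s, class = c("lot_scenario", "list")))
}

validate_scenario <- function(s) {
  stopifnot(s$n_patients >= 1)
  probs <- c(s$transplant_fraction, s$male_fraction, s$bridge_probability,
             s$quad_start_probability, s$suspected_fraction,
             s$p_line5_given_4plus, s$comorbidity_prevalence,
             s$ineligible_fractions, s$pathway_weights)
  if (any(probs < 0 | probs > 1)) abort("scenario probabilities must be in [0, 1]")
  for (g in names(s$line_count_probs)) {
    if (abs(sum(s$line_count_probs[[g]]) - 1) > 1e-6) {
      abort(paste0("line_count_probs for ", g, " must sum to 1"))
    }
    for (fr in s$regimen_freqs[[g]]) {
      if (abs(sum(fr) - 1) > 1e-6) abort("regimen frequencies must sum to 1")
    }
  }
  if (sum(s$ineligible_fractions) > 1) {
    abort("planted ineligible fractions exceed the cohort")
  }
  if (s$gap_between_range_days[1] <= s$within_gap_days) {
    abort("infeasible scenario: between-line gap must exceed within-line gap")
  }
  s
}

#' Named scenario presets
#'
#' * `minimal` — one eligible patient, one Rd line, nothing else.
#' * `paper-like` — the default mixes (500 patients).
#' * `funnel-stress` — 120 patients with 10 planted violations per
#'   eligibility criterion.
#' * `bridging-heavy` — frequent first-line bridging and quadruplet starts,
#'   to exercise the TCE pathway logic.
#'
#' @param name optional preset name; omit to get the full named list.
#' @return a `lot_scenario` (or a named list of them).
#' @export
scenario_presets <- function(name = NULL) {
  presets <- list(
    "minimal" = scenario_config(
      n_patients = 1, transplant_fraction = 0, bridge_probability = 0,
      quad_start_probability = 0, suspected_fraction = 0,
      comorbidity_prevalence = c(renal_dysfunction = 0, liver_dysfunction = 0,
                                 cardiac_dysfunction = 0,
                                 pulmonary_dysfunction = 0,
                                 vascular_disorder = 0, back_pain = 0,
                                 dementia = 0),
      line_count_probs = list("non-transplant" = c(1, 0, 0, 0),
                              "transplant" = c(1, 0, 0, 0)),
      regimen_freqs = list(
        "non-transplant" = rep(list(c("Rd-based" = 1)), 4),
        "transplant" = rep(list(c("Rd-based" = 1)), 4))),
    "paper-like" = scenario_config(),
    "funnel-stress" = scenario_config(
      n_patients = 120,
      ineligible_fractions = c(mm_diagnosis = 1 / 12, index_date = 1 / 12,
                               followup_6m = 1 / 12,
                               prior_antimyeloma = 1 / 12,
                               prior_sct = 1 / 12, lookback_record = 1 / 12)),
    "bridging-heavy" = scenario_config(
      n_patients = 200, bridge_probability = 0.5,
      quad_start_probability = 0.15)
  )
  if (is.null(name)) {
    return(presets)
  }
  if (!name %in% names(presets)) {
    abort(paste0("unknown preset '", name, "'; available: ",
                 paste(names(presets), collapse = ", ")))
  }
  presets[[name]]
}

# ---- realization helpers (integer days internally) ----

# Oral drug as 21-days-on cycles separated by `gap` days off; the last
# window is stretched to end exactly at `e`.
realize_oral <- function(drug, s, e, gap) {
  step <- 21 + gap
  cs <- seq(s, e, by = step)
  ce <- pmin(cs + 20L, e)
  ce[length(ce)] <- e
  tibble(drug = drug, route = "oral", start = as.integer(cs),
         end = as.integer(ce))
}

# Injectable drug as spaced administrations; daratumumab tapers from weekly
# to four-weekly after 8 doses. Imputed coverage (28 d/dose) stays
# continuous because no spacing exceeds 28 days.
realize_injectable <- function(drug, s, e, coverage_days = 28) {
  admins <- integer(0)
  a <- s; i <- 0L
  while (a <= e - (coverage_days - 1L)) {
    admins <- c(admins, a)
    i <- i + 1L
    a <- a + if (drug == "daratumumab" && i >= 8) 28L else
      as.integer(INJ_INTERVALS[[drug]])
  }
  if (length(admins) == 0) admins <- s
  tibble(drug = drug, route = "injectable", start = admins, end = admins)
}

# Realize one regimen over [s, s + dur - 1]; returns records plus the last
# core-covered day (steroid coverage never counts towards the end).
realize_regimen <- function(drugs, s, dur, scenario, coverage_days) {
  e <- s + dur - 1L
  rows <- lapply(drugs, function(dr) {
    if (dr %in% ORAL_DRUGS) {
      realize_oral(dr, s, e, scenario$within_gap_days)
    } else {
      realize_injectable(dr, s, e, coverage_days)
    }
  })
  rx <- bind_rows(rows)
  core <- drugs[!drugs %in% c("dexamethasone", "prednisone")]
  core_end <- max(map_int(core, function(dr) {
    rr <- rx[rx$drug == dr, ]
    if (rr$route[1] == "oral") max(rr$end) else max(rr$end) + coverage_days - 1L
  }))
  list(rx = rx, core_end = core_end)
}

label_members <- function(label, config) {
  if (label == "Other") {
    return(c("daratumumab", "carfilzomib")) # steroid-free pair: no catalogue hit
  }
  config$catalogue$members[[match(label, config$catalogue$label)]]
}

sample_one <- function(x, prob = NULL) {
  if (length(x) == 1) return(x)
  sample(x, 1, prob = prob)
}

# ---- the generator ----

#' Generate a synthetic claims bundle with ground truth
#'
#' Deterministic given `seed`: all randomness flows from one seeded stream
#' and the caller's RNG state is untouched. Planted ineligible patients
#' violate exactly one funnel criterion each; for eligible patients the
#' emitted prescriptions realize the planned lines exactly, with
#' between-line gaps strictly above and within-line gaps strictly below
#' the transfer threshold, so true boundaries are recoverable.
#'
#' @param scenario a `lot_scenario` (see [scenario_config()],
#'   [scenario_presets()]), or a preset name.
#' @param seed integer seed.
#' @param config pipeline configuration the bundle should be analysed with.
#' @return list of class `lot_sim`: `bundle` (a `claims_bundle`) and
#'   `truth` (list of `patients` and `lines` tibbles; the pipeline never
#'   reads it).
#' @export
generate_claims <- function(scenario = scenario_presets("paper-like"),
                            seed = 1, config = default_config()) {
  if (is.character(scenario)) scenario <- scenario_presets(scenario)
  scenario <- validate_scenario(scenario)
  if (scenario$gap_between_range_days[1] <= config$lines$gap_threshold_days) {
    abort("infeasible scenario: between-line gap range must exceed the gap threshold")
  }
  withr::with_seed(seed, generate_impl(scenario, config))
}

generate_impl <- function(scenario, config) {
  n <- scenario$n_patients
  cov_days <- config$lines$injectable_coverage_days
  window_end <- as.integer(config$cohort$study_window_end)

  n_h <- max(3L, ceiling(n / 40))
  hospitals <- tibble(
    hospital_id = sprintf("H%03d", seq_len(n_h)),
    bed_size_class = sample(names(scenario$hospital_bed_probs), n_h,
                            replace = TRUE, prob = scenario$hospital_bed_probs),
    category = sample(names(scenario$hospital_category_probs), n_h,
                      replace = TRUE,
                      prob = scenario$hospital_category_probs)
  )

  # planted violators occupy the tail patient slots, round(n * fraction) each
  viol_counts <- round(n * scenario$ineligible_fractions)
  violated <- rep(NA_character_, n)
  if (sum(viol_counts) > 0) {
    slot <- n - sum(viol_counts) + 1L
    for (k in names(viol_counts)) {
      if (viol_counts[[k]] > 0) {
        violated[seq(slot, slot + viol_counts[[k]] - 1L)] <- k
        slot <- slot + viol_counts[[k]]
      }
    }
  }

  m0 <- ymd(paste0(scenario$index_month_range[1], "-01"))
  m1 <- ymd(paste0(scenario$index_month_range[2], "-01"))
  index_months <- seq(m0, m1, by = "month")

  dx_rows <- list(); rx_rows <- list(); pr_rows <- list()
  pat_rows <- vector("list", n); truth_pat <- vector("list", n)
  truth_line <- list()

  for (i in seq_len(n)) {
    pid <- sprintf("P%05d", i)
    viol <- violated[i]
    group <- if (runif(1) < scenario$transplant_fraction) "transplant" else "non-transplant"
    sex <- if (runif(1) < scenario$male_fraction) "male" else "female"
    agesp <- scenario$age[[group]]
    age <- round(min(max(stats::rnorm(1, agesp["mean"], agesp["sd"]),
                         agesp["min"]), agesp["max"]))
    index <- as.integer(sample_one(index_months)) + sample.int(28, 1) - 1L
    birth <- as.integer(ymd(as.Date(index, origin = "1970-01-01")) %m-%
                          years(age)) - sample(30:300, 1)

    # trajectory plan
    nl_probs <- scenario$line_count_probs[[group]]
    n_lines <- sample_one(seq_along(nl_probs), prob = nl_probs)
    if (n_lines == 4 && runif(1) < scenario$p_line5_given_4plus) n_lines <- 5L
    quad <- runif(1) < scenario$quad_start_probability
    bridge <- !quad && runif(1) < scenario$bridge_probability
    labels <- map_chr(seq_len(n_lines), function(k) {
      fr <- scenario$regimen_freqs[[group]][[min(k, 4)]]
      sample_one(names(fr), prob = fr)
    })
    if (quad) labels[1] <- "D-RVd-based"
    pathway1 <- if (bridge) {
      scenario$pathway_menu[[sample_one(seq_along(scenario$pathway_menu),
                                        prob = scenario$pathway_weights)]]
    } else {
      NULL
    }
    if (viol %in% c("index_date")) {
      labels[] <- "Pd-based"; pathway1 <- NULL; quad <- FALSE
    }
    if (viol %in% c("followup_6m")) {
      n_lines <- 1L; labels <- labels[1]; pathway1 <- NULL
    }
    med_days <- scenario$duration_median_months[[group]] * 30.4375
    durs <- map_int(seq_len(n_lines), function(k) {
      d <- round(rlnorm(1, log(med_days[min(k, 4)]), scenario$duration_sdlog))
      as.integer(min(max(d, scenario$duration_range_days[1]),
                     scenario$duration_range_days[2]))
    })
    if (viol %in% "followup_6m") durs[1] <- 70L
    gaps <- sample(seq(scenario$gap_between_range_days[1],
                       scenario$gap_between_range_days[2]),
                   n_lines, replace = TRUE)

    # realize lines, truncating at the data-window end
    s <- index
    p_rx <- list(); p_lines <- list()
    segs_all <- list()
    for (k in seq_len(n_lines)) {
      if (k > 1 && s + durs[k] + 30L > window_end) {
        n_lines <- k - 1L
        break
      }
      if (k == 1 && !is.null(pathway1)) {
        # durations compatible with weekly schedules so every core drug of
        # the first regimen stops together; the second regimen starts the
        # next day ("sequentially bridged", no treatment-free days)
        d1 <- sample_one(c(70L, 77L, 84L))
        memA <- label_members(pathway1[1], config)
        memB <- label_members(pathway1[2], config)
        ra <- realize_regimen(memA, s, d1, scenario, cov_days)
        sb <- ra$core_end + 1L
        rb <- realize_regimen(memB, sb, durs[1], scenario, cov_days)
        p_rx <- c(p_rx, list(ra$rx, rb$rx))
        e <- max(ra$core_end, rb$core_end)
        segs <- tibble(label = pathway1, seg_start = c(s, sb))
        labels[1] <- pathway1[1]
      } else {
        mem <- label_members(labels[k], config)
        rr <- realize_regimen(mem, s, durs[k], scenario, cov_days)
        p_rx <- c(p_rx, list(rr$rx))
        e <- rr$core_end
        segs <- tibble(label = labels[k], seg_start = s)
      }
      p_lines[[k]] <- tibble(line_number = k, start = s, end = e,
                             label = labels[k])
      segs$line_number <- k
      segs_all[[k]] <- segs
      s <- e + gaps[k]
    }
    lines_tr <- bind_rows(p_lines)
    segs_tr <- bind_rows(segs_all)
    rx <- bind_rows(p_rx)
    rx$patient_id <- pid

    # diagnoses
    dx <- list()
    if (is.na(viol) || viol != "mm_diagnosis") {
      mm_date <- if (!is.na(viol) && viol == "lookback_record") {
        index
      } else {
        as.integer(month_floor(as.Date(index, origin = "1970-01-01")))
      }
      dx <- c(dx, list(tibble(patient_id = pid, icd10_code = "C90",
                              date = mm_date, suspected = FALSE)))
    } else {
      # only a suspected (rule-out) record: excluded from case finding
      dx <- c(dx, list(tibble(patient_id = pid, icd10_code = "C90",
                              date = index - 45L, suspected = TRUE)))
    }
    if ((is.na(viol) || !viol %in% c("mm_diagnosis", "lookback_record")) &&
        runif(1) < scenario$suspected_fraction) {
      dx <- c(dx, list(tibble(patient_id = pid, icd10_code = "C90",
                              date = index - 75L, suspected = TRUE)))
    }
    comorbs <- character(0)
    if (is.na(viol) || viol != "lookback_record") {
      for (cc in names(scenario$comorbidity_prevalence)) {
        if (runif(1) < scenario$comorbidity_prevalence[[cc]]) {
          comorbs <- c(comorbs, cc)
          dx <- c(dx, list(tibble(
            patient_id = pid,
            icd10_code = sample_one(config$comorbidities[[cc]]),
            date = index - sample(30:150, 1), suspected = FALSE)))
        }
      }
      # anchor visit guaranteeing a record in the 3-year lookback
      dx <- c(dx, list(tibble(patient_id = pid, icd10_code = "Z00",
                              date = index - sample(40:360, 1),
                              suspected = FALSE)))
    }

    # follow-up visits after the last line (criterion 3 needs >= 6 months)
    last_end <- max(lines_tr$end)
    if (is.na(viol) || viol != "followup_6m") {
      censor <- max(last_end + sample(60:400, 1),
                    as.integer(add_months(as.Date(index, origin = "1970-01-01"), 7)))
      censor <- min(censor, window_end)
      dx <- c(dx, list(tibble(patient_id = pid, icd10_code = "Z00",
                              date = censor, suspected = FALSE)))
    } else {
      censor <- last_end
    }

    # procedures + violation-specific records
    prc <- list()
    sct_date <- NA_integer_
    if (is.na(viol) && group == "transplant") {
      sct_line <- min(sample_one(c(1L, 2L), prob = scenario$sct_line_probs),
                      n_lines)
      ls <- lines_tr$start[sct_line]; le <- lines_tr$end[sct_line]
      sct_date <- min(ls + scenario$sct_offset_days, le)
      prc <- c(prc, list(tibble(patient_id = pid, procedure_code = "SCT-AUTO",
                                date = sct_date)))
      # conditioning melphalan two days before transplant
      rx <- bind_rows(rx, tibble(drug = "melphalan", route = "oral",
                                 start = sct_date - 2L, end = sct_date - 2L,
                                 patient_id = pid))
    }
    if (!is.na(viol) && viol == "prior_sct") {
      prc <- c(prc, list(tibble(patient_id = pid, procedure_code = "SCT-AUTO",
                                date = index - 300L)))
    }
    if (!is.na(viol) && viol == "prior_antimyeloma") {
      rx <- bind_rows(rx, tibble(drug = "thalidomide", route = "oral",
                                 start = index - 400L, end = index - 390L,
                                 patient_id = pid))
    }

    pat_rows[[i]] <- tibble(patient_id = pid, sex = sex,
                            birth_date = birth,
                            hospital_id = sample_one(hospitals$hospital_id))
    dx_rows[[i]] <- bind_rows(dx)
    rx_rows[[i]] <- rx
    if (length(prc)) pr_rows[[length(pr_rows) + 1]] <- bind_rows(prc)

    # ground truth (planned, by construction)
    eligible <- is.na(viol)
    classes_by_line <- map(seq_len(max(lines_tr$line_number)), function(k) {
      labs <- segs_tr$label[segs_tr$line_number <= k]
      drugs <- unique(unlist(map(labs, label_members, config = config)))
      cl <- classify_drug(drugs, config)
      sort(unique(cl[cl %in% CORE_CLASSES]))
    })
    tce_by_line <- map_lgl(classes_by_line, function(cl) all(TCE_CLASSES %in% cl))
    first_tce <- if (any(tce_by_line)) min(which(tce_by_line)) else NA_integer_
    truth_pat[[i]] <- tibble(
      patient_id = pid, eligible = eligible,
      violated_criterion = viol,
      index_date = if (eligible || !viol %in% c("mm_diagnosis", "index_date"))
        as.Date(index, origin = "1970-01-01") else as.Date(NA),
      group = if (eligible) group else NA_character_,
      age = as.integer(age), sex = sex,
      n_lines = if (eligible) max(lines_tr$line_number) else NA_integer_,
      first_tce_line = if (eligible) first_tce else NA_integer_,
      quad_start = eligible && quad,
      most_recent_line = if (eligible) max(lines_tr$line_number) else NA_integer_,
      sct_line = if (eligible && group == "transplant") {
        max(lines_tr$line_number[lines_tr$start <= sct_date])
      } else NA_integer_,
      comorbidities = paste(sort(comorbs), collapse = ";"),
      followup_end = as.Date(max(censor, last_end), origin = "1970-01-01")
    )
    if (eligible) {
      lt <- lines_tr
      lt$patient_id <- pid
      lt$segments <- map_chr(lt$line_number, function(k) {
        paste(segs_tr$label[segs_tr$line_number == k], collapse = "->")
      })
      truth_line[[length(truth_line) + 1]] <- lt
    }
  }

  to_date <- function(x) as.Date(x, origin = "1970-01-01")
  patients <- bind_rows(pat_rows)
  patients$birth_date <- to_date(patients$birth_date)
  dxs <- bind_rows(dx_rows); dxs$date <- to_date(dxs$date)
  rxs <- bind_rows(rx_rows)
  rxs <- tibble(patient_id = rxs$patient_id, drug = rxs$drug,
                route = rxs$route, start_date = to_date(rxs$start),
                end_date = to_date(rxs$end))
  prs <- if (length(pr_rows)) {
    p <- bind_rows(pr_rows); p$date <- to_date(p$date); p
  } else {
    tibble(patient_id = character(0), procedure_code = character(0),
           date = as.Date(character(0)))
  }
  bundle <- claims_bundle(patients, hospitals, dxs, rxs, prs)
  tl <- bind_rows(truth_line)
  truth_lines <- if (nrow(tl)) {
    tibble(patient_id = tl$patient_id, line_number = tl$line_number,
           start = to_date(tl$start), end = to_date(tl$end),
           label = tl$label, segments = tl$segments)
  } else {
    tibble(patient_id = character(0), line_number = integer(0),
           start = as.Date(character(0)), end = as.Date(character(0)),
           label = character(0), segments = character(0))
  }
  structure(list(bundle = bundle,
                 truth = list(patients = bind_rows(truth_pat),
                              lines = truth_lines)),
            class = "lot_sim")
}

#' @export
print.lot_sim <- function(x, ...) {
  cat("<lot_sim> ", nrow(x$bundle$patients), " patients (",
      sum(x$truth$patients$eligible), " eligible by construction)\n", sep = "")
  print(x$bundle)
  invisible(x)
}

#' Write a simulation to disk
#'
#' Writes the bundle CSVs plus the ground-truth sidecars
#' (`truth_patients.csv`, `truth_lines.csv`). The sidecars exist for test
#' harnesses only; the analysis pipeline never reads them.
#'
#' @param sim a `lot_sim` from [generate_claims()].
#' @param dir output directory.
#' @return named vector of file paths, invisibly.
#' @export
write_sim <- function(sim, dir) {
  paths <- write_bundle(sim$bundle, dir)
  tp <- file.path(dir, "truth_patients.csv")
  tl <- file.path(dir, "truth_lines.csv")
  readr::write_csv(sim$truth$patients, tp, progress = FALSE)
  readr::write_csv(sim$truth$lines, tl, progress = FALSE)
  invisible(c(paths, truth_patients = tp, truth_lines = tl))
}
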