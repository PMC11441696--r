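test_that("index date follows the same-month rule", {
  cfg <- test_cfg()
  dx <- dx_row("C90", "2016-03-10")
  # same calendar month, earlier day: qualifies
  idx <- compute_index_date(dx, rx_row("bortezomib", "2016-03-02",
                                       route = "injectable"), cfg)
  expect_equal(idx$index_date, as.Date("2016-03-02"))
  # month before diagnosis month: no index
  idx <- compute_index_date(dx, rx_row("lenalidomide", "2016-02-20",
                                       "2016-03-20"), cfg)
  expect_true(is.na(idx$index_date))
  # minimum over qualifying index-drug prescriptions
  rx <- dplyr::bind_rows(
    rx_row("daratumumab", "2016-05-01", route = "injectable"),
    rx_row("bortezomib", "2016-04-15", route = "injectable"),
    rx_row("pomalidomide", "2016-04-01", "2016-04-20")) # not an index drug
  idx <- compute_index_date(dx, rx, cfg)
  # brute-force: earliest start among index drugs in/after the dx month
  brute <- min(rx$start_date[tolower(rx$drug) %in% cfg$cohort$index_drugs &
                               format(rx$start_date, "%Y-%m") >= "2016-03"])
  expect_equal(idx$index_date, as.Date("2016-04-15"))
  expect_equal(idx$index_date, brute)
  # suspected diagnoses do not start the clock
  idx <- compute_index_date(
    dplyr::bind_rows(dx_row("C90", "2016-01-05", suspected = TRUE), dx),
    rx_row("bortezomib", "2016-02-10", route = "injectable"), cfg)
  expect_true(is.na(idx$index_date))
})

make_eligible <- function(extra_dx = NULL, extra_rx = NULL, extra_pr = NULL,
                          followup_months = 12) {
  dx <- dplyr::bind_rows(
    dx_row("C90", "2018-01-05"),
    dx_row("Z00", "2017-06-01"),
    dx_row("Z00", as.character(lubridate::add_with_rollback(
      as.Date("2018-01-10"), months(followup_months)))),
    extra_dx)
  rx <- dplyr::bind_rows(
    rx_row("lenalidomide", "2018-01-10", "2018-06-30"),
    rx_row("dexamethasone", "2018-01-10", "2018-06-30"),
    extra_rx)
  one_patient_bundle(diagnoses = dx, prescriptions = rx,
                     procedures = extra_pr)
}

test_that("eligibility criteria fire at the documented steps", {
  cfg <- test_cfg()
  excluded_at <- function(bundle) {
    f <- apply_eligibility(bundle, cfg)$funnel
    f$criterion[f$n_excluded > 0]
  }
  expect_equal(nrow(apply_eligibility(make_eligible(), cfg)$cohort), 1L)

  # prior core anti-myeloma drug
  b <- make_eligible(extra_rx = rx_row("thalidomide", "2014-06-01",
                                       "2014-07-01"))
  expect_identical(excluded_at(b), "prior_antimyeloma")

  # prior steroid exposure alone never fires criterion 4
  b <- make_eligible(extra_rx = rx_row("dexamethasone", "2016-02-01",
                                       "2016-03-01"))
  expect_equal(nrow(apply_eligibility(b, cfg)$cohort), 1L)

  # short follow-up
  expect_identical(excluded_at(make_eligible(followup_months = 5)),
                   "followup_6m")

  # SCT before index
  b <- make_eligible(extra_pr = pr_row("SCT-AUTO", "2016-08-01"))
  expect_identical(excluded_at(b), "prior_sct")

  # SCT before the exclusion window start is allowed
  b <- make_eligible(extra_pr = pr_row("SCT-AUTO", "2008-03-01"))
  expect_equal(nrow(apply_eligibility(b, cfg)$cohort), 1L)

  # no record in the 3 years before index
  dx <- dplyr::bind_rows(dx_row("C90", "2018-01-10"),
                         dx_row("Z00", "2019-06-01"))
  rx <- dplyr::bind_rows(rx_row("lenalidomide", "2018-01-10", "2018-06-30"))
  b <- one_patient_bundle(diagnoses = dx, prescriptions = rx)
  expect_identical(excluded_at(b), "lookback_record")
})

test_that("funnel telescopes and matches planted violations", {
  sim <- generate_claims("funnel-stress", seed = 7)
  f <- apply_eligibility(sim$bundle, test_cfg())$funnel
  # telescoping
  expect_equal(f$n_entering[-1], (f$n_entering - f$n_excluded)[-nrow(f)])
  # exclusions equal planted counts per criterion, in order
  planted <- table(sim$truth$patients$violated_criterion)
  expect_equal(f$n_excluded, as.integer(planted[f$criterion]))
  # final cohort + all exclusions = patients entering
  expect_equal(sum(f$n_excluded) + nrow(apply_eligibility(sim$bundle)$cohort),
               f$n_entering[1])
})

test_that("cohort derivation is invariant to input row order", {
  sim <- generate_claims(scenario_config(n_patients = 30), seed = 9)
  b <- sim$bundle
  shuf <- claims_bundle(
    b$patients[sample(nrow(b$patients)), ],
    b$hospitals[sample(nrow(b$hospitals)), ],
    b$diagnoses[sample(nrow(b$diagnoses)), ],
    b$prescriptions[sample(nrow(b$prescriptions)), ],
    if (nrow(b$procedures) > 1) {
      b$procedures[sample(nrow(b$procedures)), ]
    } else {
      b$procedures
    })
  a <- apply_eligibility(b, test_cfg())
  s <- apply_eligibility(shuf, test_cfg())
  expect_equal(a$funnel, s$funnel)
  expect_equal(dplyr::arrange(a$cohort, patient_id)$index_date,
               dplyr::arrange(s$cohort, patient_id)$index_date)
})

test_that("baseline comorbidity mapping respects window and prefixes", {
  cfg <- test_cfg()
  idx <- tibble::tibble(patient_id = "P1",
                        index_date = as.Date("2019-06-15"))
  # inside the window
  got <- map_baseline_comorbidities(dx_row("I50", "2019-04-10"), idx, cfg)
  expect_equal(got$category, "cardiac_dysfunction")
  # 8 months pre-index: outside
  got <- map_baseline_comorbidities(dx_row("N18", "2018-10-10"), idx, cfg)
  expect_equal(nrow(got), 0L)
  # several categories at once, one month pre-index
  dx <- dplyr::bind_rows(dx_row("I10", "2019-05-10"),
                         dx_row("N18", "2019-05-10"),
                         dx_row("M54", "2019-05-10"))
  got <- map_baseline_comorbidities(dx, idx, cfg)
  expect_setequal(got$category, c("vascular_disorder", "renal_dysfunction",
                                  "back_pain"))
  # suspected records never map
  got <- map_baseline_comorbidities(dx_row("I50", "2019-04-10",
                                           suspected = TRUE), idx, cfg)
  expect_equal(nrow(got), 0L)
})

test_that("transplant group and SCT line attribution", {
  cfg <- test_cfg()
  b <- make_eligible(extra_pr = pr_row("SCT-AUTO", "2018-04-10"))
  res <- apply_eligibility(b, cfg)
  lines <- build_cohort_lines(b, res$cohort, cfg)$lines
  grp <- assign_group(res$cohort, b$procedures, lines, cfg)
  expect_identical(grp$group, "transplant")
  expect_identical(grp$sct_line, 1L)

  # no SCT record
  grp <- assign_group(res$cohort, make_eligible()$procedures, lines, cfg)
  expect_identical(grp$group, "non-transplant")

  # an SCT recorded after the follow-up end is ignored with a warning
  late_sct <- pr_row("SCT-AUTO", "2022-01-01")
  expect_warning(
    grp2 <- assign_group(res$cohort, late_sct, lines, cfg),
    "after follow-up")
  expect_identical(grp2$group, "non-transplant")

  # SCT in a generated second line matches the planted truth
  sim <- paper_sim(); run <- paper_run()
  tr <- sim$truth$patients
  got <- run$cohort[!is.na(run$cohort$sct_line), ]
  expect_gt(nrow(got), 0)
  expect_equal(got$sct_line,
               tr$sct_line[match(got$patient_id, tr$patient_id)])
  expect_equal(run$cohort$group,
               tr$group[match(run$cohort$patient_id, tr$patient_id)])
})

test_that("age at index uses completed years", {
  cfg <- test_cfg()
  b <- make_eligible()
  b$patients$birth_date <- as.Date("1950-01-11") # day after index anniversary
  res <- apply_eligibility(b, cfg)
  expect_equal(res$cohort$age_at_index, 67L)
  b$patients$birth_date <- as.Date("1950-01-10")
  expect_equal(apply_eligibility(b, cfg)$cohort$age_at_index, 68L)
})
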