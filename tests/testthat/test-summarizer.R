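test_that("percent applies half-up rounding with the study conventions", {
  expect_equal(percent(605, 1656), 36.5)
  expect_equal(percent(0, 128), 0)
  expect_equal(percent(56, 128), 43.8)  # 43.75 rounds up
  expect_equal(percent(350, 1656), 21.1)
  expect_equal(percent(3, 73, digits = 0), 4)
  expect_warning(out <- percent(1, 0), "zero denominator")
  expect_true(is.na(out))
  expect_equal(round_half_up(c(0.05, 0.15, -0.05), 1), c(0.1, 0.2, -0.1))
})

test_that("characteristics table matches independent statistics", {
  run <- paper_run()
  tab <- run$tables$characteristics
  co <- run$cohort
  for (g in unique(co$group)) {
    sub <- co[co$group == g, ]
    age <- tab[tab$group == g & tab$section == "age_years", ]
    expect_equal(age$value[age$item == "median"],
                 as.numeric(stats::median(sub$age_at_index)))
    expect_equal(age$value[age$item == "mean"], mean(sub$age_at_index))
    expect_equal(age$value[age$item == "max"], max(sub$age_at_index))
    sex <- tab[tab$group == g & tab$section == "sex", ]
    expect_equal(sex$n[sex$item == "male"], sum(sub$sex == "male"))
    # age category counts partition the group
    ac <- tab[tab$group == g & tab$section == "age_category", ]
    expect_equal(sum(ac$n), nrow(sub))
    # follow-up months = inclusive days / 30.4375
    fu <- tab[tab$group == g & tab$section == "followup_months", ]
    expect_equal(fu$value[fu$item == "median"],
                 as.numeric(stats::median(
                   (as.integer(sub$followup_end - sub$index_date) + 1) /
                     30.4375)))
  }
  # planted comorbidity truth
  tr <- paper_sim()$truth$patients
  m <- match(co$patient_id, tr$patient_id)
  planted <- strsplit(tr$comorbidities[m], ";")
  expect_equal(lapply(co$baseline_comorbidities, sort),
               lapply(planted, function(x) sort(x[nzchar(x)])))
})

test_that("single-patient and empty-group tables render without error", {
  sim <- generate_claims("minimal", seed = 2)
  run <- run_pipeline(sim$bundle, quiet = TRUE)
  tab <- run$tables$characteristics
  expect_equal(tab$n[tab$section == "n"], 1L)
  lc <- run$tables$line_counts
  expect_equal(lc$n[lc$table == "cumulative" & lc$line == "1"], 1L)
  expect_equal(sum(lc$n[lc$table == "cumulative" & lc$line != "1"]), 0L)
})

test_that("line tables satisfy the cumulative/most-recent identity", {
  run <- paper_run()
  lc <- run$tables$line_counts
  tr <- paper_sim()$truth$patients
  for (g in unique(lc$group)) {
    cum <- lc[lc$group == g & lc$table == "cumulative", ]
    rec <- lc[lc$group == g & lc$table == "most_recent", ]
    cum_n <- cum$n[match(c("1", "2", "3", "4+"), cum$line)]
    rec_n <- rec$n[match(c("1", "2", "3", "4+"), rec$line)]
    expect_equal(rec_n, cum_n - c(cum_n[-1], 0))
    # equals generator truth
    sub <- tr[tr$eligible & tr$group == g, ]
    expect_equal(cum_n, vapply(1:4, function(k) {
      if (k < 4) sum(sub$n_lines >= k) else sum(sub$n_lines >= 4)
    }, numeric(1)))
    expect_equal(rec_n[1:3], vapply(1:3, function(k) {
      sum(sub$most_recent_line == k)
    }, numeric(1)))
  }
})

test_that("duration table strata partition the overall distribution", {
  run <- paper_run()
  dt <- run$tables$duration
  lines <- run$lines
  expect_equal(dt$median[dt$group == "non-transplant" & dt$line == 1 &
                           dt$stratum == "overall"],
               as.numeric(stats::median(
                 lines$duration_months[lines$line_number == 1 &
                   lines$patient_id %in%
                     run$cohort$patient_id[run$cohort$group == "non-transplant"]]
               )))
  for (i in seq_len(nrow(dt))) {
    if (dt$stratum[i] == "overall") {
      sub <- dt[dt$group == dt$group[i] & dt$line == dt$line[i], ]
      expect_equal(sub$n[sub$stratum == "overall"],
                   sum(sub$n[sub$stratum != "overall"]))
    }
  }
  # directed: a 61-day line is 2.00 months
  expect_equal(round(line_duration_months(as.Date("2021-01-01"),
                                          as.Date("2021-03-02")), 2), 2.00)
})

test_that("regimen tables recover planted label frequencies", {
  run <- paper_run()
  tr <- paper_sim()$truth
  rt <- run$tables$regimens
  truth_l1 <- tr$lines[tr$lines$line_number == 1, ]
  grp <- tr$patients$group[match(truth_l1$patient_id, tr$patients$patient_id)]
  for (g in unique(rt$group)) {
    want <- table(truth_l1$label[grp == g])
    got <- rt[rt$group == g & rt$line == 1, ]
    expect_equal(sum(got$n), got$denominator[1])
    for (lab in names(want)) {
      expect_equal(got$n[got$label == lab], as.integer(want[[lab]]),
                   info = paste(g, lab))
    }
    expect_identical(got$label[nrow(got)], "Other")
  }
  # custom induction-context denominators
  rt2 <- regimen_table(run$lines,
                       dplyr::select(run$cohort, patient_id, group),
                       test_cfg(),
                       denominators = list("transplant" = c(107L, 55L, 15L, 7L)))
  t1 <- rt2[rt2$group == "transplant" & rt2$line == 1, ]
  expect_true(all(t1$denominator == 107L))
  expect_equal(t1$pct, percent(t1$n, 107))
})

test_that("stratified regimens split by age and by comorbidity", {
  cfg <- test_cfg()
  cohort <- tibble::tibble(
    patient_id = c("A", "B"), age_category = c("75-84", "18-64"),
    baseline_comorbidities = list(c("renal_dysfunction", "back_pain"),
                                  character(0)))
  lines <- tibble::tibble(
    patient_id = c("A", "B"), line_number = 1L,
    line_regimen_label = c("Rd-based", "RVd-based"))
  by_age <- stratified_regimens(lines, cohort, "age_category", cfg)
  old <- by_age[by_age$stratum == "75-84", ]
  expect_equal(old$n, 1L)
  expect_equal(old$pct, 100)
  expect_identical(old$label, "Rd-based")
  by_com <- stratified_regimens(lines, cohort, "comorbidity", cfg)
  # patient A appears under both of its comorbidity strata
  expect_setequal(by_com$stratum, c("renal_dysfunction", "back_pain"))
  expect_equal(sum(by_com$n), 2L)
  expect_error(stratified_regimens(lines, cohort, "hospital", cfg),
               "unknown strata")
})

test_that("every emitted percentage re-derives from its counts", {
  run <- paper_run()
  expect_true(audit_percentages(run$tables, test_cfg()))
  # a corrupted cell fails the audit
  broken <- run$tables
  broken$regimens$pct[1] <- broken$regimens$pct[1] + 0.1
  expect_error(audit_percentages(broken, test_cfg()), "audit failed")
})
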