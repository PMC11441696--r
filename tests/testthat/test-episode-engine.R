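test_that("coverage intervals merge oral windows and imputed injections", {
  cfg <- test_cfg()
  # single oral window, inclusive endpoints
  cov <- coverage_intervals(rx_row("lenalidomide", "2020-01-01",
                                   "2020-01-21"), cfg)
  expect_equal(as.integer(cov$end - cov$start) + 1L, 21L)
  # weekly injections with 28-day coverage merge into one 42-day interval
  rx <- dplyr::bind_rows(
    rx_row("bortezomib", "2020-01-01", route = "injectable"),
    rx_row("bortezomib", "2020-01-08", route = "injectable"),
    rx_row("bortezomib", "2020-01-15", route = "injectable"))
  cov <- coverage_intervals(rx, cfg)
  expect_equal(nrow(cov), 1L)
  # day-set enumeration oracle
  days <- sort(unique(unlist(lapply(as.integer(rx$start_date),
                                    function(s) seq(s, s + 27)))))
  expect_equal(as.integer(cov$end - cov$start) + 1L, length(days))
  expect_equal(length(days), 42L)
  # two oral windows 40 days apart stay distinct
  rx <- dplyr::bind_rows(rx_row("lenalidomide", "2020-01-01", "2020-01-21"),
                         rx_row("lenalidomide", "2020-03-02", "2020-03-20"))
  expect_equal(nrow(coverage_intervals(rx, cfg)), 2L)
})

test_that("gap rule splits lines; short gaps bridge within a line", {
  cfg <- test_cfg()
  d0 <- as.Date("2020-01-01")
  vd <- function(from, to) dplyr::bind_rows(
    rx_row("bortezomib", as.character(d0 + from), as.character(d0 + to)),
    rx_row("dexamethasone", as.character(d0 + from), as.character(d0 + to)))
  drd <- function(from, to) dplyr::bind_rows(
    rx_row("daratumumab", as.character(d0 + from), as.character(d0 + to)),
    rx_row("lenalidomide", as.character(d0 + from), as.character(d0 + to)),
    rx_row("dexamethasone", as.character(d0 + from), as.character(d0 + to)))

  # continuous Rd: one line
  rx <- dplyr::bind_rows(
    rx_row("lenalidomide", "2020-01-01", "2020-10-27"),
    rx_row("dexamethasone", "2020-01-01", "2020-10-27"))
  res <- build_lines(rx, d0, cfg)
  expect_equal(nrow(res$lines), 1L)
  expect_identical(res$lines$line_regimen_label, "Rd-based")

  # 119-day treatment-free gap: two lines
  res <- build_lines(dplyr::bind_rows(vd(0, 180), drd(300, 400)), d0, cfg)
  expect_equal(nrow(res$lines), 2L)
  expect_equal(res$lines$start, d0 + c(0, 300))
  expect_equal(res$lines$end, d0 + c(180, 400))
  expect_identical(res$lines$line_regimen_label, c("Vd-based", "DRd-based"))

  # 9-day gap: one line, bridged Vd -> DRd
  res <- build_lines(dplyr::bind_rows(vd(0, 120), drd(130, 250)), d0, cfg)
  expect_equal(nrow(res$lines), 1L)
  segs <- res$segments
  expect_identical(segs$label, c("Vd-based", "DRd-based"))
  expect_identical(segs$kind, c("initial", "bridge"))
})

test_that("segments capture add-on, de-escalation and bridging", {
  cfg <- test_cfg()
  d0 <- as.Date("2020-01-01")
  # RVd formation window, bortezomib stops at day 100 -> Rd de-escalation
  rx <- dplyr::bind_rows(
    rx_row("lenalidomide", "2020-01-01", "2020-08-01"),
    rx_row("dexamethasone", "2020-01-01", "2020-08-01"),
    rx_row("bortezomib", "2020-01-01", "2020-04-10"))
  segs <- build_lines(rx, d0, cfg)$segments
  expect_identical(segs$label, c("RVd-based", "Rd-based"))
  expect_identical(segs$kind, c("initial", "de-escalation"))
  expect_equal(segs$start[2], as.Date("2020-04-11"))

  # Vd window; daratumumab+lenalidomide start day 70 as bortezomib ends
  rx <- dplyr::bind_rows(
    rx_row("bortezomib", "2020-01-01", "2020-03-10"),
    rx_row("dexamethasone", "2020-01-01", "2020-08-01"),
    rx_row("daratumumab", "2020-03-11", "2020-08-01"),
    rx_row("lenalidomide", "2020-03-11", "2020-08-01"))
  segs <- build_lines(rx, d0, cfg)$segments
  expect_identical(segs$label, c("Vd-based", "DRd-based"))
  expect_identical(segs$kind, c("initial", "bridge"))

  # add-on: daratumumab joins Rd after the window
  rx <- dplyr::bind_rows(
    rx_row("lenalidomide", "2020-01-01", "2020-08-01"),
    rx_row("dexamethasone", "2020-01-01", "2020-08-01"),
    rx_row("daratumumab", "2020-04-01", "2020-08-01"))
  segs <- build_lines(rx, d0, cfg)$segments
  expect_identical(segs$label, c("Rd-based", "DRd-based"))
  expect_identical(segs$kind, c("initial", "add-on"))

  # a drug starting inside the window joins the initial regimen
  rx <- dplyr::bind_rows(
    rx_row("lenalidomide", "2020-01-01", "2020-08-01"),
    rx_row("dexamethasone", "2020-01-01", "2020-08-01"),
    rx_row("bortezomib", "2020-02-10", "2020-08-01"))
  segs <- build_lines(rx, d0, cfg)$segments
  expect_identical(segs$label, "RVd-based")
})

test_that("duration uses inclusive days over 30.4375", {
  expect_equal(line_duration_months(as.Date("2020-01-01"),
                                    as.Date("2020-01-01")),
               1 / 30.4375)
  expect_equal(line_duration_months(as.Date("2020-01-01"),
                                    as.Date("2020-03-01")),
               61 / 30.4375, tolerance = 1e-12)
  expect_equal(round(61 / 30.4375, 2), 2.00)
  expect_error(line_duration_months(as.Date("2020-01-02"),
                                    as.Date("2020-01-01")),
               "precedes")
})

test_that("most recent line is the last line started before censoring", {
  lines <- tibble::tibble(line_number = 1:3,
                          start = as.Date("2020-01-01") + c(0, 200, 400))
  expect_equal(most_recent_line(lines, as.Date("2021-06-01")), 3)
  expect_equal(most_recent_line(lines[1, ], as.Date("2020-06-01")), 1)
  expect_equal(most_recent_line(lines, as.Date("2020-08-01")), 2)
})

test_that("conditioning melphalan near SCT never reaches labels or coverage", {
  cfg <- test_cfg()
  d0 <- as.Date("2020-01-01")
  rx <- dplyr::bind_rows(
    rx_row("lenalidomide", "2020-01-01", "2020-05-30"),
    rx_row("dexamethasone", "2020-01-01", "2020-05-30"),
    rx_row("melphalan", "2020-04-08", "2020-04-08"))
  with_mel <- build_lines(rx, d0, cfg)
  cond <- build_lines(rx, d0, cfg, sct_dates = as.Date("2020-04-10"))
  expect_identical(cond$lines$line_regimen_label, "Rd-based")
  expect_equal(nrow(cond$segments), 1L)
  # without an SCT nearby the melphalan opens a real segment
  expect_gt(nrow(with_mel$segments), 1L)
})

test_that("steroid-only coverage neither extends a line nor bridges a gap", {
  cfg <- test_cfg()
  d0 <- as.Date("2020-01-01")
  rx <- dplyr::bind_rows(
    rx_row("bortezomib", "2020-01-01", "2020-03-31"),
    rx_row("dexamethasone", "2020-01-01", "2020-12-31"), # steroid continues
    rx_row("lenalidomide", "2020-08-01", "2020-12-01"))
  res <- build_lines(rx, d0, cfg)
  # gap between bortezomib end (Mar 31) and lenalidomide start (Aug 1)
  # exceeds 90 days despite continuous dexamethasone: two lines
  expect_equal(nrow(res$lines), 2L)
  expect_equal(res$lines$end[1], as.Date("2020-03-31"))
})

test_that("engine agrees with the brute-force day-set oracle", {
  cfg <- test_cfg()
  set.seed(4711)
  n_checked <- 0
  for (i in seq_len(1000)) {
    rx <- random_trajectory(cfg)
    index <- min(rx$start_date)
    got <- build_lines(rx, index, cfg)
    want <- oracle_lines(rx, index, cfg)
    expect_equal(nrow(got$lines), nrow(want))
    expect_equal(got$lines$start, want$start)
    expect_equal(got$lines$end, want$end)
    # TCE flags from segments match the raw prescription scan
    exp_lines <- cumulative_class_exposure(
      dplyr::mutate(got$lines, patient_id = "X"))
    expect_equal(exp_lines$tce, oracle_tce_flags(rx, got$lines$end, cfg))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 1000)
})

test_that("lines partition coverage and counts are monotone", {
  run <- paper_run()
  by_pat <- split(run$lines, run$lines$patient_id)
  for (ln in by_pat) {
    expect_true(all(ln$start <= ln$end))
    expect_equal(ln$line_number, seq_len(nrow(ln)))
    if (nrow(ln) > 1) {
      expect_true(all(ln$start[-1] > ln$end[-nrow(ln)]))
    }
  }
  # line 1 starts at the index date
  l1 <- run$lines[run$lines$line_number == 1, ]
  expect_equal(l1$start,
               run$cohort$index_date[match(l1$patient_id,
                                           run$cohort$patient_id)])
  # patients reaching line k+1 are a subset of those reaching line k
  nl <- table(factor(run$lines$line_number, levels = 1:10))
  expect_true(all(diff(as.integer(nl)) <= 0))
})
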