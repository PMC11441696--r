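# Summary tables with the study conventions: percentages rounded half-up
# at one decimal (integer for the approval-era analysis), durations in
# months via the 30.4375 divisor, and explicit denominator columns so every
# percentage can be re-derived from its counts.

group_sizes <- function(groups) {
  summarise(group_by(groups, .data$group), n = dplyr::n(), .groups = "drop")
}

#' Patient characteristics table
#'
#' By group: age summaries and categories, sex, baseline comorbidity
#' categories, hospital size and category, and follow-up months
#' (inclusive days from index to follow-up end divided by 30.4375).
#'
#' @param cohort eligible cohort with `group` (from [assign_group()]).
#' @param hospitals hospital attribute records.
#' @param config pipeline configuration.
#' @return long tibble `group`, `section`, `item`, `n`, `denominator`,
#'   `pct`, `value` — count rows carry `n`/`pct`, continuous rows carry
#'   `value` with `item` naming the statistic.
#' @export
characteristics_table <- function(cohort, hospitals, config = default_config()) {
  ch <- left_join(cohort, hospitals, by = "hospital_id")
  digits <- config$summary$percent_digits
  div <- config$summary$months_divisor
  cat_row <- function(g, section, item, n, den) {
    tibble(group = g, section = section, item = item, n = n,
           denominator = den, pct = percent(n, den, digits),
           value = NA_real_)
  }
  num_rows <- function(g, section, x) {
    s <- summary_stats(x)
    tibble(group = g, section = section, item = s$statistic, n = NA_integer_,
           denominator = NA_integer_, pct = NA_real_, value = s$value)
  }
  out <- lapply(split(ch, ch$group), function(g) {
    gn <- nrow(g)
    grp <- g$group[1]
    fu <- (as.integer(g$followup_end - g$index_date) + 1L) / div
    comorb <- unlist(g$baseline_comorbidities)
    bind_rows(
      tibble(group = grp, section = "n", item = "patients", n = gn,
             denominator = gn, pct = percent(gn, gn, digits),
             value = NA_real_),
      num_rows(grp, "age_years", g$age_at_index),
      bind_rows(lapply(levels(age_category(0)), function(lv) {
        cat_row(grp, "age_category", lv, sum(g$age_category == lv), gn)
      })),
      bind_rows(lapply(c("male", "female"), function(s) {
        cat_row(grp, "sex", s, sum(g$sex == s), gn)
      })),
      bind_rows(lapply(names(config$comorbidities), function(cc) {
        cat_row(grp, "comorbidity", cc, sum(comorb == cc), gn)
      })),
      bind_rows(lapply(unique(hospitals$bed_size_class), function(bs) {
        cat_row(grp, "hospital_size", bs, sum(g$bed_size_class == bs), gn)
      })),
      bind_rows(lapply(unique(hospitals$category), function(hc) {
        cat_row(grp, "hospital_category", hc, sum(g$category == hc), gn)
      })),
      num_rows(grp, "followup_months", fu)
    )
  })
  bind_rows(out)
}

#' Baseline diagnosis history table
#'
#' Restricted to patients with at least one non-suspected, non-myeloma
#' diagnosis record during the baseline window; counts patients per
#' three-character ICD-10 code with that restricted denominator.
#'
#' @param diagnoses diagnosis records.
#' @param cohort eligible cohort with `group`.
#' @param config pipeline configuration.
#' @param top_n keep the `top_n` most frequent codes per group (default 10).
#' @return tibble `group`, `icd10_code`, `n`, `denominator`, `pct`.
#' @export
comorbidity_history_table <- function(diagnoses, cohort,
                                      config = default_config(), top_n = 10) {
  d <- diagnoses[!diagnoses$suspected &
                   !startsWith(diagnoses$icd10_code,
                               config$cohort$mm_icd10_prefix), ]
  d <- left_join(d, select(cohort, "patient_id", "index_date", "group"),
                 by = "patient_id")
  d <- d[!is.na(d$index_date) &
           d$date >= sub_months(d$index_date, config$cohort$baseline_months) &
           d$date < d$index_date, ]
  d$code3 <- substr(d$icd10_code, 1, 3)
  digits <- config$summary$percent_digits
  out <- lapply(split(d, d$group), function(g) {
    den <- dplyr::n_distinct(g$patient_id)
    cc <- count(distinct(g, .data$patient_id, .data$code3), .data$code3,
                name = "n")
    cc <- utils::head(arrange(cc, dplyr::desc(.data$n), .data$code3), top_n)
    tibble(group = g$group[1], icd10_code = cc$code3, n = cc$n,
           denominator = den, pct = percent(cc$n, den, digits))
  })
  bind_rows(out)
}

#' Cumulative and most-recent treatment-line tables
#'
#' Cumulative counts are patients who reached each line (lines 4 and beyond
#' bucketed as `"4+"`); most-recent counts are patients whose highest line
#' is each line. Both use the group's 1st-line N as denominator, so
#' `most_recent(k) = cumulative(k) - cumulative(k+1)` holds by construction.
#'
#' @param lines cohort lines tibble.
#' @param groups tibble `patient_id`, `group`.
#' @param config pipeline configuration.
#' @return tibble `group`, `table` (`cumulative`/`most_recent`), `line`,
#'   `n`, `denominator`, `pct`.
#' @export
line_tables <- function(lines, groups, config = default_config()) {
  digits <- config$summary$percent_digits
  nl <- summarise(group_by(lines, .data$patient_id),
                  n_lines = max(.data$line_number), .groups = "drop")
  nl <- left_join(nl, groups, by = "patient_id")
  out <- lapply(split(nl, nl$group), function(g) {
    gn <- nrow(g)
    rows <- lapply(1:4, function(k) {
      line_lab <- if (k < 4) as.character(k) else "4+"
      cum <- sum(g$n_lines >= k)
      rec <- if (k < 4) sum(g$n_lines == k) else sum(g$n_lines >= 4)
      bind_rows(
        tibble(group = g$group[1], table = "cumulative", line = line_lab,
               n = cum, denominator = gn, pct = percent(cum, gn, digits)),
        tibble(group = g$group[1], table = "most_recent", line = line_lab,
               n = rec, denominator = gn, pct = percent(rec, gn, digits))
      )
    })
    bind_rows(rows)
  })
  arrange(bind_rows(out), .data$group, .data$table, .data$line)
}

#' Duration-of-treatment table
#'
#' Per group and line 1–4 (exactly line 4, not a bucket): median, minimum
#' and maximum treatment duration in months — overall and stratified by
#' whether a subsequent line was prescribed.
#'
#' @param lines cohort lines tibble (with `duration_months`).
#' @param groups tibble `patient_id`, `group`.
#' @param config pipeline configuration.
#' @return tibble `group`, `line`, `stratum` (`overall`, `prescribed`,
#'   `not_prescribed`), `n`, `median`, `min`, `max`.
#' @export
duration_table <- function(lines, groups, config = default_config()) {
  nl <- summarise(group_by(lines, .data$patient_id),
                  n_lines = max(.data$line_number), .groups = "drop")
  ln <- left_join(left_join(lines, nl, by = "patient_id"), groups,
                  by = "patient_id")
  ln <- ln[ln$line_number <= 4, ]
  ln$has_next <- ln$line_number < ln$n_lines
  strat_row <- function(g, line, stratum, x) {
    tibble(group = g, line = line, stratum = stratum, n = length(x),
           median = if (length(x)) median(x) else NA_real_,
           min = if (length(x)) min(x) else NA_real_,
           max = if (length(x)) max(x) else NA_real_)
  }
  out <- lapply(split(ln, list(ln$group, ln$line_number), drop = TRUE),
                function(g) {
    bind_rows(
      strat_row(g$group[1], g$line_number[1], "overall", g$duration_months),
      strat_row(g$group[1], g$line_number[1], "prescribed",
                g$duration_months[g$has_next]),
      strat_row(g$group[1], g$line_number[1], "not_prescribed",
                g$duration_months[!g$has_next])
    )
  })
  arrange(bind_rows(out), .data$group, .data$line)
}

#' Regimen-by-line table
#'
#' Counts and percentages of the formation-window regimen label per line
#' (1–4) and group, catalogue labels ordered by frequency with `"Other"`
#' last. Denominators default to the number of patients in the
#' corresponding line; they can be overridden per group with a named list
#' of integer vectors (e.g. an induction-context subset for the transplant
#' group), since some published tables restrict the transplant denominators
#' in ways the data alone cannot reconstruct.
#'
#' @param lines cohort lines tibble.
#' @param groups tibble `patient_id`, `group`.
#' @param config pipeline configuration.
#' @param denominators optional named list `group -> integer vector`
#'   indexed by line number.
#' @return tibble `group`, `line`, `label`, `n`, `denominator`, `pct`.
#' @export
regimen_table <- function(lines, groups, config = default_config(),
                          denominators = NULL) {
  digits <- config$summary$percent_digits
  ln <- left_join(lines, groups, by = "patient_id")
  ln <- ln[ln$line_number <= 4, ]
  out <- lapply(split(ln, list(ln$group, ln$line_number), drop = TRUE),
                function(g) {
    grp <- g$group[1]; k <- g$line_number[1]
    den <- nrow(g)
    if (!is.null(denominators) && !is.null(denominators[[grp]]) &&
        length(denominators[[grp]]) >= k && !is.na(denominators[[grp]][k])) {
      den <- denominators[[grp]][k]
    }
    cc <- count(g, label = .data$line_regimen_label, name = "n")
    cc <- arrange(cc, .data$label == "Other", dplyr::desc(.data$n), .data$label)
    tibble(group = grp, line = k, label = cc$label, n = cc$n,
           denominator = den, pct = percent(cc$n, den, digits))
  })
  arrange(bind_rows(out), .data$group, .data$line)
}

#' First-line regimens stratified by age or comorbidity
#'
#' @param lines cohort lines tibble.
#' @param cohort eligible cohort (with `age_category` and the baseline
#'   comorbidity list-column); subset it to one group first if desired.
#' @param strata `"age_category"` or `"comorbidity"`; comorbidity strata
#'   are non-exclusive, so a patient may appear in several and row sums may
#'   exceed the cohort size.
#' @param config pipeline configuration.
#' @return tibble `stratum`, `label`, `n`, `denominator`, `pct`.
#' @export
stratified_regimens <- function(lines, cohort, strata = "age_category",
                                config = default_config()) {
  digits <- config$summary$percent_digits
  l1 <- lines[lines$line_number == 1, ]
  if (strata == "age_category") {
    key <- select(cohort, "patient_id", stratum = "age_category")
  } else if (strata == "comorbidity") {
    key <- tidyr::unnest(
      select(cohort, "patient_id", stratum = "baseline_comorbidities"),
      "stratum")
  } else {
    abort(paste0("unknown strata '", strata,
                 "'; use 'age_category' or 'comorbidity'"))
  }
  dat <- dplyr::inner_join(l1, key, by = "patient_id",
                           relationship = "many-to-many")
  out <- lapply(split(dat, dat$stratum), function(g) {
    den <- nrow(g)
    cc <- count(g, label = .data$line_regimen_label, name = "n")
    cc <- arrange(cc, .data$label == "Other", dplyr::desc(.data$n), .data$label)
    tibble(stratum = g$stratum[1], label = cc$label, n = cc$n,
           denominator = den, pct = percent(cc$n, den, digits))
  })
  bind_rows(out)
}

#' Self-consistency audit of emitted tables
#'
#' Re-derives every percentage column from its count and denominator
#' columns through [percent()] and checks equality; the TCE table's two
#' denominator conventions are both audited.
#'
#' @param tables the `tables` list from [run_pipeline()].
#' @param config pipeline configuration.
#' @return `TRUE` invisibly, or an error naming the first inconsistency.
#' @export
audit_percentages <- function(tables, config = default_config()) {
  digits <- config$summary$percent_digits
  check <- function(tbl, name) {
    sel <- !is.na(tbl$denominator) & tbl$denominator > 0
    again <- percent(tbl$n[sel], tbl$denominator[sel], digits)
    if (!isTRUE(all.equal(again, tbl$pct[sel]))) {
      abort(paste0("audit failed: ", name))
    }
  }
  for (nm in intersect(names(tables),
                       c("characteristics", "history", "line_counts",
                         "regimens", "regimens_by_age",
                         "regimens_by_comorbidity"))) {
    tbl <- tables[[nm]]
    if (all(c("n", "denominator", "pct") %in% names(tbl))) check(tbl, nm)
  }
  if (!is.null(tables$tce)) {
    tt <- tables$tce
    for (g in unique(tt$group)) {
      gt <- tt[tt$group == g, ]
      n1 <- gt$n_total[gt$line == "1"]
      ok_line <- gt$n_total > 0
      if (!isTRUE(all.equal(percent(gt$n_tce_line[ok_line],
                                    gt$n_total[ok_line], digits),
                            gt$pct_tce_line[ok_line])) ||
          !isTRUE(all.equal(percent(gt$n_tce_cumulative, rep(n1, nrow(gt)),
                                    digits),
                            gt$pct_tce_cumulative))) {
        abort("audit failed: tce table")
      }
    }
  }
  if (!is.null(tables$era)) {
    et <- tables$era
    sel <- et$n > 0
    if (!isTRUE(all.equal(percent(et$n_dara_combo[sel], et$n[sel],
                                  config$summary$era_percent_digits),
                          et$pct[sel]))) {
      abort("audit failed: era table")
    }
  }
  invisible(TRUE)
}
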