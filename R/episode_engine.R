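# Episode engine: drug coverage, treatment-line construction, regimen
# segmentation and durations.
#
# Line-transfer rule (T1, default): a new line opens at the first core-drug
# start date with no core-drug coverage anywhere in the preceding
# `gap_threshold_days` (90 by default). An optional novel-class trigger
# (T2, off by default) additionally opens a line when a core drug of a
# class absent from the current line starts after the formation window;
# T2 is off because within-line regimen "bridging" (e.g. Vd to DRd in one
# line) is a real phenomenon a class trigger would forbid.
#
# Steroid-only coverage never extends a line's end and never bridges a gap:
# the engine works on core-drug coverage only and brings steroids back in
# solely for regimen labelling.

#' Per-drug covered-day intervals
#'
#' Oral prescriptions cover their inclusive `[start_date, end_date]`
#' window; injectable administrations (single-day records) are imputed to
#' cover `injectable_coverage_days` from each administration (default 28, a
#' typical cycle length — claims carry only administration dates, so some
#' persistence assumption is unavoidable). Overlapping or touching
#' intervals of the same drug are merged.
#'
#' @param prescriptions prescription records for one patient.
#' @param config pipeline configuration.
#' @return tibble `drug`, `start`, `end` (Date), merged per drug.
#' @export
coverage_intervals <- function(prescriptions, config = default_config()) {
  rx <- prescriptions
  if (nrow(rx) == 0) {
    return(tibble(drug = character(0), start = as.Date(character(0)),
                  end = as.Date(character(0))))
  }
  cov_days <- config$lines$injectable_coverage_days
  end <- dplyr::if_else(rx$route == "injectable",
                        rx$start_date + cov_days - 1L, rx$end_date)
  pieces <- lapply(split(seq_len(nrow(rx)), tolower(rx$drug)), function(i) {
    m <- merge_intervals(as.integer(rx$start_date[i]), as.integer(end[i]))
    tibble(drug = tolower(rx$drug[i][1]),
           start = as.Date(m$start, origin = "1970-01-01"),
           end = as.Date(m$end, origin = "1970-01-01"))
  })
  arrange(bind_rows(pieces), .data$drug, .data$start)
}

# Drop melphalan records within +/- conditioning_window_days of any SCT
# date: high-dose conditioning around transplant is not regimen membership
# and must not extend coverage or create spurious M-containing labels.
drop_conditioning_melphalan <- function(rx, sct_dates, config) {
  if (length(sct_dates) == 0) {
    return(rx)
  }
  mel <- tolower(rx$drug) == "melphalan"
  if (!any(mel)) {
    return(rx)
  }
  w <- config$lines$conditioning_window_days
  near <- map_lgl(seq_len(nrow(rx)), function(i) {
    mel[i] && any(abs(as.integer(rx$start_date[i] - sct_dates)) <= w)
  })
  rx[!near, ]
}

#' Build one patient's treatment lines
#'
#' Applies the gap-based transfer rule to the patient's post-index core-drug
#' prescriptions. Line 1 starts at the index date; each line ends on its
#' last core-covered day before the next line's start (or overall). Core
#' drugs starting on the same day after a qualifying gap open one line
#' jointly.
#'
#' @param prescriptions the patient's prescription records (on/after index).
#' @param index_date the patient's index date.
#' @param config pipeline configuration.
#' @param sct_dates optional SCT dates, used to discard conditioning
#'   melphalan.
#' @return list with `lines` (line_number, start, end, duration_months,
#'   line_regimen_label, classes list-column) and `segments` (line_number,
#'   segment_index, start, end, label, kind, drugs list-column).
#' @export
build_lines <- function(prescriptions, index_date, config = default_config(),
                        sct_dates = as.Date(character(0))) {
  rx <- prescriptions[prescriptions$start_date >= index_date, ]
  rx <- drop_conditioning_melphalan(rx, sct_dates, config)
  core_rx <- rx[is_core_drug(rx$drug, config), ]
  if (nrow(core_rx) == 0) {
    abort("empty treatment history: no core anti-myeloma prescription on/after index")
  }
  gap <- config$lines$gap_threshold_days
  fw <- config$lines$formation_window_days
  cov <- coverage_intervals(core_rx, config)
  cs <- as.integer(cov$start); ce <- as.integer(cov$end)
  starts <- sort(unique(as.integer(core_rx$start_date)))

  line_start <- starts[1]
  line_classes <- unique(classify_drug(
    core_rx$drug[as.integer(core_rx$start_date) == line_start], config))
  bounds <- line_start
  for (d in starts[-1]) {
    d_classes <- unique(classify_drug(
      core_rx$drug[as.integer(core_rx$start_date) == d], config))
    t1 <- !any_overlap(cs, ce, d - gap, d - 1)
    t2 <- isTRUE(config$lines$novel_class_trigger) &&
      (d - line_start) > fw && !all(d_classes %in% line_classes)
    if (t1 || t2) {
      bounds <- c(bounds, d)
      line_start <- d
      line_classes <- d_classes
    } else {
      line_classes <- union(line_classes, d_classes)
    }
  }

  n_lines <- length(bounds)
  ends <- integer(n_lines)
  for (k in seq_len(n_lines)) {
    hi <- if (k < n_lines) bounds[k + 1] - 1L else max(ce)
    sel <- cs <= hi & ce >= bounds[k]
    ends[k] <- max(pmin(ce[sel], hi))
  }

  seg_list <- vector("list", n_lines)
  for (k in seq_len(n_lines)) {
    seg <- segment_line(rx, as.Date(bounds[k], origin = "1970-01-01"),
                        as.Date(ends[k], origin = "1970-01-01"), config)
    seg$line_number <- k
    seg_list[[k]] <- seg
  }
  segments <- bind_rows(seg_list)
  lines <- tibble(
    line_number = seq_len(n_lines),
    start = as.Date(bounds, origin = "1970-01-01"),
    end = as.Date(ends, origin = "1970-01-01"),
    duration_months = line_duration_months(
      as.Date(bounds, origin = "1970-01-01"),
      as.Date(ends, origin = "1970-01-01"),
      config$summary$months_divisor),
    line_regimen_label = map_chr(seq_len(n_lines), function(k) {
      segments$label[segments$line_number == k][1]
    }),
    classes = map(seq_len(n_lines), function(k) {
      drugs <- unique(unlist(segments$drugs[segments$line_number == k]))
      sort(unique(classify_drug(drugs, config)[
        classify_drug(drugs, config) %in% CORE_CLASSES]))
    })
  )
  list(lines = lines, segments = select(
    segments, "line_number", "segment_index", "start", "end", "label",
    "kind", "drugs"))
}

#' Split a treatment line into regimen segments
#'
#' The initial segment is labelled from every core drug (plus steroids)
#' started within the 56-day formation window after line start. A later
#' core-drug start, or a core drug's discontinuation, opens a new segment;
#' events inside the formation window never split the initial segment.
#'
#' Cyclic dosing must not read as regimen change: a drug's coverage lapse
#' of at most `refill_gap_days` (default 30 — longer than an oral
#' off-cycle week, shorter than the line-transfer threshold) counts as
#' continuation, and a drug stopping within `refill_gap_days` of the line
#' end is a ragged stop, not a de-escalation. Consecutive segments with
#' the same drug set are merged, and spans with no core coverage are
#' dropped.
#'
#' @param prescriptions the patient's prescriptions (core and steroid).
#' @param line_start,line_end line boundaries (Dates).
#' @param config pipeline configuration.
#' @return tibble `segment_index`, `start`, `end`, `label`, `kind`
#'   (`initial`, `add-on`, `de-escalation`, `bridge`), `drugs` list-column.
#' @export
segment_line <- function(prescriptions, line_start, line_end,
                         config = default_config()) {
  fw_end <- as.integer(line_start) + config$lines$formation_window_days - 1L
  ls <- as.integer(line_start); le <- as.integer(line_end)
  rx <- prescriptions[prescriptions$start_date >= line_start &
                        prescriptions$start_date <= line_end, ]
  core_rx <- rx[is_core_drug(rx$drug, config), ]
  ster_rx <- rx[is_steroid(rx$drug, config), ]
  stopifnot(nrow(core_rx) > 0)

  allow <- config$lines$refill_gap_days
  cov <- merge_with_allowance(coverage_intervals(core_rx, config), allow)
  cov$start <- pmax(cov$start, ls)
  cov$end <- pmin(cov$end, le)
  scov <- merge_with_allowance(coverage_intervals(ster_rx, config), allow)
  scov$end <- pmin(scov$end, le)

  initial_core <- unique(tolower(core_rx$drug[
    as.integer(core_rx$start_date) <= fw_end]))
  initial_ster <- unique(tolower(ster_rx$drug[
    as.integer(ster_rx$start_date) <= fw_end]))

  bp_start <- cov$start[cov$start > fw_end]
  bp_stop <- cov$end[cov$end < le & le - cov$end > allow] + 1L
  bps <- sort(unique(c(bp_start, bp_stop[bp_stop > fw_end])))
  bps <- bps[bps > ls & bps <= le]

  seg_bounds <- c(ls, bps)
  seg_ends <- c(bps - 1L, le)
  segs <- vector("list", length(seg_bounds))
  for (j in seq_along(seg_bounds)) {
    a <- seg_bounds[j]; b <- seg_ends[j]
    if (j == 1) {
      core_set <- initial_core
      ster_set <- initial_ster
    } else {
      core_set <- unique(cov$drug[cov$start <= b & cov$end >= a])
      ster_set <- unique(scov$drug[scov$start <= b & scov$end >= a])
    }
    segs[[j]] <- list(start = a, end = b, core = sort(core_set),
                      ster = sort(ster_set))
  }
  segs <- segs[lengths(map(segs, "core")) > 0]

  # merge consecutive segments with identical core + steroid sets
  merged <- list(segs[[1]])
  for (j in seq_along(segs)[-1]) {
    prev <- merged[[length(merged)]]
    if (identical(prev$core, segs[[j]]$core) &&
        identical(prev$ster, segs[[j]]$ster)) {
      merged[[length(merged)]]$end <- segs[[j]]$end
    } else {
      merged <- c(merged, segs[j])
    }
  }

  kinds <- "initial"
  if (length(merged) > 1) {
    for (j in seq_along(merged)[-1]) {
      prev <- merged[[j - 1]]$core; cur <- merged[[j]]$core
      kinds <- c(kinds, if (all(prev %in% cur) && length(cur) > length(prev)) {
        "add-on"
      } else if (all(cur %in% prev) && length(cur) < length(prev)) {
        "de-escalation"
      } else {
        "bridge"
      })
    }
  }
  tibble(
    segment_index = seq_along(merged),
    start = as.Date(map_int(merged, "start"), origin = "1970-01-01"),
    end = as.Date(map_int(merged, "end"), origin = "1970-01-01"),
    label = map_chr(merged, function(s) {
      label_regimen(c(s$core, s$ster), config)
    }),
    kind = kinds,
    drugs = map(merged, function(s) c(s$core, s$ster))
  )
}

#' Treatment duration in months
#'
#' Inclusive day count divided by 30.4375 (the mean calendar-month length),
#' unrounded; a single-day line has positive duration.
#'
#' @param start,end line boundary dates (vectors), with `start <= end`.
#' @param months_divisor days per month (default 30.4375).
#' @return numeric vector of month durations.
#' @export
#' @examples
#' line_duration_months(as.Date("2020-01-01"), as.Date("2020-03-01"))
line_duration_months <- function(start, end, months_divisor = 30.4375) {
  days <- as.integer(end - start) + 1L
  if (any(days < 1)) abort("line end precedes line start")
  days / months_divisor
}

#' Most recent treatment line
#'
#' @param lines one patient's lines tibble.
#' @param followup_end the patient's follow-up end date.
#' @return the highest line number whose start is on/before `followup_end`.
#' @export
most_recent_line <- function(lines, followup_end) {
  stopifnot(nrow(lines) >= 1)
  max(lines$line_number[lines$start <= followup_end])
}

#' Build treatment lines for a whole cohort
#'
#' Runs [build_lines()] per eligible patient and stacks the results.
#'
#' @param bundle a `claims_bundle`.
#' @param cohort the eligible-cohort tibble from [apply_eligibility()].
#' @param config pipeline configuration.
#' @return list with cohort-level `lines` and `segments` tibbles (both
#'   keyed by `patient_id`).
#' @export
build_cohort_lines <- function(bundle, cohort, config = default_config()) {
  rx_by <- split(bundle$prescriptions,
                 factor(bundle$prescriptions$patient_id,
                        levels = cohort$patient_id))
  sct <- bundle$procedures[bundle$procedures$procedure_code %in%
                             config$cohort$sct_procedure_codes, ]
  sct_by <- split(sct$date, factor(sct$patient_id, levels = cohort$patient_id))
  out_lines <- vector("list", nrow(cohort))
  out_segs <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    res <- build_lines(rx_by[[pid]], cohort$index_date[i], config,
                       sct_dates = sct_by[[pid]])
    res$lines$patient_id <- pid
    res$segments$patient_id <- pid
    out_lines[[i]] <- res$lines
    out_segs[[i]] <- res$segments
  }
  lines <- bind_rows(out_lines)
  segments <- bind_rows(out_segs)
  list(
    lines = select(lines, "patient_id", "line_number", "start", "end",
                   "duration_months", "line_regimen_label", "classes"),
    segments = select(segments, "patient_id", "line_number", "segment_index",
                      "start", "end", "label", "kind", "drugs")
  )
}
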