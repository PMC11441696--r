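# Triple-class exposure (TCE): per-line and cumulative flags, pathways to
# first TCE, and approval-era splits of daratumumab-combination initiation.
#
# "Received" a class means at least one prescription or administration of a
# drug in that class on/after index — a single day suffices. A patient is
# TCE at line k when the cumulative classes through the end of line k cover
# IMiD, PI and anti-CD38; the flag is attributed to the line whose segments
# complete the triple.

DARA_COMBO_LABELS <- c("D-RVd-based", "DVd-based", "D-VMP-based", "DRd-based")

#' Cumulative drug-class exposure per line
#'
#' @param lines cohort lines tibble from [build_cohort_lines()] (needs the
#'   `classes` list-column).
#' @return `lines` with `cum_classes` (classes through the end of each
#'   line) and logical `tce` per line; flags are monotone within a patient.
#' @export
cumulative_class_exposure <- function(lines) {
  lines <- arrange(lines, .data$patient_id, .data$line_number)
  out <- lapply(split(seg_idx <- seq_len(nrow(lines)), lines$patient_id),
                function(i) {
    acc <- character(0)
    cum <- vector("list", length(i))
    for (j in seq_along(i)) {
      acc <- sort(union(acc, lines$classes[[i[j]]]))
      cum[[j]] <- acc
    }
    cum
  })
  lines$cum_classes <- unsplit_list(out, lines$patient_id)
  lines$tce <- map_lgl(lines$cum_classes, function(cl) all(TCE_CLASSES %in% cl))
  lines
}

# split()/unsplit for list results keyed by patient.
unsplit_list <- function(pieces, f) {
  out <- vector("list", length(f))
  idx <- split(seq_along(f), f)
  for (k in names(pieces)) out[idx[[k]]] <- pieces[[k]]
  out
}

#' Per-patient TCE status
#'
#' Derives, for every patient: the first line at which the triple is
#' complete (`first_tce_line`, `NA` when never TCE), whether TCE was reached
#' by the initial formation-window regimen of line 1 alone (`quad_start`,
#' e.g. a D-RVd quadruplet) versus within-line/between-line sequencing, and
#' the ordered pathway of segment labels up to and including the segment
#' completing the triple (consecutive duplicate labels collapsed).
#'
#' @param lines,segments cohort tibbles from [build_cohort_lines()].
#' @param config pipeline configuration.
#' @return list with `per_line` (lines plus `cum_classes`/`tce`) and
#'   `patients` (one row per patient: `n_lines`, `first_tce_line`,
#'   `tce_ever`, `quad_start`, `pathway`, `first_line_label`).
#' @export
tce_status <- function(lines, segments, config = default_config()) {
  per_line <- cumulative_class_exposure(lines)
  segments <- arrange(segments, .data$patient_id, .data$line_number,
                      .data$segment_index)
  pat_ids <- unique(per_line$patient_id)
  seg_by <- split(segments, factor(segments$patient_id, levels = pat_ids))
  line_by <- split(per_line, factor(per_line$patient_id, levels = pat_ids))

  rows <- lapply(pat_ids, function(pid) {
    ln <- line_by[[pid]]
    sg <- seg_by[[pid]]
    first_tce <- if (any(ln$tce)) min(ln$line_number[ln$tce]) else NA_integer_
    seg_classes <- map(sg$drugs, function(d) {
      cl <- classify_drug(d, config)
      sort(unique(cl[cl %in% CORE_CLASSES]))
    })
    quad <- all(TCE_CLASSES %in% seg_classes[[1]])
    pathway <- NA_character_
    if (!is.na(first_tce)) {
      acc <- character(0)
      upto <- 0
      for (j in seq_len(nrow(sg))) {
        acc <- union(acc, seg_classes[[j]])
        if (all(TCE_CLASSES %in% acc)) { upto <- j; break }
      }
      labs <- sg$label[seq_len(upto)]
      labs <- labs[c(TRUE, labs[-1] != labs[-length(labs)])]
      pathway <- paste(labs, collapse = "->")
    }
    tibble(patient_id = pid, n_lines = max(ln$line_number),
           first_tce_line = first_tce, tce_ever = !is.na(first_tce),
           quad_start = quad && identical(first_tce, 1L),
           pathway = pathway,
           first_line_label = ln$line_regimen_label[ln$line_number == 1])
  })
  list(per_line = per_line, patients = bind_rows(rows))
}

#' Per-line and cumulative TCE counts by group
#'
#' Reproduces the two denominator conventions of the TCE summary: the
#' per-line percentage uses the number of patients in the corresponding
#' treatment line, the cumulative percentage uses the number of patients in
#' the 1st line. Lines 5 and beyond are bucketed as `"5+"`; there the
#' per-line flag is the patient's flag at their final line.
#'
#' @param status output of [tce_status()].
#' @param groups tibble `patient_id`, `group`.
#' @param config pipeline configuration.
#' @return tibble `group`, `line`, `n_total`, `n_tce_line`, `pct_tce_line`,
#'   `n_tce_cumulative`, `pct_tce_cumulative`.
#' @export
tce_tables <- function(status, groups, config = default_config()) {
  st <- left_join(status$patients, groups, by = "patient_id")
  digits <- config$summary$percent_digits
  per_line <- left_join(status$per_line,
                        select(st, "patient_id", "group"), by = "patient_id")
  rows <- lapply(split(st, st$group), function(g) {
    n1 <- nrow(g)
    pl <- per_line[per_line$group == g$group[1], ]
    out <- lapply(1:5, function(k) {
      if (k < 5) {
        tot <- sum(g$n_lines >= k)
        tce_k <- sum(pl$tce[pl$line_number == k])
        cum_k <- sum(!is.na(g$first_tce_line) & g$first_tce_line <= k)
        line_lab <- as.character(k)
      } else {
        reach <- g$n_lines >= 5
        tot <- sum(reach)
        tce_k <- sum(reach & g$tce_ever)
        cum_k <- sum(g$tce_ever)
        line_lab <- "5+"
      }
      tibble(group = g$group[1], line = line_lab, n_total = tot,
             n_tce_line = tce_k,
             pct_tce_line = if (tot > 0) percent(tce_k, tot, digits) else NA_real_,
             n_tce_cumulative = cum_k,
             pct_tce_cumulative = percent(cum_k, n1, digits))
    })
    bind_rows(out)
  })
  bind_rows(rows)
}

#' TCE pathways and the quadruplet-vs-sequencing split
#'
#' Among patients who are TCE in the 1st line, splits quadruplet starters
#' (the initial formation-window regimen already spans all three classes)
#' from sequencing patients (two or more regimen segments needed), and
#' tabulates the ordered pathway strings.
#'
#' @param status output of [tce_status()].
#' @param config pipeline configuration.
#' @return list with `split` (kind, n, pct) and `pathways`
#'   (pathway, n, pct), percentages over 1st-line TCE patients.
#' @export
tce_pathways <- function(status, config = default_config()) {
  st <- status$patients
  first_line <- st[!is.na(st$first_tce_line) & st$first_tce_line == 1, ]
  digits <- config$summary$percent_digits
  n <- nrow(first_line)
  split_tbl <- tibble(
    kind = c("quad_start", "sequencing"),
    n = c(sum(first_line$quad_start), sum(!first_line$quad_start))
  )
  split_tbl$pct <- if (n > 0) percent(split_tbl$n, n, digits) else NA_real_
  paths <- count(first_line, .data$pathway, name = "n")
  paths <- arrange(paths, dplyr::desc(.data$n), .data$pathway)
  paths$pct <- if (n > 0) percent(paths$n, n, digits) else NA_real_
  list(split = split_tbl, pathways = paths)
}

#' Approval-era split of first-line daratumumab-combination initiation
#'
#' Buckets 1st-line TCE patients by index month against the approval-era
#' boundaries (month granularity) and counts those whose 1st-line initial
#' regimen is a daratumumab combination (D-RVd-, DVd-, D-VMP- or
#' DRd-based). Percentages are integer-rounded, the convention used for
#' this analysis.
#'
#' @param status output of [tce_status()].
#' @param index_dates tibble `patient_id`, `index_date`.
#' @param config pipeline configuration (era boundaries under `eras`).
#' @return tibble `era`, `n`, `n_dara_combo`, `pct`; eras are
#'   `pre_d_vmp_approval`, `post_d_vmp_approval`, and the sub-era
#'   `post_drd_approval`.
#' @export
era_split <- function(status, index_dates, config = default_config()) {
  st <- left_join(status$patients, index_dates, by = "patient_id")
  st <- st[!is.na(st$first_tce_line) & st$first_tce_line == 1, ]
  m <- month_floor(st$index_date)
  dara <- st$first_line_label %in% DARA_COMBO_LABELS
  digits <- config$summary$era_percent_digits
  eras <- list(
    pre_d_vmp_approval = m < config$eras$d_vmp_approval,
    post_d_vmp_approval = m >= config$eras$d_vmp_approval,
    post_drd_approval = m >= config$eras$drd_approval
  )
  bind_rows(lapply(names(eras), function(e) {
    sel <- eras[[e]]
    n <- sum(sel)
    tibble(era = e, n = n, n_dara_combo = sum(dara & sel),
           pct = if (n > 0) percent(sum(dara & sel), n, digits) else NA_real_)
  }))
}
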