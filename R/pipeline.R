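# End-to-end pipeline: cohort -> episodes -> TCE -> tables, plus the
# command-line interface. The pipeline is a pure function of
# (bundle, config): repeated runs give identical outputs.

#' Run the full analysis pipeline
#'
#' Applies the eligibility funnel, builds treatment lines and segments for
#' the eligible cohort, assigns transplant groups, classifies triple-class
#' exposure, and produces all summary tables. Finishes with the
#' percentage self-consistency audit.
#'
#' @param bundle a validated `claims_bundle`.
#' @param config pipeline configuration.
#' @param quiet suppress per-stage progress messages.
#' @return list: `funnel`, `cohort` (with `group`, `sct_line`), `lines`
#'   (with `sct_in_line`), `segments`, `tce` (per-patient status +
#'   per-line flags), `tables` (characteristics, history, line_counts,
#'   duration, regimens, tce, era, pathways, regimens_by_age,
#'   regimens_by_comorbidity), `manifest`.
#' @export
run_pipeline <- function(bundle, config = default_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) inform(paste0(...))
  validate_bundle(bundle)

  elig <- apply_eligibility(bundle, config)
  say("cohort: ", nrow(elig$cohort), " eligible of ",
      nrow(bundle$patients), " patients")
  cohort <- elig$cohort
  if (nrow(cohort) == 0) {
    abort("no eligible patients; nothing to analyse")
  }

  eps <- build_cohort_lines(bundle, cohort, config)
  say("episodes: ", nrow(eps$lines), " lines, ", nrow(eps$segments),
      " segments")
  cohort <- assign_group(cohort, bundle$procedures, eps$lines, config)
  eps$lines$sct_in_line <- FALSE
  sct_key <- paste(cohort$patient_id, cohort$sct_line)
  eps$lines$sct_in_line <-
    paste(eps$lines$patient_id, eps$lines$line_number) %in%
    sct_key[!is.na(cohort$sct_line)]

  tce <- tce_status(eps$lines, eps$segments, config)
  say("TCE: ", sum(tce$patients$tce_ever), " ever triple-class exposed")

  groups <- select(cohort, "patient_id", "group")
  nt <- cohort[cohort$group == "non-transplant", ]
  nt_lines <- eps$lines[eps$lines$patient_id %in% nt$patient_id, ]
  tables <- list(
    characteristics = characteristics_table(cohort, bundle$hospitals, config),
    history = comorbidity_history_table(bundle$diagnoses, cohort, config),
    line_counts = line_tables(eps$lines, groups, config),
    duration = duration_table(eps$lines, groups, config),
    regimens = regimen_table(eps$lines, groups, config),
    tce = tce_tables(tce, groups, config),
    pathways = tce_pathways(tce, config),
    era = era_split(tce, select(cohort, "patient_id", "index_date"), config),
    regimens_by_age = stratified_regimens(nt_lines, nt, "age_category", config),
    regimens_by_comorbidity = stratified_regimens(nt_lines, nt, "comorbidity",
                                                  config)
  )
  audit_percentages(tables, config)
  say("tables: self-consistency audit passed")

  res <- list(funnel = elig$funnel, cohort = cohort, lines = eps$lines,
              segments = eps$segments, tce = tce, tables = tables)
  res$manifest <- tibble(
    output = c("funnel", "cohort", "lines", "segments", "tce",
               names(tables)),
    rows = c(nrow(elig$funnel), nrow(cohort), nrow(eps$lines),
             nrow(eps$segments), nrow(tce$patients),
             map_int(tables, function(t) {
               if (is.data.frame(t)) nrow(t) else nrow(t$pathways)
             })),
    config_hash = rlang::hash(unclass(config))
  )
  res
}

flatten_list_col <- function(x) map_chr(x, paste, collapse = ";")

#' Write pipeline outputs as CSV files
#'
#' @param res result of [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(x, p, progress = FALSE)
    p
  }
  cohort <- res$cohort
  cohort$baseline_comorbidities <- flatten_list_col(cohort$baseline_comorbidities)
  lines <- res$lines
  lines$classes <- flatten_list_col(lines$classes)
  segments <- res$segments
  segments$drugs <- flatten_list_col(segments$drugs)
  per_line <- res$tce$per_line
  per_line$classes <- flatten_list_col(per_line$classes)
  per_line$cum_classes <- flatten_list_col(per_line$cum_classes)
  paths <- c(
    funnel = w(res$funnel, "funnel"),
    cohort = w(cohort, "cohort"),
    lines = w(lines, "lines"),
    segments = w(segments, "segments"),
    tce = w(res$tce$patients, "tce"),
    tce_per_line = w(per_line, "tce_per_line"),
    characteristics = w(res$tables$characteristics, "characteristics"),
    history = w(res$tables$history, "history"),
    line_counts = w(res$tables$line_counts, "line_counts"),
    duration = w(res$tables$duration, "duration"),
    regimens = w(res$tables$regimens, "regimens"),
    tce_table = w(res$tables$tce, "tce_table"),
    pathways = w(res$tables$pathways$pathways, "pathways"),
    pathway_split = w(res$tables$pathways$split, "pathway_split"),
    era = w(res$tables$era, "era"),
    regimens_by_age = w(res$tables$regimens_by_age, "regimens_by_age"),
    regimens_by_comorbidity = w(res$tables$regimens_by_comorbidity,
                                "regimens_by_comorbidity"),
    manifest = w(res$manifest, "manifest")
  )
  invisible(paths)
}

parse_cli_flags <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) {
      abort(paste0("unexpected argument: ", args[i]))
    }
    if (i + 1 > length(args)) abort(paste0("missing value for ", args[i]))
    out[[substring(args[i], 3)]] <- args[i + 1]
    i <- i + 2
  }
  out
}

#' Command-line entry point
#'
#' Subcommands:
#' * `simulate --preset <name> --seed <int> --outdir <dir> [--n <int>]` —
#'   write a synthetic bundle plus ground-truth sidecars.
#' * `run --data <dir> --outdir <dir> [--config <yaml>] [--seed <int>]` —
#'   read a bundle and write every derived CSV.
#' * `summarize --data <run-outdir> --outdir <dir> [--config <yaml>]` —
#'   rebuild only the summary tables from a previous run's cached
#'   intermediates (cohort/lines/segments CSVs).
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments, for use from the installed `Rscript` shim).
#' @return `0` invisibly on success; errors propagate to the caller.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    abort("usage: myelolot <simulate|run|summarize> [--flags]")
  }
  cmd <- args[1]
  flags <- parse_cli_flags(args[-1])
  if (cmd == "simulate") {
    if (is.null(flags$outdir)) abort("simulate: --outdir is required")
    scenario <- scenario_presets(flags$preset %||% "paper-like")
    if (!is.null(flags$n)) scenario$n_patients <- as.integer(flags$n)
    sim <- generate_claims(scenario, seed = as.integer(flags$seed %||% "1"))
    paths <- write_sim(sim, flags$outdir)
    inform(paste0("simulate: wrote ", length(paths), " files to ",
                  flags$outdir, " (", nrow(sim$bundle$patients),
                  " patients)"))
  } else if (cmd == "run") {
    if (is.null(flags$data) || is.null(flags$outdir)) {
      abort("run: --data and --outdir are required")
    }
    config <- load_config(flags$config)
    bundle <- read_bundle(flags$data)
    res <- run_pipeline(bundle, config)
    write_pipeline_outputs(res, flags$outdir)
    inform(paste0("run: wrote outputs to ", flags$outdir))
  } else if (cmd == "summarize") {
    if (is.null(flags$data) || is.null(flags$outdir)) {
      abort("summarize: --data and --outdir are required")
    }
    config <- load_config(flags$config)
    res <- summarize_cached(flags$data, config)
    dir.create(flags$outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(res)) {
      tbl <- if (nm == "pathways") res[[nm]]$pathways else res[[nm]]
      readr::write_csv(tbl, file.path(flags$outdir, paste0(nm, ".csv")),
                       progress = FALSE)
    }
    inform(paste0("summarize: wrote tables to ", flags$outdir))
  } else {
    abort(paste0("unknown command '", cmd,
                 "'; use simulate, run or summarize"))
  }
  invisible(0L)
}

# Rebuild the summary tables from a previous run's cached cohort / lines /
# segments CSVs (no re-derivation of episodes).
summarize_cached <- function(dir, config = default_config()) {
  need <- file.path(dir, c("cohort.csv", "lines.csv", "segments.csv"))
  if (!all(file.exists(need))) {
    abort(paste0("summarize: missing cached intermediates in ", dir))
  }
  rd <- function(p) readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  cohort <- rd(need[1])
  cohort$baseline_comorbidities <-
    lapply(strsplit(dplyr::coalesce(as.character(cohort$baseline_comorbidities),
                                    ""), ";"),
           function(x) x[nzchar(x)])
  lines <- rd(need[2])
  lines$classes <- strsplit(dplyr::coalesce(as.character(lines$classes), ""),
                            ";")
  segments <- rd(need[3])
  segments$drugs <- strsplit(as.character(segments$drugs), ";")
  tce <- tce_status(lines, segments, config)
  groups <- select(cohort, "patient_id", "group")
  nt <- cohort[cohort$group == "non-transplant", ]
  nt_lines <- lines[lines$patient_id %in% nt$patient_id, ]
  tables <- list(
    line_counts = line_tables(lines, groups, config),
    duration = duration_table(lines, groups, config),
    regimens = regimen_table(lines, groups, config),
    tce = tce_tables(tce, groups, config),
    pathways = tce_pathways(tce, config),
    era = era_split(tce, select(cohort, "patient_id", "index_date"), config),
    regimens_by_age = stratified_regimens(nt_lines, nt, "age_category",
                                          config),
    regimens_by_comorbidity = stratified_regimens(nt_lines, nt,
                                                  "comorbidity", config)
  )
  audit_percentages(tables, config)
  tables
}
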