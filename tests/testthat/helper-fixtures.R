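# Shared fixtures. The expensive simulations are generated once per test
# run and cached; every consumer sees the same objects.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

test_cfg <- function() cached("cfg", default_config())

paper_sim <- function() {
  cached("paper_sim", generate_claims("paper-like", seed = 42))
}

paper_run <- function() {
  cached("paper_run", run_pipeline(paper_sim()$bundle, quiet = TRUE))
}

bridging_sim <- function() {
  cached("bridging_sim", generate_claims("bridging-heavy", seed = 11))
}

bridging_run <- function() {
  cached("bridging_run", run_pipeline(bridging_sim()$bundle, quiet = TRUE))
}

# One-patient bundle builder for directed cohort tests.
one_patient_bundle <- function(diagnoses = NULL, prescriptions = NULL,
                               procedures = NULL,
                               birth_date = as.Date("1950-06-15")) {
  pid <- "P1"
  patients <- tibble::tibble(patient_id = pid, sex = "male",
                             birth_date = birth_date, hospital_id = "H1")
  hospitals <- tibble::tibble(hospital_id = "H1", bed_size_class = ">=500",
                              category = "public")
  empty_dx <- tibble::tibble(patient_id = character(0),
                             icd10_code = character(0),
                             date = as.Date(character(0)),
                             suspected = logical(0))
  empty_rx <- tibble::tibble(patient_id = character(0), drug = character(0),
                             route = character(0),
                             start_date = as.Date(character(0)),
                             end_date = as.Date(character(0)))
  empty_pr <- tibble::tibble(patient_id = character(0),
                             procedure_code = character(0),
                             date = as.Date(character(0)))
  claims_bundle(patients, hospitals, diagnoses %||% empty_dx,
                prescriptions %||% empty_rx, procedures %||% empty_pr)
}

dx_row <- function(code, date, suspected = FALSE, pid = "P1") {
  tibble::tibble(patient_id = pid, icd10_code = code, date = as.Date(date),
                 suspected = suspected)
}

rx_row <- function(drug, start, end = start, route = "oral", pid = "P1") {
  tibble::tibble(patient_id = pid, drug = drug, route = route,
                 start_date = as.Date(start), end_date = as.Date(end))
}

pr_row <- function(code, date, pid = "P1") {
  tibble::tibble(patient_id = pid, procedure_code = code,
                 date = as.Date(date))
}

`%||%` <- rlang::`%||%`
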