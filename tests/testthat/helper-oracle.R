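# Independent brute-force oracle: enumerates covered days as explicit
# integer sets and applies the transfer/exposure definitions literally.
# Deliberately shares no code with the package's interval arithmetic.

oracle_covered_days <- function(rx, cfg) {
  # per-drug explicit day sets (core drugs only)
  core <- rx[classify_drug(rx$drug, cfg) %in%
               c("IMiD", "PI", "anti-CD38", "anti-SLAMF7", "HDACi",
                 "alkylator"), ]
  days <- list()
  for (i in seq_len(nrow(core))) {
    d <- tolower(core$drug[i])
    s <- as.integer(core$start_date[i])
    e <- if (core$route[i] == "injectable") {
      s + cfg$lines$injectable_coverage_days - 1L
    } else {
      as.integer(core$end_date[i])
    }
    days[[d]] <- sort(unique(c(days[[d]], seq(s, e))))
  }
  days
}

# Literal line derivation: scan core start days in order; a day opens a new
# line when none of the preceding gap_threshold_days is covered.
oracle_lines <- function(rx, index_date, cfg) {
  core <- rx[classify_drug(rx$drug, cfg) %in%
               c("IMiD", "PI", "anti-CD38", "anti-SLAMF7", "HDACi",
                 "alkylator"), ]
  all_days <- sort(unique(unlist(oracle_covered_days(rx, cfg))))
  starts <- sort(unique(as.integer(core$start_date)))
  starts <- starts[starts >= as.integer(index_date)]
  gap <- cfg$lines$gap_threshold_days
  bounds <- starts[1]
  for (d in starts[-1]) {
    lookback <- seq(d - gap, d - 1)
    if (!any(lookback %in% all_days)) bounds <- c(bounds, d)
  }
  out <- data.frame(line_number = seq_along(bounds), start = bounds, end = NA)
  for (k in seq_along(bounds)) {
    hi <- if (k < length(bounds)) bounds[k + 1] - 1 else max(all_days)
    out$end[k] <- max(all_days[all_days >= bounds[k] & all_days <= hi])
  }
  out$start <- as.Date(out$start, origin = "1970-01-01")
  out$end <- as.Date(out$end, origin = "1970-01-01")
  out
}

# Literal TCE: classes of every core drug prescribed on/before each line's
# end date, scanned straight from the raw prescriptions.
oracle_tce_flags <- function(rx, line_ends, cfg) {
  core <- rx[classify_drug(rx$drug, cfg) %in%
               c("IMiD", "PI", "anti-CD38", "anti-SLAMF7", "HDACi",
                 "alkylator"), ]
  vapply(line_ends, function(e) {
    cls <- unique(classify_drug(core$drug[core$start_date <= e], cfg))
    all(c("IMiD", "PI", "anti-CD38") %in% cls)
  }, logical(1))
}

# Random small trajectory (<= 3 core drugs, <= ~400 days) for the
# equivalence property; returns a prescriptions tibble.
random_trajectory <- function(cfg) {
  drugs <- sample(c("lenalidomide", "bortezomib", "daratumumab"),
                  sample(1:3, 1))
  rows <- list()
  for (d in drugs) {
    n_rx <- sample(1:4, 1)
    for (j in seq_len(n_rx)) {
      s <- sample(0:400, 1)
      if (d == "lenalidomide") {
        rows[[length(rows) + 1]] <- tibble::tibble(
          patient_id = "X", drug = d, route = "oral",
          start_date = as.Date("2018-01-01") + s,
          end_date = as.Date("2018-01-01") + s + sample(0:60, 1))
      } else {
        rows[[length(rows) + 1]] <- tibble::tibble(
          patient_id = "X", drug = d, route = "injectable",
          start_date = as.Date("2018-01-01") + s,
          end_date = as.Date("2018-01-01") + s)
      }
    }
  }
  dplyr::bind_rows(rows)
}
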