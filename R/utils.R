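# Shared helpers: rounding, percentages, calendar arithmetic.

#' Round half away from zero
#'
#' `base::round()` rounds half to even; claims-study tables round half up,
#' and several printed cells (e.g. 43.75 -> 43.8) can only be reproduced with
#' half-up rounding, so every table in this package goes through this one
#' routine.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return `x` rounded half away from zero to `digits` places.
#' @export
#' @examples
#' round_half_up(43.75, 1) # 43.8, where round() gives 43.8 or 43.7
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage with the shared rounding convention
#'
#' All emitted tables derive their percentage columns from their count
#' columns through this function, so a self-consistency audit can re-derive
#' every percentage.
#'
#' @param numerator,denominator counts; `numerator` must lie in
#'   `[0, denominator]`.
#' @param digits decimal places (1 for the main tables, 0 for the
#'   approval-era analysis).
#' @return percentage rounded half up; `NA` with a warning when the
#'   denominator is zero (rendered blank downstream).
#' @export
#' @examples
#' percent(605, 1656) # 36.5
#' percent(56, 128)   # 43.8
percent <- function(numerator, denominator, digits = 1) {
  stopifnot(length(numerator) == length(denominator) || length(denominator) == 1)
  out <- round_half_up(100 * numerator / denominator, digits)
  bad <- !is.na(denominator) & denominator == 0
  if (any(bad)) {
    warn("percent(): zero denominator; returning NA for those cells")
    out[bad] <- NA_real_
  }
  out
}

# Calendar month arithmetic (lubridate %m+% rolls back month-end overflow,
# e.g. Jan 31 + 1 month -> Feb 28). All eligibility windows use calendar
# arithmetic, never 30/365-day approximations.
add_months <- function(date, n) date %m+% months(n)
sub_months <- function(date, n) date %m-% months(n)
sub_years  <- function(date, n) date %m-% years(n)

# First day of the calendar month containing `date`.
month_floor <- function(date) lubridate::floor_date(date, "month")

# Completed years of age at `at` (birthday convention).
age_at <- function(birth_date, at) {
  a <- lubridate::year(at) - lubridate::year(birth_date)
  had_birthday <- (lubridate::month(at) > lubridate::month(birth_date)) |
    (lubridate::month(at) == lubridate::month(birth_date) &
       lubridate::mday(at) >= lubridate::mday(birth_date))
  as.integer(a - !had_birthday)
}

# Age bands used by the characteristics table.
age_category <- function(age) {
  cut(age, breaks = c(-Inf, 17, 64, 74, 84, Inf),
      labels = c("<18", "18-64", "65-74", "75-84", ">=85"))
}

# Merge a sorted tibble of [start, end] intervals (integer days), joining
# intervals that overlap or touch (next start <= current end + 1).
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  if (length(start) == 0) {
    return(list(start = integer(0), end = integer(0)))
  }
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

# Re-merge a per-drug interval tibble, bridging gaps of at most `allow`
# days (refill/grace merging); returns integer start/end columns.
merge_with_allowance <- function(cov, allow) {
  pieces <- lapply(split(cov, cov$drug), function(d) {
    s <- as.integer(d$start); e <- as.integer(d$end)
    o <- order(s)
    s <- s[o]; e <- e[o]
    ms <- s[1]; me <- e[1]
    out <- list()
    for (i in seq_along(s)[-1]) {
      if (s[i] <= me + 1L + allow) {
        me <- max(me, e[i])
      } else {
        out[[length(out) + 1]] <- c(ms, me)
        ms <- s[i]; me <- e[i]
      }
    }
    out[[length(out) + 1]] <- c(ms, me)
    tibble(drug = d$drug[1],
           start = vapply(out, `[`, integer(1), 1),
           end = vapply(out, `[`, integer(1), 2))
  })
  res <- bind_rows(pieces)
  if (nrow(res) == 0) {
    res <- tibble(drug = character(0), start = integer(0), end = integer(0))
  }
  res
}

# TRUE if any interval intersects [a, b].
any_overlap <- function(start, end, a, b) {
  any(start <= b & end >= a)
}

# Continuous summary block used by the characteristics and follow-up rows.
summary_stats <- function(x) {
  q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  tibble(
    statistic = c("mean", "sd", "median", "min", "max", "q1", "q3"),
    value = c(mean(x, na.rm = TRUE), sd(x), median(x, na.rm = TRUE),
              min(x, na.rm = TRUE), max(x, na.rm = TRUE), q[1], q[2])
  )
}
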