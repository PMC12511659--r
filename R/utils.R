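# Internal helpers shared across pipeline stages.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; dispensed-quantity-to-days conversion
#' uses the conventional half-up rule so that e.g. 14.5 DDDs cover 15 days.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

#' Clamped calendar-month arithmetic
#'
#' Adds whole months to dates preserving the day of month and clamping at the
#' end of shorter months (Jan 31 + 1 month = Feb 28/29), the convention used
#' for follow-up windows.
#'
#' @param dates Date vector.
#' @param n integer vector of months to add (recycled against `dates`).
#' @return Date vector.
#' @keywords internal
add_months <- function(dates, n) {
  lubridate::`%m+%`(dates, months(n))
}

#' Derive a per-stage RNG seed from the run seed
#'
#' One global seed is fanned out to stage substreams by a stable string hash,
#' so a stage re-run in isolation sees the same stream as inside the full
#' pipeline. Result is always a valid 32-bit seed.
#'
#' @param seed integer run seed.
#' @param stage character scalar naming the stage.
#' @return integer seed.
#' @keywords internal
stage_seed <- function(seed, stage) {
  h <- Reduce(function(a, b) (a * 31 + b) %% 1000003, utf8ToInt(stage), 7)
  as.integer((abs(as.numeric(seed)) %% 2147483647 + h * 2654435761) %% 2147480009)
}

#' Union a set of half-open integer intervals
#'
#' Gaps-and-islands pass: sort by start, merge any interval whose start does
#' not exceed the running maximum end. Used to collapse overlapping dispensing
#' coverage so overlapping days are counted once.
#'
#' @param start,end integer vectors of half-open intervals `[start, end)`.
#' @return data.table with columns `start`, `end` of disjoint intervals.
#' @keywords internal
union_intervals <- function(start, end) {
  stopifnot(length(start) == length(end), all(end > start))
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  cummax_end <- cummax(end)
  grp <- cumsum(c(TRUE, start[-1] > cummax_end[-length(cummax_end)]))
  data.table::data.table(
    start = tapply(start, grp, min),
    end = tapply(end, grp, max)
  )
}

#' Percentage of a count, Table-style
#'
#' @param n count.
#' @param N denominator.
#' @return numeric percentage (0-100 scale).
#' @export
pct <- function(n, N) {
  100 * n / N
}

#' Format a percentage to one decimal, report style
#'
#' @param n count.
#' @param N denominator.
#' @return character, e.g. `"36.2"`.
#' @export
fmt_pct <- function(n, N) {
  sprintf("%.1f", pct(n, N))
}

# Quiet R CMD check notes for data.table non-standard evaluation columns.
utils::globalVariables(c(
  ".", ".N", ".SD", "patient_id", "dispense_date", "atc_code", "substance",
  "product_type", "quantity_ddd", "route", "event_date", "code_system",
  "code", "registry_entry", "registry_exit", "birth_date", "index_date",
  "true_class", "distractor", "month", "pdc", "start", "end", "wstart",
  "wend", "window_len", "covered", "label", "cluster", "offset", "q",
  "mlen", "mstart", "index_substance", "index_type", "index_atc",
  "switched", "days_to_first_switch", "drug_class", "n_users", "grp",
  "target", "sex", "region", "indication", "age_band", "index_drug",
  "month_idx", "wlen", "switch_kind", "first_switch_date", "i.start",
  "i.end", "day0", "is_diff", "same_day_mixed", "days", "N", "s", "e",
  "i.month", "x.e", "x.s", "i.wend", "i.wstart", "fu", "old", "last_cd",
  "last_uc", "is_cd", "is_uc", "index_class", "index_route", "step",
  "aic", "size", "action", "term", "n", "mean_pdc", "covered",
  "window_start", "window_end"
))
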