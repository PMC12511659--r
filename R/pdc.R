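# Monthly proportion-of-days-covered (PDC) from dispensing records.
#
# Each dispensing of q DDDs covers round(q) whole days from its dispensing
# date, at one DDD per day. Overlapping coverage is unioned so days covered
# by more than one dispensing count once, and coverage by any eligible
# biologic counts (switching does not interrupt adherence). Months are
# anchored at the index date (rolling calendar months, 28-31 days each), so
# every patient has exactly T windows.

#' Coverage intervals from dispensing records
#'
#' Converts each eligible dispensing into a raw coverage interval
#' `[dispense_date, dispense_date + round(quantity_ddd))`, unions the
#' intervals per patient, and truncates coverage to the follow-up
#' `[index_date, index_date + T months)`.
#'
#' @param dispensings data.table of dispensing records.
#' @param index_dates data.table with `patient_id`, `index_date` (a cohort
#'   table works).
#' @param T_months follow-up length in months.
#' @param atc_codes ATC codes that count towards coverage (default: the five
#'   IBD biologics).
#' @return data.table with `patient_id`, `start`, `end` (Dates, half-open,
#'   pairwise disjoint within patient).
#' @export
coverage_intervals <- function(dispensings, index_dates, T_months = 36L,
                               atc_codes = default_drug_catalog()$atc_code) {
  dispensings <- data.table::as.data.table(dispensings)
  if (any(dispensings$quantity_ddd <= 0)) {
    stop("quantity_ddd must be positive", call. = FALSE)
  }
  idx <- data.table::as.data.table(index_dates)[, .(patient_id, index_date)]
  d <- merge(dispensings[atc_code %in% atc_codes],
             idx, by = "patient_id")
  if (nrow(d) == 0L) {
    return(data.table::data.table(patient_id = character(),
                                  start = as.Date(character()),
                                  end = as.Date(character())))
  }
  d[, `:=`(start = as.integer(dispense_date - index_date),
           end = as.integer(dispense_date - index_date) +
             as.integer(round_half_up(quantity_ddd)))]
  fu_days <- data.table::data.table(
    patient_id = idx$patient_id,
    fu = as.integer(add_months(idx$index_date, T_months) - idx$index_date)
  )
  d <- merge(d, fu_days, by = "patient_id")
  d[, `:=`(start = pmax(start, 0L), end = pmin(end, fu))]
  d <- d[end > start]
  u <- d[, union_intervals(start, end), by = patient_id]
  u <- merge(u, idx, by = "patient_id")
  u[, `:=`(start = index_date + start, end = index_date + end)]
  data.table::setorder(u, patient_id, start)
  u[, .(patient_id, start, end)]
}

#' Monthly PDC series over the follow-up
#'
#' Splits the follow-up of each patient into `T_months` index-anchored
#' calendar-month windows (half-open, 28-31 days, day-of-month preserved and
#' clamped at month end) and computes, per window, covered days divided by
#' window length.
#'
#' @param intervals disjoint coverage intervals from [coverage_intervals()].
#' @param index_dates data.table with `patient_id`, `index_date`; every
#'   patient listed here gets a series (zero coverage if no intervals).
#' @param T_months number of monthly windows.
#' @return data.table with `patient_id`, `month` (1..T), `window_start`,
#'   `window_end`, `window_len`, `pdc`.
#' @export
monthly_pdc <- function(intervals, index_dates, T_months = 36L) {
  stopifnot(T_months >= 1)
  idx <- data.table::as.data.table(index_dates)[, .(patient_id, index_date)]
  n <- nrow(idx)
  boundaries <- add_months(rep(idx$index_date, each = T_months + 1L),
                           rep(0:T_months, n))
  bmat <- matrix(as.integer(boundaries - rep(idx$index_date,
                                             each = T_months + 1L)),
                 n, T_months + 1L, byrow = TRUE)
  win <- data.table::data.table(
    patient_id = rep(idx$patient_id, each = T_months),
    index_date = rep(idx$index_date, each = T_months),
    month = rep(seq_len(T_months), n),
    wstart = as.vector(t(bmat[, -(T_months + 1L), drop = FALSE])),
    wend = as.vector(t(bmat[, -1L, drop = FALSE]))
  )
  win[, window_len := wend - wstart]
  stopifnot(all(win$window_len >= 28L & win$window_len <= 31L))

  iv <- data.table::as.data.table(intervals)
  if (nrow(iv)) {
    iv <- merge(iv, idx, by = "patient_id")
    iv[, `:=`(s = as.integer(start - index_date),
              e = as.integer(end - index_date))]
    ov <- iv[win, on = .(patient_id, s < wend, e > wstart),
             .(patient_id, month = i.month,
               covered = pmin(x.e, i.wend) - pmax(x.s, i.wstart)),
             nomatch = NULL]
    cov <- ov[, .(covered = sum(covered)), by = .(patient_id, month)]
    win <- merge(win, cov, by = c("patient_id", "month"), all.x = TRUE)
  } else {
    win[, covered := 0L]
  }
  win[is.na(covered), covered := 0L]
  win[, pdc := covered / window_len]
  stopifnot(all(win$pdc >= 0 & win$pdc <= 1))
  win[, `:=`(window_start = index_date + wstart, window_end = index_date + wend)]
  data.table::setorder(win, patient_id, month)
  win[, .(patient_id, month, window_start, window_end, window_len, pdc)]
}

#' Wide PDC matrix from a long series table
#'
#' @param series long table from [monthly_pdc()].
#' @return numeric matrix, one row per patient (rownames = patient ids),
#'   one column per month.
#' @export
pdc_matrix <- function(series) {
  series <- data.table::as.data.table(series)
  wide <- data.table::dcast(series, patient_id ~ month, value.var = "pdc")
  m <- as.matrix(wide[, -1L])
  rownames(m) <- wide$patient_id
  colnames(m) <- paste0("month_", colnames(m))
  m
}

#' Mean PDC per group and month
#'
#' The plot-ready table of monthly average adherence per trajectory group.
#'
#' @param series long series table from [monthly_pdc()].
#' @param labels data.table with `patient_id` and `label`.
#' @return data.table with `group`, `month`, `mean_pdc`, `n`.
#' @export
mean_pdc_by_group <- function(series, labels) {
  series <- data.table::as.data.table(series)
  labels <- data.table::as.data.table(labels)
  miss <- setdiff(unique(series$patient_id), labels$patient_id)
  if (length(miss)) {
    stop("unlabeled patient(s): ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  }
  x <- merge(series, labels[, .(patient_id, label)], by = "patient_id")
  out <- x[, .(mean_pdc = mean(pdc), n = .N), by = .(group = label, month)]
  data.table::setorder(out, group, month)
  out[]
}
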