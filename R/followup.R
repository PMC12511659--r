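# Switching and follow-up drug-use descriptives by trajectory cluster.

#' Detect biologic switches during follow-up
#'
#' A switch is the first dispensing strictly after the index date (and
#' within follow-up) of an eligible biologic with a different active
#' substance than the index drug, or the same substance with a different
#' product type (originator vs biosimilar). Same-day mixed dispensings at
#' the index date do not count as switches but are flagged for review.
#'
#' @param cohort cohort table (needs `patient_id`, `index_date`,
#'   `index_substance`, `index_type`).
#' @param dispensings dispensing table.
#' @param T_months follow-up length in months.
#' @param atc_codes eligible biologic ATC codes.
#' @return data.table with `patient_id`, `switched`, `first_switch_date`,
#'   `days_to_first_switch`, `switch_kind` (`substance`, `type`, `none`),
#'   `same_day_mixed` flag.
#' @export
detect_switch <- function(cohort, dispensings, T_months = 36L,
                          atc_codes = default_drug_catalog()$atc_code) {
  cohort <- data.table::as.data.table(cohort)
  dispensings <- data.table::as.data.table(dispensings)
  d <- merge(dispensings[atc_code %in% atc_codes],
             cohort[, .(patient_id, index_date, index_substance, index_type)],
             by = "patient_id")
  fu_end <- add_months(d$index_date, T_months)
  d[, is_diff := substance != index_substance |
      (substance == index_substance & product_type != index_type)]
  mixed <- unique(d[dispense_date == index_date & is_diff, patient_id])
  sw <- d[dispense_date > index_date & dispense_date <= fu_end & is_diff]
  data.table::setorder(sw, patient_id, dispense_date, substance, product_type)
  first <- sw[, .SD[1L], by = patient_id]
  first[, `:=`(
    switched = TRUE,
    days_to_first_switch = as.integer(dispense_date - index_date),
    switch_kind = data.table::fifelse(substance != index_substance,
                                      "substance", "type")
  )]
  out <- merge(
    cohort[, .(patient_id)],
    first[, .(patient_id, switched, first_switch_date = dispense_date,
              days_to_first_switch, switch_kind)],
    by = "patient_id", all.x = TRUE
  )
  out[is.na(switched), `:=`(switched = FALSE, switch_kind = "none")]
  out[, same_day_mixed := patient_id %in% mixed]
  data.table::setorder(out, patient_id)
  out[]
}

#' Follow-up drug-use table by cluster
#'
#' Person-level drug-class use during follow-up: a patient counts once per
#' drug class if they have at least one dispensing with a matching ATC
#' prefix in `(index, index + T months]`. Percentages are within cluster;
#' the switch row adds median and IQR of days to first switch among
#' switchers (quantiles by linear interpolation).
#'
#' @param cohort cohort table.
#' @param dispensings dispensing table (non-biologic and biologic).
#' @param labels data.table `patient_id`, `label` (cluster labels).
#' @param switches output of [detect_switch()].
#' @param code_lists named list of ATC prefixes per drug class.
#' @param T_months follow-up length.
#' @return list with `use` (long table: drug_class, cluster, n, pct) and
#'   `switch_timing` (cluster, n_switched, median_days, q1, q3).
#' @export
followup_drug_use <- function(cohort, dispensings, labels, switches,
                              code_lists = default_code_lists()$drug_class,
                              T_months = 36L) {
  cohort <- data.table::as.data.table(cohort)
  labels <- data.table::as.data.table(labels)
  miss <- setdiff(cohort$patient_id, labels$patient_id)
  if (length(miss)) {
    stop("unlabeled patient(s): ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  }
  lab <- labels[, .(patient_id, label)]
  cl_levels <- c(unique(lab$label[order(lab$label)]))
  d <- merge(data.table::as.data.table(dispensings),
             cohort[, .(patient_id, index_date)], by = "patient_id")
  fu_end <- add_months(d$index_date, T_months)
  d <- d[dispense_date > index_date & dispense_date <= fu_end]
  d <- merge(d, lab, by = "patient_id")
  totals <- lab[patient_id %in% cohort$patient_id, .(N = .N), by = label]

  rows <- list()
  for (dc in names(code_lists)) {
    users <- unique(d[matches_prefix(atc_code, code_lists[[dc]]),
                      .(patient_id, label)])
    cnt <- users[, .(n = .N), by = label]
    cnt <- merge(totals, cnt, by = "label", all.x = TRUE)
    cnt[is.na(n), n := 0L]
    rows[[dc]] <- data.table::data.table(
      drug_class = dc, cluster = cnt$label, n = cnt$n,
      pct = pct(cnt$n, cnt$N)
    )
  }
  sw <- merge(switches, lab, by = "patient_id")
  sw_cnt <- sw[, .(n = sum(switched)), by = label]
  sw_cnt <- merge(totals, sw_cnt, by = "label", all.x = TRUE)
  sw_cnt[is.na(n), n := 0L]
  rows$switch <- data.table::data.table(
    drug_class = "switch", cluster = sw_cnt$label, n = sw_cnt$n,
    pct = pct(sw_cnt$n, sw_cnt$N)
  )
  use <- data.table::rbindlist(rows)

  timing_all <- sw[switched == TRUE,
                   .(label = "overall", days = days_to_first_switch)]
  timing_cl <- sw[switched == TRUE, .(label, days = days_to_first_switch)]
  timing <- rbind(timing_all, timing_cl)[, .(
    n_switched = .N,
    median_days = stats::quantile(days, 0.5, type = 7, names = FALSE),
    q1 = stats::quantile(days, 0.25, type = 7, names = FALSE),
    q3 = stats::quantile(days, 0.75, type = 7, names = FALSE)
  ), by = .(cluster = label)]
  list(use = use, switch_timing = timing)
}
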