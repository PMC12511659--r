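# New-user cohort construction: inclusion/exclusion cascade, index-date
# attributes, indication, baseline covariates, and the attrition table.

#' Apply the new-user inclusion cascade
#'
#' Builds the analysis cohort from raw registry/dispensing/event tables by a
#' fixed-order cascade: (1) at least one eligible biologic dispensing inside
#' the study window (the first such dispensing is the index date);
#' (2) ustekinumab indexes only on/after its IBD market-entry date;
#' (3) at least `lookback_days` of registry observation before the index
#' date; (4) no eligible biologic dispensing in the washout window before
#' the index date (new-user rule; the washout may look before the study
#' window opens); (5) registry coverage through `T_months` months after the
#' index date; (6) an IBD indication (CD or UC) on or before the index date.
#'
#' @param registry data.table of patient registry rows (one per patient).
#' @param dispensings data.table of dispensing claims.
#' @param events data.table of diagnosis/exemption events.
#' @param rules rules list, see [default_rules()].
#' @return list with `cohort` (one row per retained patient with index-date
#'   attributes and demographics) and `attrition` (per-step counts).
#' @export
identify_new_users <- function(registry, dispensings, events,
                               rules = default_rules()) {
  registry <- data.table::as.data.table(registry)
  dispensings <- data.table::as.data.table(dispensings)
  events <- data.table::as.data.table(events)
  if (anyDuplicated(registry$patient_id)) {
    stop("registry has duplicate rows for the same patient", call. = FALSE)
  }
  steps <- c(
    "eligible biologic dispensing in study window",
    "ustekinumab index-date rule",
    "sufficient look-back before index",
    "no biologic in washout before index (new user)",
    "registry coverage through follow-up",
    "IBD indication (CD or UC)"
  )
  n_all <- nrow(registry)
  attr_rows <- list()
  record <- function(step, n_in, n_out) {
    attr_rows[[length(attr_rows) + 1L]] <<- data.table::data.table(
      step = step, n_entering = n_in, n_excluded = n_in - n_out,
      n_retained = n_out
    )
  }

  elig <- dispensings[atc_code %in% rules$biologic_atc]
  if (nrow(elig) == 0L) {
    for (s in steps) {
      record(s, n_all, if (s == steps[1]) 0L else 0L)
      n_all <- 0L
    }
    return(list(
      cohort = empty_cohort(),
      attrition = data.table::rbindlist(attr_rows)
    ))
  }

  # Step 1: index = first eligible dispensing inside the study window.
  in_win <- elig[dispense_date >= rules$study_start &
                   dispense_date <= rules$study_end]
  data.table::setorder(in_win, patient_id, dispense_date, atc_code,
                       product_type)
  index <- in_win[, .SD[1L], by = patient_id]
  cand <- merge(registry, index[, .(patient_id, index_date = dispense_date,
                                    index_atc = atc_code,
                                    index_substance = substance,
                                    index_type = product_type,
                                    index_route = route)],
                by = "patient_id")
  record(steps[1], n_all, nrow(cand))

  # Step 2: ustekinumab index-date rule.
  keep <- !(cand$index_atc == "L04AC05" &
              cand$index_date < rules$ustekinumab_start)
  record(steps[2], nrow(cand), sum(keep))
  cand <- cand[keep]

  # Step 3: look-back.
  keep <- as.integer(cand$index_date - cand$registry_entry) >= rules$lookback_days
  record(steps[3], nrow(cand), sum(keep))
  cand <- cand[keep]

  # Step 4: washout (new user).
  prior <- merge(elig, cand[, .(patient_id, index_date)], by = "patient_id")
  prior <- prior[dispense_date < index_date &
                   dispense_date >= index_date - rules$washout_days]
  keep <- !(cand$patient_id %in% unique(prior$patient_id))
  record(steps[4], nrow(cand), sum(keep))
  cand <- cand[keep]

  # Step 5: registry coverage through follow-up.
  fu_end <- add_months(cand$index_date, rules$T_months)
  keep <- is.na(cand$registry_exit) | cand$registry_exit >= fu_end
  record(steps[5], nrow(cand), sum(keep))
  cand <- cand[keep]

  # Step 6: IBD indication.
  cand[, indication := determine_indication_batch(events, cand,
                                                  rules$code_lists$indication)]
  keep <- cand$indication %in% c("CD", "UC")
  record(steps[6], nrow(cand), sum(keep))
  cand <- cand[keep]

  # Index attributes from the drug catalog + demographics at index.
  attrs <- index_attributes(cand[, .(atc_code = index_atc,
                                     product_type = index_type)],
                            rules$drug_catalog)
  cand[, `:=`(index_substance = attrs$substance,
              index_route = attrs$route)]
  cand[, index_class := attrs$index_class]
  age <- floor(as.numeric(cand$index_date - cand$birth_date) / 365.25)
  cand[, age_band := cut(age, c(-Inf, 17, 44, 64, 79, Inf),
                         labels = c("<18", "18-44", "45-64", "65-79", ">=80"))]
  cand[, age_band := as.character(age_band)]
  cohort <- cand[, .(patient_id, index_date, index_substance, index_atc,
                     index_type, index_route, index_class, indication,
                     sex, age_band, region, birth_date,
                     registry_entry, registry_exit)]
  attrition <- data.table::rbindlist(attr_rows)
  stopifnot(all(attrition$n_retained == attrition$n_entering - attrition$n_excluded))
  list(cohort = cohort, attrition = attrition)
}

#' @keywords internal
empty_cohort <- function() {
  data.table::data.table(
    patient_id = character(), index_date = as.Date(character()),
    index_substance = character(), index_atc = character(),
    index_type = character(), index_route = character(),
    index_class = character(), indication = character(),
    sex = character(), age_band = character(), region = character(),
    birth_date = as.Date(character()),
    registry_entry = as.Date(character()),
    registry_exit = as.Date(character())
  )
}

#' Determine the IBD indication for one patient
#'
#' CD if any CD-coded event on or before the index date, else UC if any
#' UC-coded event; when both conditions appear, the condition of the most
#' recent event wins, with ties resolved to CD. Codes match by prefix
#' against the configured code lists (diagnosis and exemption codes).
#'
#' @param events data.table of events for one patient (`event_date`, `code`).
#' @param index_date the patient's index date.
#' @param code_lists list with `CD` and `UC` code-prefix vectors.
#' @return `"CD"`, `"UC"` or `"other"`.
#' @export
determine_indication <- function(events, index_date,
                                 code_lists = default_code_lists()$indication) {
  events <- data.table::as.data.table(events)
  ev <- events[event_date <= index_date]
  if (nrow(ev) == 0L) return("other")
  is_cd <- matches_prefix(ev$code, code_lists$CD)
  is_uc <- matches_prefix(ev$code, code_lists$UC)
  if (!any(is_cd) && !any(is_uc)) return("other")
  if (any(is_cd) && !any(is_uc)) return("CD")
  if (any(is_uc) && !any(is_cd)) return("UC")
  last_cd <- max(ev$event_date[is_cd])
  last_uc <- max(ev$event_date[is_uc])
  if (last_cd >= last_uc) "CD" else "UC"   # tie -> CD
}

#' @keywords internal
matches_prefix <- function(codes, prefixes) {
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}

# Vectorized indication over a candidate table.
#' @keywords internal
determine_indication_batch <- function(events, cand, code_lists) {
  ev <- merge(events, cand[, .(patient_id, index_date)], by = "patient_id")
  ev <- ev[event_date <= index_date]
  if (nrow(ev) == 0L) return(rep("other", nrow(cand)))
  ev[, `:=`(is_cd = matches_prefix(code, code_lists$CD),
            is_uc = matches_prefix(code, code_lists$UC))]
  agg <- ev[, .(
    last_cd = suppressWarnings(max(event_date[is_cd])),
    last_uc = suppressWarnings(max(event_date[is_uc]))
  ), by = patient_id]
  agg[, indication := data.table::fifelse(
    is.infinite(as.numeric(last_cd)) & is.infinite(as.numeric(last_uc)), "other",
    data.table::fifelse(is.infinite(as.numeric(last_uc)), "CD",
      data.table::fifelse(is.infinite(as.numeric(last_cd)), "UC",
        data.table::fifelse(last_cd >= last_uc, "CD", "UC"))))]
  out <- agg$indication[match(cand$patient_id, agg$patient_id)]
  out[is.na(out)] <- "other"
  out
}

#' Look up index-drug attributes in the drug catalog
#'
#' @param first_dispensing data.table (or list) with `atc_code` and
#'   `product_type` of the index dispensing(s).
#' @param drug_catalog catalog table, see [default_drug_catalog()].
#' @return data.table with `substance`, `index_type`, `route`,
#'   `index_class`.
#' @export
index_attributes <- function(first_dispensing,
                             drug_catalog = default_drug_catalog()) {
  fd <- data.table::as.data.table(first_dispensing)
  hit <- match(fd$atc_code, drug_catalog$atc_code)
  if (anyNA(hit)) {
    stop("ATC code(s) not in drug catalog: ",
         paste(unique(fd$atc_code[is.na(hit)]), collapse = ", "),
         call. = FALSE)
  }
  data.table::data.table(
    substance = drug_catalog$substance[hit],
    index_type = fd$product_type,
    route = drug_catalog$route[hit],
    index_class = drug_catalog$index_class[hit]
  )
}

#' Baseline covariate flags for a cohort
#'
#' Comorbidity flags use every event strictly before the index date (whole
#' available history); drug-use flags use dispensings in the half-open
#' window `[index - 365, index)`. Events dated exactly on the index date
#' count as neither.
#'
#' @param cohort cohort table from [identify_new_users()].
#' @param events events table.
#' @param dispensings dispensings table.
#' @param code_lists list with `comorbidity` (diagnosis-code prefixes) and
#'   `drug_class` (ATC prefixes), see [default_code_lists()].
#' @return data.table: `patient_id` plus one logical column per comorbidity
#'   (`como_*`) and per drug class (`drug_*`).
#' @export
build_covariates <- function(cohort, events, dispensings,
                             code_lists = default_code_lists()) {
  events <- data.table::as.data.table(events)
  dispensings <- data.table::as.data.table(dispensings)
  out <- data.table::data.table(patient_id = cohort$patient_id)
  ev <- merge(events, cohort[, .(patient_id, index_date)], by = "patient_id")
  ev <- ev[event_date < index_date]
  for (cm in names(code_lists$comorbidity)) {
    ids <- unique(ev$patient_id[matches_prefix(ev$code,
                                               code_lists$comorbidity[[cm]])])
    out[, paste0("como_", cm) := patient_id %in% ids]
  }
  dd <- merge(dispensings, cohort[, .(patient_id, index_date)],
              by = "patient_id")
  dd <- dd[dispense_date < index_date & dispense_date >= index_date - 365L]
  for (dc in names(code_lists$drug_class)) {
    ids <- unique(dd$patient_id[matches_prefix(dd$atc_code,
                                               code_lists$drug_class[[dc]])])
    out[, paste0("drug_", dc) := patient_id %in% ids]
  }
  out[]
}
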