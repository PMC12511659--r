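# End-to-end pipeline orchestration: simulate (or load) claims, build the
# cohort, compute adherence, cluster trajectories, model determinants,
# summarize follow-up, and write a run report with a manifest.

#' Run the full adherence-trajectory pipeline
#'
#' Executes the stages in order -- simulate (or load CSV inputs), cohort,
#' adherence, trajectories, determinants, follow-up, report -- writing every
#' stage output as CSV plus a markdown report and a JSON run manifest into
#' `out_dir`. Deterministic given the configured seed.
#'
#' @param config a [sim_config()], a path to a YAML config file, or `NULL`
#'   for defaults.
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param seed overrides the config seed when not `NULL`.
#' @param t_months overrides `T_months` (36 primary, 60 for the 5-year
#'   secondary analysis).
#' @param forced_k clinical-plausibility override of the voted k.
#' @param k_range candidate numbers of clusters.
#' @param stepwise run stepwise AIC selection over the candidate covariates
#'   (otherwise the full default covariate set is fitted).
#' @param input_tables optional list with `registry`, `dispensings`,
#'   `events` tables to analyse instead of simulating.
#' @return list of class `traj_run` with all stage outputs and the manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, seed = NULL,
                         t_months = NULL, forced_k = NULL, k_range = 2:10,
                         stepwise = FALSE, input_tables = NULL) {
  t0 <- Sys.time()
  if (is.character(config)) {
    loaded <- load_config(config)
    cfg <- loaded$sim
    if (!is.null(loaded$options$forced_k) && is.null(forced_k)) {
      forced_k <- loaded$options$forced_k
    }
    stepwise <- stepwise || loaded$options$stepwise
  } else if (is.null(config)) {
    cfg <- sim_config()
  } else {
    cfg <- config
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(t_months)) {
    cfg$T_months <- as.integer(t_months)
    cfg$rules$T_months <- as.integer(t_months)
  }
  cfg <- validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  rules <- cfg$rules
  timings <- list()
  tick <- function(stage, expr) {
    st <- Sys.time()
    res <- force(expr)
    timings[[stage]] <<- round(as.numeric(difftime(Sys.time(), st,
                                                   units = "secs")), 2)
    message(sprintf("stage=%s event=done elapsed=%.1fs", stage,
                    timings[[stage]]))
    res
  }

  # -- simulate ----------------------------------------------------------
  if (is.null(input_tables)) {
    sim <- tick("simulate", simulate_population(cfg))
    registry <- sim$registry
    dispensings <- sim$dispensings
    events <- sim$events
    true_labels <- sim$true_labels
  } else {
    sim <- NULL
    registry <- data.table::as.data.table(input_tables$registry)
    dispensings <- data.table::as.data.table(input_tables$dispensings)
    events <- data.table::as.data.table(input_tables$events)
    true_labels <- NULL
    check_schema(registry, c("patient_id", "sex", "birth_date", "region",
                             "registry_entry", "registry_exit"), "registry")
    check_schema(dispensings, c("patient_id", "dispense_date", "atc_code",
                                "substance", "product_type", "quantity_ddd",
                                "route"), "dispensings")
    check_schema(events, c("patient_id", "event_date", "code_system",
                           "code"), "events")
  }

  # -- cohort ------------------------------------------------------------
  cb <- tick("cohort", identify_new_users(registry, dispensings, events,
                                          rules))
  cohort <- cb$cohort
  if (nrow(cohort) == 0L) {
    stop("stage=cohort: no patients retained (rows in registry: ",
         nrow(registry), ")", call. = FALSE)
  }
  covars <- tick("covariates",
                 build_covariates(cohort, events, dispensings,
                                  rules$code_lists))
  cohort <- merge(cohort, covars, by = "patient_id")

  # -- adherence ---------------------------------------------------------
  intervals <- tick("coverage",
                    coverage_intervals(dispensings, cohort, cfg$T_months,
                                       rules$biologic_atc))
  series <- tick("adherence", monthly_pdc(intervals, cohort, cfg$T_months))

  # -- trajectories ------------------------------------------------------
  model <- tick("trajectories",
                fit_trajectories(series, k_range = k_range,
                                 forced_k = forced_k,
                                 seed = stage_seed(cfg$seed, "clustering")))
  curves <- mean_pdc_by_group(series, model$assignments)

  # -- determinants ------------------------------------------------------
  det <- tick("determinants", {
    mdat <- model_frame(cohort, model$assignments)
    if (stepwise) {
      sw <- stepwise_aic(mdat$outcome, mdat$covariates, reference = "high")
      list(fit = sw$fit, path = sw$path, selected = sw$selected)
    } else {
      list(fit = fit_multinomial(mdat$outcome, mdat$covariates,
                                 reference = "high"),
           path = NULL, selected = names(mdat$covariates))
    }
  })
  effects <- or_table(det$fit)

  # -- follow-up ---------------------------------------------------------
  switches <- tick("switches", detect_switch(cohort, dispensings,
                                             cfg$T_months,
                                             rules$biologic_atc))
  fu <- tick("followup",
             followup_drug_use(cohort, dispensings, model$assignments,
                               switches, rules$code_lists$drug_class,
                               cfg$T_months))

  out <- list(
    config = cfg, sim = sim, cohort = cohort, attrition = cb$attrition,
    series = series, curves = curves, model = model,
    determinants = det, effects = effects, switches = switches,
    followup = fu, true_labels = true_labels
  )
  class(out) <- "traj_run"

  # -- write -------------------------------------------------------------
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (!is.null(sim)) write_claims(sim, out_dir)
    fw <- function(x, f) data.table::fwrite(x, file.path(out_dir, f),
                                            dateTimeAs = "ISO")
    fw(cohort, "cohort.csv")
    fw(cb$attrition, "attrition.csv")
    adh <- data.table::dcast(series, patient_id ~ paste0("month_", month),
                             value.var = "pdc")
    data.table::setcolorder(adh, c("patient_id",
                                   paste0("month_", seq_len(cfg$T_months))))
    fw(adh, "adherence.csv")
    fw(curves, "curves.csv")
    fw(model$measures, "measures.csv")
    fw(model$assignments, "assignments.csv")
    fw(effects, "effects.csv")
    if (!is.null(det$path)) fw(det$path, "aic_path.csv")
    fw(switches, "switches.csv")
    fw(fu$use, "followup_use.csv")
    jsonlite::write_json(list(
      selected_measures = model$selected_measures,
      eigenvalues = model$selection$eigenvalues,
      index_votes = as.list(model$index_votes),
      k = model$k, k_voted = model$k_voted
    ), file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
    write_report(out, file.path(out_dir, "report.md"))
    files <- sort(list.files(out_dir, pattern = "\\.(csv|md|json)$"))
    files <- setdiff(files, "manifest.json")
    manifest <- list(
      seed = cfg$seed,
      n_subjects = cfg$n_subjects,
      T_months = cfg$T_months,
      mode = cfg$mode,
      timings_sec = timings,
      digests = as.list(tools::md5sum(file.path(out_dir, files))),
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("adheretraj")),
      total_sec = round(as.numeric(difftime(Sys.time(), t0,
                                            units = "secs")), 2)
    )
    names(manifest$digests) <- files
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$manifest <- manifest
  }
  out
}

#' @keywords internal
check_schema <- function(dt, cols, what) {
  miss <- setdiff(cols, names(dt))
  if (length(miss)) {
    stop("table '", what, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(dt)
}

# Assemble the modelling frame: outcome = cluster label, covariates =
# demographics, index-drug attributes, indication, region, and the
# baseline comorbidity/drug-use flags, with the reference levels male,
# 18-44 years, adalimumab, originator, UC.
#' @keywords internal
model_frame <- function(cohort, assignments) {
  x <- merge(cohort, assignments[, .(patient_id, label)], by = "patient_id")
  covs <- data.frame(
    sex = factor(x$sex, levels = c("M", "F")),
    age_band = factor(x$age_band,
                      levels = c("18-44", "<18", "45-64", "65-79", ">=80")),
    index_drug = factor(x$index_substance,
                        levels = c("adalimumab", "golimumab", "infliximab",
                                   "ustekinumab", "vedolizumab")),
    index_type = factor(x$index_type, levels = c("originator", "biosimilar")),
    indication = factor(x$indication, levels = c("UC", "CD")),
    region = factor(x$region)
  )
  covs$age_band <- droplevels(covs$age_band)
  covs$index_drug <- droplevels(covs$index_drug)
  flags <- grep("^(como|drug)_", names(x), value = TRUE)
  for (f in flags) covs[[f]] <- x[[f]]
  list(outcome = x$label, covariates = covs)
}

#' Write the markdown run report
#'
#' Plain-text report with the attrition table, cluster shares, per-cluster
#' monthly mean-PDC curves, the odds-ratio table, and the switch summary.
#' Percentages are printed as 100 n / N rounded to one decimal.
#'
#' @param run a `traj_run` from [run_pipeline()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_report <- function(run, path) {
  stopifnot(inherits(run, "traj_run"))
  for (part in c("attrition", "curves", "effects", "followup")) {
    if (is.null(run[[part]])) {
      stop("missing stage output: ", part, call. = FALSE)
    }
  }
  ln <- character(0)
  add <- function(...) ln <<- c(ln, ...)
  add("# Adherence trajectory analysis", "",
      sprintf("Subjects analysed: %d | follow-up: %d months | seed: %d",
              nrow(run$cohort), run$config$T_months, run$config$seed), "")
  add("## Attrition", "",
      "| step | entering | excluded | retained |",
      "| --- | ---: | ---: | ---: |")
  for (i in seq_len(nrow(run$attrition))) {
    a <- run$attrition[i]
    add(sprintf("| %s | %d | %d | %d |", a$step, a$n_entering, a$n_excluded,
                a$n_retained))
  }
  add("", "## Trajectory clusters", "",
      sprintf("Chosen k = %d (majority vote over %d validity indices; voted k = %d)",
              run$model$k, length(run$model$index_votes), run$model$k_voted),
      "", "| cluster | n | share (%) | mean PDC |", "| --- | ---: | ---: | ---: |")
  N <- nrow(run$model$assignments)
  for (i in seq_len(nrow(run$model$label_map))) {
    m <- run$model$label_map[i]
    add(sprintf("| %s | %d | %s | %.3f |", m$label, m$n, fmt_pct(m$n, N),
                m$mean_pdc))
  }
  add("", "## Monthly mean PDC by cluster", "",
      "| cluster | month | mean PDC | n |", "| --- | ---: | ---: | ---: |")
  for (i in seq_len(nrow(run$curves))) {
    cvr <- run$curves[i]
    add(sprintf("| %s | %d | %.3f | %d |", cvr$group, cvr$month,
                cvr$mean_pdc, cvr$n))
  }
  add("", "## Determinants (odds ratios vs high adherence)", "",
      "| term | contrast | OR | 95% CI |", "| --- | --- | ---: | --- |")
  for (i in seq_len(nrow(run$effects))) {
    e <- run$effects[i]
    add(sprintf("| %s | %s | %.2f | (%.2f, %.2f) |", e$term, e$contrast,
                e$odds_ratio, e$ci_low, e$ci_high))
  }
  add("", "## Switching and follow-up drug use", "",
      "| drug class | cluster | n | % |", "| --- | --- | ---: | ---: |")
  for (i in seq_len(nrow(run$followup$use))) {
    u <- run$followup$use[i]
    add(sprintf("| %s | %s | %d | %s |", u$drug_class, u$cluster, u$n,
                sprintf("%.1f", u$pct)))
  }
  add("", "| cluster | switched | median days | IQR |", "| --- | ---: | ---: | --- |")
  for (i in seq_len(nrow(run$followup$switch_timing))) {
    s <- run$followup$switch_timing[i]
    add(sprintf("| %s | %d | %.0f | (%.0f, %.0f) |", s$cluster, s$n_switched,
                s$median_days, s$q1, s$q3))
  }
  writeLines(ln, path)
  invisible(path)
}
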