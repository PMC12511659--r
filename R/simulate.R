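# Synthetic claims generator with known latent adherence-trajectory classes.
#
# Subjects receive baseline covariates drawn from configurable marginals, a
# latent trajectory class drawn by a multinomial logit on those covariates,
# and dispensing histories whose DDD coverage realizes the class's target
# monthly PDC curve. A configurable fraction of subjects are "distractors"
# that violate exactly one cohort-selection rule each, so the attrition
# cascade can be tested end to end.

#' Calibrate class-membership intercepts
#'
#' Finds the two multinomial-logit intercepts (medium and low vs the high
#' reference) such that the class shares, averaged over the covariate
#' distribution, equal the requested mixture. Solved by Newton iteration on
#' the 2-dimensional share-residual map over the enumerated covariate cells.
#'
#' @param dgp_coefficients nested list covariate -> level -> c(medium, low)
#'   log odds ratios (see [default_dgp_coefficients()]).
#' @param covariate_marginals named list of category probabilities.
#' @param class_weights length-3 target shares (high, medium, low).
#' @param tol convergence tolerance on the share residual (default 1e-4).
#' @param max_iter Newton iteration budget.
#' @return named numeric `c(medium = , low = )`.
#' @export
calibrate_intercepts <- function(dgp_coefficients, covariate_marginals,
                                 class_weights, tol = 1e-4, max_iter = 100L) {
  stopifnot(abs(sum(class_weights) - 1) < 1e-8)
  if (any(!is.finite(unlist(dgp_coefficients)))) {
    stop("dgp_coefficients must be finite", call. = FALSE)
  }
  cells <- dgp_cells(dgp_coefficients, covariate_marginals)
  w <- unname(class_weights)
  # Newton on f(a) = E_x[P(class | x; a)] - w for the medium/low components.
  a <- c(log(w[2] / w[1]), log(w[3] / w[1]))
  for (iter in seq_len(max_iter)) {
    e2 <- exp(a[1] + cells$eta_med)
    e3 <- exp(a[2] + cells$eta_low)
    denom <- 1 + e2 + e3
    p2 <- e2 / denom
    p3 <- e3 / denom
    shares <- c(sum(cells$prob * p2), sum(cells$prob * p3))
    resid <- shares - w[2:3]
    if (max(abs(resid)) < tol) {
      out <- c(medium = a[1], low = a[2])
      attr(out, "residual") <- resid
      return(out)
    }
    J <- matrix(c(
      sum(cells$prob * p2 * (1 - p2)), -sum(cells$prob * p2 * p3),
      -sum(cells$prob * p2 * p3), sum(cells$prob * p3 * (1 - p3))
    ), 2, 2)
    a <- a - solve(J, resid)
  }
  stop(sprintf(
    "intercept calibration did not converge; residual = (%.2e, %.2e)",
    resid[1], resid[2]
  ), call. = FALSE)
}

# Enumerate the joint covariate cells (independence across covariates) with
# their probabilities and class-membership linear predictors.
#' @keywords internal
dgp_cells <- function(dgp_coefficients, covariate_marginals) {
  vars <- names(covariate_marginals)
  vars <- vars[vars %in% names(dgp_coefficients)]
  if (!length(vars)) {
    return(list(prob = 1, eta_med = 0, eta_low = 0))
  }
  grid <- do.call(expand.grid, c(
    lapply(covariate_marginals[vars], names),
    list(stringsAsFactors = FALSE)
  ))
  prob <- rep(1, nrow(grid))
  eta_med <- eta_low <- rep(0, nrow(grid))
  for (v in vars) {
    prob <- prob * covariate_marginals[[v]][grid[[v]]]
    cf <- dgp_coefficients[[v]]
    for (lev in names(cf)) {
      hit <- grid[[v]] == lev
      eta_med[hit] <- eta_med[hit] + cf[[lev]][1]
      eta_low[hit] <- eta_low[hit] + cf[[lev]][2]
    }
  }
  list(prob = unname(prob), eta_med = eta_med, eta_low = eta_low)
}

#' Target monthly PDC of a latent trajectory class
#'
#' The three archetypes: `high` holds a constant adherence level; `medium`
#' declines linearly from its start level to a plateau (0.70 by default) at
#' the change-point month and stays flat; `low` declines linearly from its
#' start level to the end level (0.20) at month `T`.
#'
#' @param class_id one of `"high"`, `"medium"`, `"low"`.
#' @param month month index (1..T), vectorized.
#' @param T_months follow-up length.
#' @param params archetype parameters, see [default_archetype_params()].
#' @return numeric target PDC values in `[0, 1]`.
#' @export
class_archetype <- function(class_id, month, T_months = 36L,
                            params = default_archetype_params()) {
  stopifnot(all(month >= 1), all(month <= T_months))
  switch(class_id,
    high = rep(params$high_level, length(month)),
    medium = {
      cp <- params$medium_changepoint
      lev <- params$medium_start +
        (params$medium_plateau - params$medium_start) * (pmin(month, cp) - 1) / (cp - 1)
      lev
    },
    low = params$low_start +
      (params$low_end - params$low_start) * (month - 1) / (T_months - 1),
    stop("unknown class_id: ", class_id, call. = FALSE)
  )
}

#' Draw per-subject target adherence curves around the class archetypes
#'
#' Builds each subject's latent monthly target PDC: the class archetype,
#' shifted by a subject-level effect and a linear drift on the logit
#' scale, plus stationary AR(1) refill noise whose volatility and
#' persistence are class-dependent with subject-level jitter (see
#' [default_archetype_params()]). Uses the current RNG stream.
#'
#' @param true_class character vector of class labels.
#' @param T_months follow-up length.
#' @param params archetype parameters, see [default_archetype_params()].
#' @return numeric matrix (subjects x months) of target PDC in `[0, 1]`.
#' @export
subject_curves <- function(true_class, T_months,
                           params = default_archetype_params()) {
  n <- length(true_class)
  ap <- params
  arch <- matrix(0, n, T_months)
  for (cl in c("high", "medium", "low")) {
    idx <- which(true_class == cl)
    if (length(idx)) {
      arch[idx, ] <- matrix(
        class_archetype(cl, 1:T_months, T_months, ap),
        length(idx), T_months, byrow = TRUE
      )
    }
  }
  # subject-level smooth deviations (logit scale)
  lvl <- stats::rnorm(n, 0, ap$subject_level_sd %||% 0)
  drift <- stats::rnorm(n, 0, ap$subject_drift_sd %||% 0)
  tfrac <- matrix((seq_len(T_months) - 1) / (T_months - 1), n, T_months,
                  byrow = TRUE)
  # AR(1) refill noise, stationary on the logit scale. Subjects carry two
  # independent noise traits: the magnitude of month-to-month supply
  # changes (`d_noise`, the SD of first differences of the noise) and the
  # refill dynamic `noise_ar` (persistent supply episodes vs gap-then-
  # catch-up oscillation). The level SD implied by the two is
  # sigma = delta / sqrt(2 (1 - phi)).
  d_noise <- ap$d_noise %||% c(high = 0, medium = 0, low = 0)
  noise_ar <- ap$noise_ar %||% c(high = 0, medium = 0, low = 0)
  delta <- d_noise[true_class] * exp(stats::rnorm(n, 0, ap$subject_noise_sd %||% 0))
  phi <- pmin(pmax(noise_ar[true_class] +
                     stats::rnorm(n, 0, ap$subject_ar_sd %||% 0), -0.9), 0.9)
  sig <- delta / sqrt(2 * (1 - phi))
  eps <- matrix(0, n, T_months)
  eps[, 1L] <- stats::rnorm(n, 0, 1)
  for (t in 2:T_months) {
    eps[, t] <- phi * eps[, t - 1L] + sqrt(1 - phi^2) * stats::rnorm(n)
  }
  lgt <- stats::qlogis(pmin(pmax(arch, 1e-4), 1 - 1e-4)) + lvl +
    drift * tfrac + sig * eps
  stats::plogis(lgt)
}

# Follow-up month windows for one index date: Date boundaries and day offsets.
#' @keywords internal
month_window_offsets <- function(index_date, T_months) {
  b <- add_months(index_date, 0:T_months)
  off <- as.integer(b - index_date)
  list(start = off[-(T_months + 1)], end = off[-1],
       len = diff(off), dates = b)
}

#' Emit dispensing records realizing a target adherence curve
#'
#' Inverse of the monthly PDC computation for a single patient. In `exact`
#' mode, one dispensing is placed at each monthly window start, sized (in
#' DDDs, at one DDD per day of coverage) so that the realized monthly PDC
#' equals the target up to whole-day rounding; quantities never exceed the
#' window length so no coverage carries into later windows. In `noisy` mode,
#' fixed pack sizes (28 DDDs subcutaneous, 56 intravenous) are dispensed at
#' refill intervals stretched by the inverse of the local target PDC and
#' jittered by a few days, so realized PDC matches the target in expectation.
#'
#' @param target_curve numeric vector of monthly target PDC in `[0, 1]`.
#' @param index_date Date of the first (index) dispensing.
#' @param drug_plan list with `substance`, `atc_code`, `product_type`,
#'   `route`, and optionally `switch_day` (integer day offset),
#'   `switch_substance`, `switch_atc`, `switch_product_type`, `switch_route`.
#' @param mode `"exact"` or `"noisy"`.
#' @param seed RNG seed (noisy mode).
#' @return data.table of dispensing records (`dispense_date`, `atc_code`,
#'   `substance`, `product_type`, `quantity_ddd`, `route`).
#' @export
emit_dispensings <- function(target_curve, index_date, drug_plan,
                             mode = c("exact", "noisy"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(target_curve >= 0), all(target_curve <= 1))
  T_months <- length(target_curve)
  win <- month_window_offsets(index_date, T_months)
  if (target_curve[1] <= 0 && all(target_curve[-1] <= 0)) {
    stop("target curve has no coverage; a cohort requires an index dispensing",
         call. = FALSE)
  }
  if (mode == "exact") {
    set.seed(seed)
    q <- dither_round(target_curve * win$len)
    q[1] <- max(q[1], 1)  # the index dispensing must exist
    keep <- q >= 1
    dt <- data.table::data.table(
      offset = win$start[keep],
      quantity_ddd = as.numeric(q[keep])
    )
  } else {
    set.seed(seed)
    followup_days <- win$end[T_months]
    offs <- numeric(0)
    qs <- numeric(0)
    t <- 0L
    pack_for <- function(route) if (route == "IV") 56 else 28
    while (t < followup_days) {
      m <- findInterval(t, win$start)
      tgt <- max(target_curve[m], 0.02)
      route_now <- if (!is.null(drug_plan$switch_day) &&
                         t >= drug_plan$switch_day) {
        drug_plan$switch_route %||% drug_plan$route
      } else {
        drug_plan$route
      }
      pack <- pack_for(route_now)
      offs <- c(offs, t)
      qs <- c(qs, pack)
      gap <- round(pack / tgt) + sample(-3:3, 1)
      t <- t + max(gap, 7L)
    }
    dt <- data.table::data.table(offset = as.integer(offs), quantity_ddd = qs)
  }
  dt[, dispense_date := index_date + offset]
  post <- if (!is.null(drug_plan$switch_day)) dt$offset >= drug_plan$switch_day else
    rep(FALSE, nrow(dt))
  dt[, `:=`(
    substance = ifelse(post, drug_plan$switch_substance %||% drug_plan$substance,
                       drug_plan$substance),
    atc_code = ifelse(post, drug_plan$switch_atc %||% drug_plan$atc_code,
                      drug_plan$atc_code),
    product_type = ifelse(post,
                          drug_plan$switch_product_type %||% drug_plan$product_type,
                          drug_plan$product_type),
    route = ifelse(post, drug_plan$switch_route %||% drug_plan$route,
                   drug_plan$route)
  )]
  dt[, offset := NULL]
  data.table::setcolorder(dt, c("dispense_date", "atc_code", "substance",
                                "product_type", "quantity_ddd", "route"))
  dt[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Unbiased randomized rounding to whole DDDs: floor(x) + Bernoulli(frac).
# Keeps the realized monthly PDC within one day of the target while avoiding
# the deterministic quantization lattice that plain rounding would imprint
# on every subject sharing a target curve.
#' @keywords internal
dither_round <- function(x) {
  f <- floor(x)
  f + (stats::runif(length(x)) < (x - f))
}

#' Draw subjects: covariates, latent class, dates
#'
#' The covariate-and-class stage of the generator: baseline covariates from
#' the configured marginals, latent trajectory class by multinomial logit
#' with calibrated intercepts, distractor designation, and registry/index
#' dates consistent with eligibility (or with exactly the violated rule).
#'
#' @param config a [sim_config()].
#' @return data.table, one row per subject, with covariates, `true_class`,
#'   `distractor`, `index_date`, `birth_date`, `registry_entry`,
#'   `registry_exit`.
#' @export
simulate_subjects <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "subjects"))
  n <- config$n_subjects
  cm <- config$covariate_marginals
  rules <- config$rules
  T_months <- config$T_months

  draw <- function(m) names(m)[sample.int(length(m), n, replace = TRUE, prob = m)]
  dt <- data.table::data.table(
    patient_id = sprintf("P%06d", seq_len(n)),
    sex = draw(cm$sex),
    age_band = draw(cm$age_band),
    region = draw(cm$region),
    index_drug = draw(cm$index_drug),
    index_type = draw(cm$index_type),
    indication = draw(cm$indication)
  )

  # Latent class by multinomial logit on the drawn covariates.
  w <- config$class_weights
  if (any(w == 1)) {
    dt[, true_class := c("high", "medium", "low")[which(w == 1)]]
  } else {
    keep <- w > 0
    ic <- calibrate_intercepts(config$dgp_coefficients, cm, w / sum(w))
    eta_med <- rep(ic[["medium"]], n)
    eta_low <- rep(ic[["low"]], n)
    for (v in names(config$dgp_coefficients)) {
      cf <- config$dgp_coefficients[[v]]
      for (lev in names(cf)) {
        hit <- dt[[v]] == lev
        eta_med[hit] <- eta_med[hit] + cf[[lev]][1]
        eta_low[hit] <- eta_low[hit] + cf[[lev]][2]
      }
    }
    p <- cbind(1, exp(eta_med), exp(eta_low))
    p[, !keep] <- 0
    p <- p / rowSums(p)
    u <- stats::runif(n)
    cls <- 1L + (u > p[, 1]) + (u > p[, 1] + p[, 2])
    dt[, true_class := c("high", "medium", "low")[cls]]
  }

  # Distractor designation: each distractor violates exactly one rule.
  dr <- config$distractor_rates
  dprob <- c(none = 1 - sum(dr), dr)
  dt[, distractor := names(dprob)[
    sample.int(length(dprob), n, replace = TRUE, prob = dprob)
  ]]

  # Index dates uniform over the study window; ustekinumab only after its
  # IBD market-entry date; washout violators need an early-window index so
  # their prior dispensing falls before the window opens.
  window_days <- as.integer(rules$study_end - rules$study_start)
  dt[distractor == "washout" & index_drug == "ustekinumab",
     index_drug := "adalimumab"]
  dt[, day0 := sample.int(window_days + 1L, .N, replace = TRUE) - 1L]
  ust_off <- as.integer(rules$ustekinumab_start - rules$study_start)
  dt[index_drug == "ustekinumab",
     day0 := ust_off + sample.int(window_days - ust_off + 1L, .N, replace = TRUE) - 1L]
  dt[distractor == "washout", day0 := sample.int(150L, .N, replace = TRUE) - 1L]
  dt[, index_date := rules$study_start + day0]
  dt[, day0 := NULL]

  # Ages consistent with the band; birth date anchored at the index date.
  lo <- c("<18" = 12, "18-44" = 18, "45-64" = 45, "65-79" = 65, ">=80" = 80)
  hi <- c("<18" = 17, "18-44" = 44, "45-64" = 64, "65-79" = 79, ">=80" = 92)
  age <- lo[dt$age_band] + stats::runif(n) * (hi[dt$age_band] - lo[dt$age_band] + 0.99)
  dt[, birth_date := index_date - round(age * 365.25)]

  # Registry interval: eligible subjects cover >= 1 year before the index
  # date and the whole follow-up after it; violators break exactly one rule.
  followup_end <- add_months(dt$index_date, T_months)
  dt[, registry_entry := index_date - 365L - sample(0:1500, .N, replace = TRUE)]
  dt[, registry_exit := followup_end + sample(0:730, .N, replace = TRUE)]
  dt[distractor == "lookback",
     registry_entry := index_date - sample(30:364, .N, replace = TRUE)]
  fu_days <- as.integer(followup_end - dt$index_date)
  short <- dt$distractor == "followup"
  if (any(short)) {
    dt$registry_exit[short] <- dt$index_date[short] +
      vapply(fu_days[short], function(d) sample(60:(d - 30L), 1L), integer(1))
  }
  dt[]
}

#' Simulate a synthetic claims database
#'
#' Generates the four linked tables emulating an administrative healthcare
#' database: patient registry, pharmacy dispensing claims (biologics whose
#' coverage realizes each subject's latent trajectory, plus non-biologic
#' therapies), diagnosis/exemption events, and the latent truth
#' (trajectory class, distractor label, target curve). Deterministic given
#' the configured seed.
#'
#' @param config a [sim_config()].
#' @return list of class `claims_sim` with data.tables `registry`,
#'   `dispensings`, `events`, `true_labels`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  subjects <- simulate_subjects(config)
  n <- nrow(subjects)
  T_months <- config$T_months
  catalog <- config$rules$drug_catalog

  # --- target curves ---------------------------------------------------
  set.seed(stage_seed(config$seed, "curves"))
  curve <- subject_curves(subjects$true_class, T_months,
                          config$archetype_params)
  if (config$mode == "noisy" && config$noise_sd > 0) {
    lgt <- stats::qlogis(pmin(pmax(curve, 1e-4), 1 - 1e-4)) +
      stats::rnorm(length(curve), 0, config$noise_sd)
    curve <- stats::plogis(lgt)
  }

  # --- switch plans ----------------------------------------------------
  set.seed(stage_seed(config$seed, "switches"))
  cat_by_sub <- catalog[match(subjects$index_drug, catalog$substance)]
  p_sw <- config$switch_probs[subjects$true_class]
  has_switch <- stats::runif(n) < p_sw
  fu_days <- as.integer(add_months(subjects$index_date, T_months) -
                          subjects$index_date)
  switch_day <- ifelse(
    has_switch,
    31L + floor(stats::runif(n) * pmax(fu_days - 31L, 1L)),
    NA_integer_
  )
  kind_type <- has_switch & stats::runif(n) < 0.30
  new_sub <- subjects$index_drug
  for (i in which(has_switch & !kind_type)) {
    others <- setdiff(catalog$substance, subjects$index_drug[i])
    new_sub[i] <- others[sample.int(length(others), 1L)]
  }
  new_cat <- catalog[match(new_sub, catalog$substance)]
  new_type <- ifelse(kind_type,
                     ifelse(subjects$index_type == "originator",
                            "biosimilar", "originator"),
                     ifelse(has_switch, "originator", subjects$index_type))

  # --- biologic dispensings --------------------------------------------
  set.seed(stage_seed(config$seed, "dispensings"))
  if (config$mode == "exact") {
    # Window starts/lengths for all subjects x months, vectorized.
    boundaries <- add_months(rep(subjects$index_date, each = T_months + 1L),
                             rep(0:T_months, n))
    bmat <- matrix(as.integer(boundaries - rep(subjects$index_date,
                                               each = T_months + 1L)),
                   n, T_months + 1L, byrow = TRUE)
    starts <- bmat[, -(T_months + 1L), drop = FALSE]
    lens <- bmat[, -1L, drop = FALSE] - starts
    q <- matrix(dither_round(curve * lens), nrow(curve), ncol(curve))
    q[, 1L] <- pmax(q[, 1L], 1)
    disp <- data.table::data.table(
      row = rep(seq_len(n), T_months),
      offset = as.vector(starts),
      quantity_ddd = as.numeric(as.vector(q))
    )[quantity_ddd >= 1]
  } else {
    parts <- vector("list", n)
    for (i in seq_len(n)) {
      plan <- list(substance = subjects$index_drug[i],
                   atc_code = cat_by_sub$atc_code[i],
                   product_type = subjects$index_type[i],
                   route = cat_by_sub$route[i])
      if (has_switch[i]) {
        plan$switch_day <- switch_day[i]
        plan$switch_route <- new_cat$route[i]
      }
      d <- emit_dispensings(curve[i, ], subjects$index_date[i], plan,
                            mode = "noisy",
                            seed = stage_seed(config$seed, paste0("emit", i)))
      parts[[i]] <- data.table::data.table(
        row = i,
        offset = as.integer(d$dispense_date - subjects$index_date[i]),
        quantity_ddd = d$quantity_ddd
      )
    }
    disp <- data.table::rbindlist(parts)
  }
  post <- !is.na(switch_day[disp$row]) & disp$offset >= switch_day[disp$row]
  bio <- data.table::data.table(
    patient_id = subjects$patient_id[disp$row],
    dispense_date = subjects$index_date[disp$row] + disp$offset,
    atc_code = ifelse(post, new_cat$atc_code[disp$row],
                      cat_by_sub$atc_code[disp$row]),
    substance = ifelse(post, new_sub[disp$row], subjects$index_drug[disp$row]),
    product_type = ifelse(post, new_type[disp$row],
                          subjects$index_type[disp$row]),
    quantity_ddd = disp$quantity_ddd,
    route = ifelse(post, new_cat$route[disp$row], cat_by_sub$route[disp$row])
  )
  # Washout violators: one prior dispensing of the index drug inside the
  # washout window but before the study window opens.
  wv <- which(subjects$distractor == "washout")
  if (length(wv)) {
    gap <- vapply(wv, function(i) {
      lo <- as.integer(subjects$index_date[i] - config$rules$study_start) + 1L
      sample(lo:364L, 1L)
    }, integer(1))
    bio <- rbind(bio, data.table::data.table(
      patient_id = subjects$patient_id[wv],
      dispense_date = subjects$index_date[wv] - gap,
      atc_code = cat_by_sub$atc_code[wv],
      substance = subjects$index_drug[wv],
      product_type = subjects$index_type[wv],
      quantity_ddd = 30,
      route = cat_by_sub$route[wv]
    ))
  }
  # Respect the registry interval (short-follow-up violators exit early).
  bio <- bio[dispense_date >= subjects$registry_entry[match(patient_id, subjects$patient_id)] &
               dispense_date <= subjects$registry_exit[match(patient_id, subjects$patient_id)]]

  # --- non-biologic dispensings ----------------------------------------
  set.seed(stage_seed(config$seed, "comedication"))
  atc_of <- c(antiplatelets = "B01AC06", anticoagulants = "B01AA03",
              antidepressants = "N06AB06", peptic_ulcer_gerd = "A02BC01",
              methotrexate = "L04AX03", glucocorticoids = "H02AB06",
              nsaids = "M01AE01")
  pre_rates <- c(anticoagulants = 0.034, peptic_ulcer_gerd = 0.032,
                 glucocorticoids = 0.019, nsaids = 0.016,
                 antidepressants = 0.009, methotrexate = 0.009)
  # follow-up use rates by latent class (high, medium, low), echoing the
  # gradient of co-medication across adherence groups
  post_rates <- list(
    anticoagulants = c(high = 0.040, medium = 0.077, low = 0.120),
    peptic_ulcer_gerd = c(high = 0.027, medium = 0.032, low = 0.045),
    antidepressants = c(high = 0.023, medium = 0.030, low = 0.039),
    antiplatelets = c(high = 0.009, medium = 0.008, low = 0.015),
    nsaids = c(high = 0.035, medium = 0.041, low = 0.043),
    glucocorticoids = c(high = 0.027, medium = 0.031, low = 0.030)
  )
  nb <- list()
  for (cls_name in names(pre_rates)) {
    hit <- which(stats::runif(n) < pre_rates[[cls_name]])
    if (length(hit)) {
      nb[[paste0("pre_", cls_name)]] <- data.table::data.table(
        patient_id = subjects$patient_id[hit],
        dispense_date = subjects$index_date[hit] -
          sample(1:365, length(hit), replace = TRUE),
        atc_code = atc_of[[cls_name]],
        substance = cls_name, product_type = "not_applicable",
        quantity_ddd = 30, route = "other"
      )
    }
  }
  for (cls_name in names(post_rates)) {
    p_use <- post_rates[[cls_name]][subjects$true_class]
    hit <- which(stats::runif(n) < p_use)
    if (length(hit)) {
      nb[[paste0("post_", cls_name)]] <- data.table::data.table(
        patient_id = subjects$patient_id[hit],
        dispense_date = subjects$index_date[hit] +
          1L + floor(stats::runif(length(hit)) * (fu_days[hit] - 1L)),
        atc_code = atc_of[[cls_name]],
        substance = cls_name, product_type = "not_applicable",
        quantity_ddd = 30, route = "other"
      )
    }
  }
  nb <- data.table::rbindlist(nb)
  if (nrow(nb)) {
    nb <- nb[dispense_date >= subjects$registry_entry[match(patient_id, subjects$patient_id)] &
               dispense_date <= subjects$registry_exit[match(patient_id, subjects$patient_id)]]
  }
  dispensings <- rbind(bio, nb)
  data.table::setorder(dispensings, patient_id, dispense_date, atc_code)

  # --- events: indication + comorbidities ------------------------------
  set.seed(stage_seed(config$seed, "events"))
  icd_codes <- list(CD = c("555.0", "555.1", "555.9"),
                    UC = c("556.9", "556.5", "556.6"))
  exe_codes <- list(CD = "009.555", UC = "009.556")
  ev <- list()
  ibd_idx <- which(subjects$distractor != "non_ibd")
  n_evt <- sample(1:3, length(ibd_idx), replace = TRUE)
  rows <- rep(ibd_idx, n_evt)
  span <- pmin(as.integer(subjects$index_date[rows] -
                            subjects$registry_entry[rows]) - 1L, 1200L)
  back <- floor(stats::runif(length(rows)) * span)
  cond <- subjects$indication[rows]
  use_exe <- stats::runif(length(rows)) < 0.3
  ev$ibd <- data.table::data.table(
    patient_id = subjects$patient_id[rows],
    event_date = subjects$index_date[rows] - back,
    code_system = ifelse(use_exe, "EXEMPTION", "ICD9CM"),
    code = ifelse(
      use_exe, unlist(exe_codes)[match(cond, names(exe_codes))],
      vapply(cond, function(cc) sample(icd_codes[[cc]], 1L), character(1))
    )
  )
  # A cross-condition noise event strictly older than every own-condition
  # event, so the most-recent rule still resolves to the drawn indication.
  nz <- ibd_idx[stats::runif(length(ibd_idx)) < 0.15]
  if (length(nz)) {
    oldest <- ev$ibd[, .(old = min(event_date)), by = patient_id]
    old_of <- oldest$old[match(subjects$patient_id[nz], oldest$patient_id)]
    dte <- pmax(subjects$registry_entry[nz], old_of - sample(30:300, length(nz),
                                                             replace = TRUE))
    ok <- dte < old_of
    if (any(ok)) {
      other <- ifelse(subjects$indication[nz[ok]] == "CD", "UC", "CD")
      ev$noise <- data.table::data.table(
        patient_id = subjects$patient_id[nz[ok]],
        event_date = dte[ok],
        code_system = "ICD9CM",
        code = vapply(other, function(cc) sample(icd_codes[[cc]], 1L),
                      character(1))
      )
    }
  }
  como_codes <- c(hypertension = "401.9", diabetes = "250.00",
                  cerebrovascular_disease = "434.91",
                  chronic_pulmonary_disease = "496",
                  ankylosing_spondylitis = "720.0",
                  intestinal_infection = "008.45")
  como_rates <- c(hypertension = 0.089, diabetes = 0.041,
                  cerebrovascular_disease = 0.011,
                  chronic_pulmonary_disease = 0.010,
                  ankylosing_spondylitis = 0.044,
                  intestinal_infection = 0.115)
  for (cm_name in names(como_rates)) {
    hit <- which(stats::runif(n) < como_rates[[cm_name]])
    hit <- hit[subjects$index_date[hit] - subjects$registry_entry[hit] > 2]
    if (length(hit)) {
      span <- as.integer(subjects$index_date[hit] - subjects$registry_entry[hit]) - 1L
      ev[[cm_name]] <- data.table::data.table(
        patient_id = subjects$patient_id[hit],
        event_date = subjects$index_date[hit] - 1L -
          floor(stats::runif(length(hit)) * span),
        code_system = "ICD9CM",
        code = como_codes[[cm_name]]
      )
    }
  }
  # Non-IBD distractors carry at least one (non-IBD) event.
  ni <- which(subjects$distractor == "non_ibd")
  if (length(ni)) {
    ev$non_ibd <- data.table::data.table(
      patient_id = subjects$patient_id[ni],
      event_date = subjects$index_date[ni] -
        sample(10:400, length(ni), replace = TRUE),
      code_system = "ICD9CM",
      code = "401.9"
    )
  }
  events <- data.table::rbindlist(ev)
  events <- events[event_date >= subjects$registry_entry[match(patient_id, subjects$patient_id)] &
                     event_date <= subjects$registry_exit[match(patient_id, subjects$patient_id)]]
  data.table::setorder(events, patient_id, event_date, code)

  registry <- subjects[, .(patient_id, sex, birth_date, region,
                           registry_entry, registry_exit)]
  labels <- data.table::data.table(
    patient_id = subjects$patient_id,
    true_class = subjects$true_class,
    distractor = subjects$distractor
  )
  tc <- data.table::as.data.table(curve)
  data.table::setnames(tc, paste0("month_", seq_len(T_months)))
  labels <- cbind(labels, tc)

  out <- list(registry = registry, dispensings = dispensings,
              events = events, true_labels = labels,
              config = config)
  class(out) <- "claims_sim"
  out
}

#' @export
print.claims_sim <- function(x, ...) {
  cat("Synthetic claims database:",
      nrow(x$registry), "subjects,",
      nrow(x$dispensings), "dispensings,",
      nrow(x$events), "events\n")
  cat("Latent classes:",
      paste(sprintf("%s %.1f%%", names(table(x$true_labels$true_class)),
                    100 * prop.table(table(x$true_labels$true_class))),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write the simulated tables as CSV files
#'
#' Writes `registry.csv`, `dispensings.csv`, `events.csv` and
#' `true_labels.csv` (UTF-8, ISO-8601 dates) into a directory.
#'
#' @param sim a `claims_sim` from [simulate_population()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_claims <- function(sim, dir) {
  stopifnot(inherits(sim, "claims_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("registry.csv", "dispensings.csv", "events.csv",
                            "true_labels.csv"))
  data.table::fwrite(sim$registry, paths[1], dateTimeAs = "ISO")
  data.table::fwrite(sim$dispensings, paths[2], dateTimeAs = "ISO")
  data.table::fwrite(sim$events, paths[3], dateTimeAs = "ISO")
  data.table::fwrite(sim$true_labels, paths[4], dateTimeAs = "ISO")
  invisible(paths)
}
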