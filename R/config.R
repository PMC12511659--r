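# Simulation and pipeline configuration with study defaults.
#
# Defaults encode the study conditions the generator emulates: a three-class
# mixture of adherence trajectories (19/46/35%), covariate-dependent class
# membership with published odds ratios, Italian-region structure, and the
# five IBD biologics with their ATC codes.

#' Default covariate marginals
#'
#' Category probabilities used to draw baseline covariates independently of
#' one another. Values follow the cohort composition reported for a large
#' Italian multi-regional IBD biologics cohort (male 55.5%, under-65 92%,
#' Crohn's disease 58.2%, biosimilar index 22.4%, and the corresponding
#' index-drug and region shares).
#'
#' @return named list of named probability vectors.
#' @export
default_covariate_marginals <- function() {
  list(
    sex = c(M = 0.555, F = 0.445),
    age_band = c("<18" = 0.061, "18-44" = 0.498, "45-64" = 0.360,
                 "65-79" = 0.078, ">=80" = 0.003),
    index_drug = c(adalimumab = 0.473, golimumab = 0.049, infliximab = 0.412,
                   ustekinumab = 0.004, vedolizumab = 0.061),
    index_type = c(originator = 0.776, biosimilar = 0.224),
    indication = c(CD = 0.582, UC = 0.418),
    region = c(
      Abruzzo = 0.021, `Emilia-Romagna` = 0.103, `Friuli-Venezia Giulia` = 0.022,
      Lazio = 0.091, Lombardy = 0.172, Marche = 0.052, Puglia = 0.138,
      Sardegna = 0.027, Sicily = 0.148, Tuscany = 0.089, Umbria = 0.024,
      Veneto = 0.113
    )
  )
}

#' Default class-membership log-odds ratios
#'
#' Log odds ratios that link baseline covariates to latent trajectory-class
#' membership in the generator's multinomial-logit model. Reference class is
#' the high-adherence trajectory; each entry gives
#' `c(medium = , low = )` contrasts for one covariate level versus its
#' reference level (male, 18-44 years, adalimumab, originator, UC).
#' Defaults encode the published determinants: female OR 1.52 and older-age
#' OR 1.44 for low vs high, biosimilar 0.47, golimumab 0.46, infliximab 0.78,
#' ustekinumab 0.10, vedolizumab 0.30 (low vs high), and Crohn's disease 1.35
#' for medium vs high.
#'
#' @return nested named list: covariate -> level -> length-2 numeric.
#' @export
default_dgp_coefficients <- function() {
  list(
    sex = list(F = c(medium = 0, low = log(1.52))),
    age_band = list(
      `65-79` = c(medium = 0, low = log(1.44)),
      `>=80` = c(medium = 0, low = log(1.44))
    ),
    index_drug = list(
      golimumab = c(medium = 0, low = log(0.46)),
      infliximab = c(medium = 0, low = log(0.78)),
      ustekinumab = c(medium = 0, low = log(0.10)),
      vedolizumab = c(medium = 0, low = log(0.30))
    ),
    index_type = list(biosimilar = c(medium = 0, low = log(0.47))),
    indication = list(CD = c(medium = log(1.35), low = 0))
  )
}

#' Default archetype curve parameters
#'
#' Shapes of the three latent monthly-PDC trajectories: a constant
#' high-adherence level; an early decline to a stable plateau around 0.70 by
#' month 9; and a steady decline reaching 0.20 at the end of follow-up.
#' Start levels (0.95 medium, 0.90 low) are calibration choices; the plateau,
#' endpoint and high level follow the reported trajectory descriptions.
#'
#' Subjects deviate from their class archetype along behavioural traits,
#' mirroring the within-cluster heterogeneity of real refill behaviour
#' while leaving each class's mean curve near the archetype: a level shift
#' (`subject_level_sd`, logit scale); a linear drift accumulating to +/-
#' `subject_drift_sd` (logit) by the end of follow-up; and month-to-month
#' refill noise following a stationary AR(1) process on the logit scale.
#' The noise is parameterized by the magnitude of month-to-month supply
#' changes (`d_noise`, the SD of the noise's first differences, logit
#' scale) and its dynamic (`noise_ar`): steady supply with slow persistent
#' episodes for high adherers versus larger, more erratic swings for the
#' declining classes, with per-subject lognormal magnitude
#' (`subject_noise_sd`) and persistence jitter (`subject_ar_sd`). The
#' refill-irregularity gradient is what makes the fluctuation-type change
#' measures class-informative, as they are in observed claims data.
#'
#' @return named list of curve parameters.
#' @export
default_archetype_params <- function() {
  list(
    high_level = 0.95,
    medium_start = 0.95, medium_plateau = 0.70, medium_changepoint = 9,
    low_start = 0.90, low_end = 0.20,
    subject_level_sd = 0.18, subject_drift_sd = 0.30,
    d_noise = c(high = 0.18, medium = 1.0, low = 0.30),
    noise_ar = c(high = 0.65, medium = 0.15, low = 0.50),
    subject_noise_sd = 0.10, subject_ar_sd = 0.08
  )
}

#' Drug catalog for the five IBD biologics
#'
#' Maps ATC code to substance, administration route and therapeutic class
#' (TNF-alpha inhibitors L04AB*, anti-interleukin L04AC05, selective
#' immunosuppressant L04AA33).
#'
#' @return data.table with columns `atc_code`, `substance`, `route`,
#'   `index_class`.
#' @export
default_drug_catalog <- function() {
  data.table::data.table(
    atc_code = c("L04AB04", "L04AB02", "L04AB06", "L04AA33", "L04AC05"),
    substance = c("adalimumab", "infliximab", "golimumab", "vedolizumab",
                  "ustekinumab"),
    route = c("SC", "IV", "SC", "IV", "SC"),
    index_class = c("TNF-alpha inhibitor", "TNF-alpha inhibitor",
                    "TNF-alpha inhibitor", "selective immunosuppressant",
                    "anti-interleukin")
  )
}

#' Default diagnosis and drug-class code lists
#'
#' Indication code lists (ICD-9-CM 555* for Crohn's disease, 556* for
#' ulcerative colitis, plus the corresponding co-payment exemption codes),
#' comorbidity diagnosis prefixes, and ATC prefixes for the drug classes
#' summarized at baseline and during follow-up.
#'
#' @return named list with elements `indication`, `comorbidity`,
#'   `drug_class`.
#' @export
default_code_lists <- function() {
  list(
    indication = list(
      CD = c("555", "009.555"),
      UC = c("556", "009.556")
    ),
    comorbidity = list(
      hypertension = "401",
      diabetes = "250",
      cerebrovascular_disease = "43",
      chronic_pulmonary_disease = "49",
      ankylosing_spondylitis = "720",
      intestinal_infection = "00"
    ),
    drug_class = list(
      antiplatelets = "B01AC",
      anticoagulants = "B01AA",
      antidepressants = "N06A",
      peptic_ulcer_gerd = "A02B",
      methotrexate = "L04AX03",
      glucocorticoids = "H02AB",
      nsaids = "M01A"
    )
  )
}

#' Cohort-selection rules
#'
#' The inclusion cascade parameters: eligible biologic ATC codes, study
#' window for index dates, the ustekinumab market-entry date rule, look-back
#' and washout lengths, and required follow-up.
#'
#' @param T_months follow-up length in months (36 primary, 60 secondary).
#' @return named list of rule parameters.
#' @export
default_rules <- function(T_months = 36) {
  list(
    biologic_atc = default_drug_catalog()$atc_code,
    study_start = as.Date("2010-01-01"),
    study_end = as.Date("2019-12-31"),
    ustekinumab_start = as.Date("2018-09-01"),
    lookback_days = 365L,
    washout_days = 365L,
    T_months = as.integer(T_months),
    code_lists = default_code_lists(),
    drug_catalog = default_drug_catalog()
  )
}

#' Build a simulation configuration
#'
#' Assembles and validates the full configuration of the synthetic claims
#' generator. All defaults encode the emulated study conditions; every value
#' can be overridden.
#'
#' @param n_subjects number of subjects to simulate (>= 10).
#' @param seed integer RNG seed; all generator randomness flows from it.
#' @param T_months follow-up length in months (>= 3; 36 default, 60
#'   supported for the 5-year secondary analysis).
#' @param class_weights length-3 probabilities of the high/medium/low
#'   trajectory classes (default 0.19/0.46/0.35).
#' @param archetype_params see [default_archetype_params()].
#' @param dgp_coefficients see [default_dgp_coefficients()].
#' @param covariate_marginals see [default_covariate_marginals()].
#' @param noise_sd monthly PDC jitter on the logit scale (noisy mode only).
#' @param distractor_rates probabilities that a subject violates one named
#'   attrition rule (`washout`, `lookback`, `followup`, `non_ibd`).
#' @param switch_probs per-class probability of a biologic switch during
#'   follow-up (defaults 0.326/0.455/0.258 for high/medium/low).
#' @param mode `"exact"` (dispensings sized to realize the target monthly
#'   PDC up to day rounding) or `"noisy"` (fixed pack sizes, jittered refill
#'   timing).
#' @param rules cohort-selection rules, see [default_rules()].
#' @return object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_subjects = 1000L,
                       seed = 1L,
                       T_months = 36L,
                       class_weights = c(high = 0.19, medium = 0.46, low = 0.35),
                       archetype_params = default_archetype_params(),
                       dgp_coefficients = default_dgp_coefficients(),
                       covariate_marginals = default_covariate_marginals(),
                       noise_sd = 0.30,
                       distractor_rates = c(washout = 0.02, lookback = 0.02,
                                            followup = 0.02, non_ibd = 0.02),
                       switch_probs = c(high = 0.326, medium = 0.455, low = 0.258),
                       mode = c("exact", "noisy"),
                       rules = default_rules(T_months)) {
  mode <- match.arg(mode)
  cfg <- list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    T_months = as.integer(T_months), class_weights = class_weights,
    archetype_params = archetype_params, dgp_coefficients = dgp_coefficients,
    covariate_marginals = covariate_marginals, noise_sd = noise_sd,
    distractor_rates = distractor_rates, switch_probs = switch_probs,
    mode = mode, rules = rules
  )
  cfg$rules$T_months <- cfg$T_months
  cfg <- validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  if (cfg$n_subjects < 10) {
    stop("n_subjects must be at least 10", call. = FALSE)
  }
  if (cfg$T_months < 3) {
    stop("T_months must be at least 3 (change measures need >= 3 values)",
         call. = FALSE)
  }
  w <- cfg$class_weights
  if (length(w) != 3 || any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("class_weights must be 3 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  for (i in seq_along(cfg$covariate_marginals)) {
    m <- cfg$covariate_marginals[[i]]
    # tolerate printed-table rounding (shares summing to e.g. 99.9%)
    if (any(m < 0) || abs(sum(m) - 1) > 0.02) {
      stop("each covariate marginal must be probabilities summing to 1",
           call. = FALSE)
    }
    cfg$covariate_marginals[[i]] <- m / sum(m)
  }
  coefs <- unlist(cfg$dgp_coefficients)
  if (length(coefs) && any(!is.finite(coefs))) {
    stop("dgp_coefficients must be finite", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  dr <- cfg$distractor_rates
  if (any(dr < 0) || sum(dr) >= 1) {
    stop("distractor_rates must be non-negative and sum to < 1", call. = FALSE)
  }
  if (any(cfg$switch_probs < 0 | cfg$switch_probs > 1)) {
    stop("switch_probs must be in [0,1]", call. = FALSE)
  }
  invisible(cfg)
}

#' Load a pipeline configuration file
#'
#' Reads a YAML configuration (see `inst/extdata/default_config.yaml` for the
#' documented defaults) and merges it over the package defaults. Only keys
#' present in the file are overridden.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return a `sim_config` plus pipeline-level options (`out_dir`,
#'   `forced_k`, `k_range`, `stepwise`).
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  sim_keys <- intersect(
    names(user),
    c("n_subjects", "seed", "T_months", "class_weights", "noise_sd",
      "distractor_rates", "switch_probs", "mode")
  )
  args <- user[sim_keys]
  if (!is.null(args$class_weights)) args$class_weights <- unlist(args$class_weights)
  if (!is.null(args$distractor_rates)) args$distractor_rates <- unlist(args$distractor_rates)
  if (!is.null(args$switch_probs)) args$switch_probs <- unlist(args$switch_probs)
  cfg <- do.call(sim_config, args)
  opts <- list(
    forced_k = user$forced_k,
    k_range = if (is.null(user$k_range)) 2:10 else user$k_range[1]:user$k_range[2],
    stepwise = isTRUE(user$stepwise),
    simulate = if (is.null(user$simulate)) TRUE else isTRUE(user$simulate),
    input_dir = user$input_dir
  )
  list(sim = cfg, options = opts)
}
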