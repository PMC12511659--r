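# Cohort builder: inclusion cascade, indication, index attributes,
# covariate windows, attrition bookkeeping.

test_that("each cascade step excludes its hand-built violator", {
  # five patients, one violating each of steps 2-6, processed together
  reg <- rbind(
    reg_row("A", "2014-01-01", "2022-12-31"),  # ustekinumab too early
    reg_row("B", "2015-06-01", "2022-12-31"),  # short look-back
    reg_row("C", "2009-01-01", "2022-12-31"),  # washout violation
    reg_row("D", "2013-01-01", "2016-06-01"),  # short follow-up
    reg_row("E", "2012-01-01", "2022-12-31")   # no IBD indication
  )
  disp <- rbind(
    disp_row("A", "2016-05-01", atc = "L04AC05", substance = "ustekinumab"),
    disp_row("B", "2015-09-01"),
    disp_row("C", "2010-03-01"),
    disp_row("C", "2009-11-15"),               # pre-window, inside washout
    disp_row("D", "2014-01-01"),
    disp_row("E", "2014-01-01")
  )
  ev <- rbind(
    event_row("A", "2015-01-01", "555.1"),
    event_row("B", "2015-07-01", "555.1"),
    event_row("C", "2009-06-01", "556.9"),
    event_row("D", "2013-06-01", "555.0"),
    event_row("E", "2013-06-01", "401.9")      # hypertension only
  )
  res <- identify_new_users(reg, disp, ev, default_rules(36))
  expect_equal(nrow(res$cohort), 0L)
  expect_equal(res$attrition$n_excluded, c(0L, 1L, 1L, 1L, 1L, 1L))
  expect_equal(res$attrition$n_entering,
               c(5L, 5L, 4L, 3L, 2L, 1L))
  expect_equal(res$attrition$n_retained,
               res$attrition$n_entering - res$attrition$n_excluded)
})

test_that("a fully eligible patient survives the cascade with attributes", {
  reg <- reg_row("P", "2011-01-01", "2020-12-31", birth = "1950-02-01",
                 sex = "F")
  disp <- rbind(disp_row("P", "2014-05-10", atc = "L04AB02",
                         substance = "infliximab", type = "biosimilar",
                         route = "IV"),
                disp_row("P", "2014-06-10", atc = "L04AB02",
                         substance = "infliximab", type = "biosimilar",
                         route = "IV"))
  ev <- event_row("P", "2013-01-01", "556.9")
  res <- identify_new_users(reg, disp, ev, default_rules(36))
  expect_equal(nrow(res$cohort), 1L)
  co <- res$cohort
  expect_equal(co$index_date, as.Date("2014-05-10"))
  expect_equal(co$index_substance, "infliximab")
  expect_equal(co$index_type, "biosimilar")
  expect_equal(co$index_route, "IV")
  expect_equal(co$index_class, "TNF-alpha inhibitor")
  expect_equal(co$indication, "UC")
  expect_equal(co$age_band, "45-64")
})

test_that("prevalent users are excluded at the washout step", {
  reg <- reg_row("P", "2008-01-01", "2022-12-31")
  # first in-window dispensing 2011-03-01; prior eligible one 200 days
  # before (in-window as well, so it becomes the index -> washout clean);
  # make the earlier one pre-window instead
  disp <- rbind(disp_row("P", "2010-06-01"),
                disp_row("P", "2009-11-20"))
  ev <- event_row("P", "2009-06-01", "555.1")
  res <- identify_new_users(reg, disp, ev, default_rules(36))
  expect_equal(nrow(res$cohort), 0L)
  expect_equal(res$attrition[step == "no biologic in washout before index (new user)",
                             n_excluded], 1L)
})

test_that("empty dispensing table yields an empty cohort with attrition", {
  reg <- reg_row("P", "2011-01-01", "2020-12-31")
  res <- identify_new_users(reg, disp_row("X", "2014-01-01")[0],
                            event_row("X", "2014-01-01", "555.1")[0],
                            default_rules())
  expect_equal(nrow(res$cohort), 0L)
  expect_equal(res$attrition$n_entering[1], 1L)
  expect_true(all(res$attrition$n_retained == 0L))
})

test_that("duplicate registry rows are rejected", {
  reg <- rbind(reg_row("P", "2011-01-01", "2020-12-31"),
               reg_row("P", "2012-01-01", "2021-12-31"))
  expect_error(
    identify_new_users(reg, disp_row("P", "2014-01-01"),
                       event_row("P", "2013-01-01", "555.1"),
                       default_rules()),
    "duplicate"
  )
})

test_that("indication follows code lists with most-recent tie-breaking", {
  idx <- as.Date("2015-01-01")
  expect_equal(determine_indication(event_row("P", "2014-01-01", "555.1"),
                                    idx), "CD")
  # most recent event wins
  ev <- rbind(event_row("P", "2013-11-01", "556.9"),
              event_row("P", "2014-12-22", "555.0"))
  expect_equal(determine_indication(ev, idx), "CD")
  ev2 <- rbind(event_row("P", "2013-11-01", "555.0"),
               event_row("P", "2014-12-22", "556.9"))
  expect_equal(determine_indication(ev2, idx), "UC")
  # same-day tie resolves to CD
  ev3 <- rbind(event_row("P", "2014-12-22", "555.0"),
               event_row("P", "2014-12-22", "556.9"))
  expect_equal(determine_indication(ev3, idx), "CD")
  # no IBD codes, or events only after index
  expect_equal(determine_indication(event_row("P", "2014-01-01", "401.9"),
                                    idx), "other")
  expect_equal(determine_indication(event_row("P", "2015-06-01", "555.1"),
                                    idx), "other")
  # exemption codes count
  expect_equal(determine_indication(
    event_row("P", "2014-01-01", "009.555", system = "EXEMPTION"), idx), "CD")
})

test_that("index attributes come from the drug catalog", {
  at <- index_attributes(data.table::data.table(
    atc_code = c("L04AB02", "L04AC05", "L04AA33"),
    product_type = c("biosimilar", "originator", "originator")
  ))
  expect_equal(at$substance, c("infliximab", "ustekinumab", "vedolizumab"))
  expect_equal(at$index_class,
               c("TNF-alpha inhibitor", "anti-interleukin",
                 "selective immunosuppressant"))
  expect_equal(at$route, c("IV", "SC", "IV"))
  expect_error(index_attributes(data.table::data.table(
    atc_code = "L04AX99", product_type = "originator")), "L04AX99")
})

test_that("covariate windows follow the stated boundary conventions", {
  cohort <- data.table::data.table(patient_id = "P",
                                   index_date = as.Date("2015-01-01"))
  ev <- rbind(
    event_row("P", "2006-10-15", "401.9"),   # ever-before: counts
    event_row("P", "2015-01-01", "250.00")   # on index day: does not
  )
  disp <- rbind(
    disp_row("P", "2013-11-01", atc = "H02AB06", substance = "gc",
             type = "not_applicable", route = "other"),  # > 1y: no
    disp_row("P", "2014-06-01", atc = "M01AE01", substance = "nsaid",
             type = "not_applicable", route = "other"),  # in window: yes
    disp_row("P", "2015-01-01", atc = "B01AA03", substance = "ac",
             type = "not_applicable", route = "other")   # index day: no
  )
  cv <- build_covariates(cohort, ev, disp)
  expect_true(cv$como_hypertension)
  expect_false(cv$como_diabetes)
  expect_false(cv$drug_glucocorticoids)
  expect_true(cv$drug_nsaids)
  expect_false(cv$drug_anticoagulants)
})

test_that("attrition is conserved and idempotent on simulated data", {
  sim <- small_sim()
  rules <- sim$config$rules
  res <- identify_new_users(sim$registry, sim$dispensings, sim$events, rules)
  at <- res$attrition
  expect_equal(at$n_retained, at$n_entering - at$n_excluded)
  expect_equal(at$n_entering[-1], at$n_retained[-nrow(at)])
  # re-running on the retained subjects reproduces the same cohort
  keep <- res$cohort$patient_id
  res2 <- identify_new_users(
    sim$registry[patient_id %in% keep],
    sim$dispensings[patient_id %in% keep],
    sim$events[patient_id %in% keep], rules)
  expect_equal(data.table::setorder(res2$cohort, patient_id),
               data.table::setorder(data.table::copy(res$cohort), patient_id))
})

test_that("every synthetic distractor is excluded at its labelled step", {
  cfg <- sim_config(n_subjects = 2000, seed = 77,
                    distractor_rates = c(washout = 0.05, lookback = 0.05,
                                         followup = 0.05, non_ibd = 0.05))
  sim <- simulate_population(cfg)
  res <- identify_new_users(sim$registry, sim$dispensings, sim$events,
                            cfg$rules)
  lab <- sim$true_labels
  retained <- res$cohort$patient_id
  # no distractor is retained; every clean subject is
  expect_true(all(lab[distractor != "none", patient_id] %in%
                    setdiff(lab$patient_id, retained)))
  expect_true(all(lab[distractor == "none", patient_id] %in% retained))
  # each distractor fails exactly its labelled rule (and so is excluded
  # there and nowhere earlier, given the fixed cascade order)
  step_of <- c(lookback = "sufficient look-back before index",
               washout = "no biologic in washout before index (new user)",
               followup = "registry coverage through follow-up",
               non_ibd = "IBD indication (CD or UC)")
  rules <- cfg$rules
  idx <- sim$dispensings[atc_code %in% rules$biologic_atc &
                           dispense_date >= rules$study_start &
                           dispense_date <= rules$study_end,
                         .(index_date = min(dispense_date)), by = patient_id]
  chk <- merge(merge(lab[, .(patient_id, distractor)], idx,
                     by = "patient_id"),
               sim$registry, by = "patient_id")
  viol <- function(p, rule) {
    r <- chk[patient_id == p]
    switch(rule,
      lookback = as.integer(r$index_date - r$registry_entry) < 365,
      washout = nrow(sim$dispensings[
        patient_id == p & atc_code %in% rules$biologic_atc &
          dispense_date < r$index_date &
          dispense_date >= r$index_date - 365]) > 0,
      followup = r$registry_exit < adheretraj:::add_months(r$index_date, 36),
      non_ibd = determine_indication(sim$events[patient_id == p],
                                     r$index_date) == "other")
  }
  set.seed(5)
  rules_all <- c("lookback", "washout", "followup", "non_ibd")
  sampled <- lab[distractor != "none"][sample(.N, min(.N, 60))]
  for (i in seq_len(nrow(sampled))) {
    p <- sampled$patient_id[i]
    d <- sampled$distractor[i]
    expect_true(viol(p, d), label = paste(p, "violates", d))
    for (other in setdiff(rules_all, d)) {
      expect_false(viol(p, other),
                   label = paste(p, "does not violate", other))
    }
  }
})
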