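# Synthetic claims generator: calibration, archetypes, emission round trips,
# determinism, and distractor construction.

test_that("intercept calibration reproduces closed forms", {
  # no covariate effects, symmetric mixture
  ic <- calibrate_intercepts(list(), default_covariate_marginals(),
                             c(1, 1, 1) / 3)
  expect_equal(as.numeric(ic), c(0, 0), tolerance = 1e-8)
  # no covariate effects, general mixture: log-share ratios vs reference
  w <- c(high = 0.2, medium = 0.5, low = 0.3)
  ic2 <- calibrate_intercepts(list(), default_covariate_marginals(), w)
  expect_equal(as.numeric(ic2), c(log(0.5 / 0.2), log(0.3 / 0.2)),
               tolerance = 1e-6)
  # with the default coefficient set, expected shares hit the target
  ic3 <- calibrate_intercepts(default_dgp_coefficients(),
                              default_covariate_marginals(),
                              c(0.19, 0.46, 0.35))
  expect_lt(max(abs(attr(ic3, "residual"))), 1e-4)
  expect_error(
    calibrate_intercepts(list(sex = list(F = c(medium = Inf, low = 0))),
                         default_covariate_marginals(), c(0.19, 0.46, 0.35)),
    "finite"
  )
})

test_that("simulated class shares match the target mixture", {
  cfg <- sim_config(n_subjects = 10000, seed = 1)
  sub <- simulate_subjects(cfg)
  shares <- prop.table(table(factor(sub$true_class,
                                    c("high", "medium", "low"))))
  expect_lt(max(abs(shares - c(0.19, 0.46, 0.35))), 0.02)
})

test_that("degenerate mixture assigns every subject to the single class", {
  cfg <- sim_config(n_subjects = 50, seed = 3,
                    class_weights = c(high = 1, medium = 0, low = 0))
  sim <- simulate_population(cfg)
  expect_true(all(sim$true_labels$true_class == "high"))
})

test_that("simulation is deterministic given the seed", {
  a <- simulate_population(sim_config(n_subjects = 120, seed = 9))
  b <- simulate_population(sim_config(n_subjects = 120, seed = 9))
  expect_identical(a$registry, b$registry)
  expect_identical(a$dispensings, b$dispensings)
  expect_identical(a$events, b$events)
  expect_identical(a$true_labels, b$true_labels)
  c2 <- simulate_population(sim_config(n_subjects = 120, seed = 10))
  expect_false(identical(a$dispensings, c2$dispensings))
})

test_that("DGP odds ratios are recoverable from true labels", {
  cfg <- sim_config(n_subjects = 100000, seed = 2)
  sub <- simulate_subjects(cfg)
  tab <- table(sub$sex, sub$true_class)
  emp_or <- (tab["F", "low"] / tab["F", "high"]) /
    (tab["M", "low"] / tab["M", "high"])
  expect_lt(abs(emp_or - 1.52), 0.1)
  shares <- prop.table(table(factor(sub$true_class,
                                    c("high", "medium", "low"))))
  expect_lt(max(abs(shares - c(0.19, 0.46, 0.35))), 0.01)
})

test_that("class archetypes follow the three described shapes", {
  expect_equal(class_archetype("high", c(1, 18, 36)), rep(0.95, 3))
  expect_equal(class_archetype("medium", 9:36), rep(0.70, 28))
  expect_equal(class_archetype("medium", 1), 0.95)
  expect_equal(class_archetype("low", 36, T_months = 36), 0.20)
  expect_equal(class_archetype("low", 1, T_months = 36), 0.90)
  expect_error(class_archetype("none", 1), "unknown class")
})

test_that("exact-mode emission round-trips through monthly PDC", {
  idx <- as.Date("2014-03-15")
  plan <- list(substance = "adalimumab", atc_code = "L04AB04",
               product_type = "originator", route = "SC")
  # saturated target reproduces exactly
  d <- emit_dispensings(rep(1, 3), idx, plan, mode = "exact", seed = 1)
  d[, patient_id := "P1"]
  iv <- coverage_intervals(d, data.table::data.table(
    patient_id = "P1", index_date = idx), T_months = 3)
  ser <- monthly_pdc(iv, data.table::data.table(
    patient_id = "P1", index_date = idx), T_months = 3)
  expect_equal(ser$pdc, rep(1, 3))
  # a mixed target is realized within one day per window
  tgt <- c(1, 0.5, 0)
  d2 <- emit_dispensings(tgt, idx, plan, mode = "exact", seed = 1)
  d2[, patient_id := "P1"]
  iv2 <- coverage_intervals(d2, data.table::data.table(
    patient_id = "P1", index_date = idx), T_months = 3)
  ser2 <- monthly_pdc(iv2, data.table::data.table(
    patient_id = "P1", index_date = idx), T_months = 3)
  expect_lt(max(abs(ser2$pdc - tgt)), 1 / 28)
  # duplicating every record leaves the realized PDC unchanged
  ser3 <- monthly_pdc(coverage_intervals(rbind(d2, d2),
    data.table::data.table(patient_id = "P1", index_date = idx), 3),
    data.table::data.table(patient_id = "P1", index_date = idx), 3)
  expect_equal(ser3$pdc, ser2$pdc)
  expect_error(
    emit_dispensings(rep(0, 3), idx, plan, mode = "exact"),
    "index dispensing"
  )
})

test_that("exact-mode round trip holds for random curves (property)", {
  set.seed(7)
  plan <- list(substance = "infliximab", atc_code = "L04AB02",
               product_type = "originator", route = "IV")
  for (i in 1:25) {
    tgt <- runif(12)
    idx <- as.Date("2012-01-01") + sample(0:2500, 1)
    d <- emit_dispensings(tgt, idx, plan, mode = "exact", seed = i)
    d[, patient_id := "X"]
    who <- data.table::data.table(patient_id = "X", index_date = idx)
    ser <- monthly_pdc(coverage_intervals(d, who, 12), who, 12)
    dev <- abs(ser$pdc - tgt)
    dev[1] <- min(dev[1], abs(ser$pdc[1] - max(tgt[1], 1 / 31)))
    expect_lt(max(dev), 1 / 28)
  }
})

test_that("noisy-mode emission approximates the target on average", {
  plan <- list(substance = "adalimumab", atc_code = "L04AB04",
               product_type = "originator", route = "SC")
  idx <- as.Date("2015-06-01")
  tgt <- rep(0.8, 24)
  d <- emit_dispensings(tgt, idx, plan, mode = "noisy", seed = 4)
  d[, patient_id := "P1"]
  who <- data.table::data.table(patient_id = "P1", index_date = idx)
  ser <- monthly_pdc(coverage_intervals(d, who, 24), who, 24)
  expect_lt(abs(mean(ser$pdc) - 0.8), 0.12)
})

test_that("switch plans change the post-switch records", {
  plan <- list(substance = "adalimumab", atc_code = "L04AB04",
               product_type = "originator", route = "SC",
               switch_day = 200L, switch_substance = "vedolizumab",
               switch_atc = "L04AA33", switch_product_type = "originator",
               switch_route = "IV")
  d <- emit_dispensings(rep(0.9, 12), as.Date("2013-02-01"), plan,
                        mode = "exact", seed = 2)
  off <- as.integer(d$dispense_date - as.Date("2013-02-01"))
  expect_true(all(d$substance[off < 200] == "adalimumab"))
  expect_true(all(d$substance[off >= 200] == "vedolizumab"))
})

test_that("subject target curves stay in [0,1] and average to the archetypes", {
  set.seed(11)
  cls <- rep(c("high", "medium", "low"), each = 800)
  cur <- subject_curves(cls, 36)
  expect_true(all(cur >= 0 & cur <= 1))
  for (cl in c("high", "medium", "low")) {
    dev <- colMeans(cur[cls == cl, ]) - class_archetype(cl, 1:36, 36)
    expect_lt(max(abs(dev)), 0.05)
  }
})

test_that("config validation rejects invalid settings", {
  expect_error(sim_config(n_subjects = 5), "at least 10")
  expect_error(sim_config(T_months = 2), "at least 3")
  expect_error(sim_config(class_weights = c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(sim_config(noise_sd = -1), "non-negative")
  expect_error(sim_config(distractor_rates = c(washout = 0.5, lookback = 0.5,
                                               followup = 0.3, non_ibd = 0)),
               "sum to < 1")
})

test_that("written CSV files round-trip the tables", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_claims(sim, dir)
  reg <- data.table::fread(file.path(dir, "registry.csv"))
  expect_equal(nrow(reg), nrow(sim$registry))
  expect_equal(names(reg), names(sim$registry))
  expect_equal(as.Date(reg$registry_entry), sim$registry$registry_entry)
})
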