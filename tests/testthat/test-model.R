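# Multinomial determinants model: reduction oracle, Wald intervals,
# invariances, stepwise behaviour.

sim_mnl <- function(n, seed, beta_a = 0.8, beta_low = -0.6) {
  set.seed(seed)
  x <- data.frame(a = rnorm(n), g = factor(sample(c("u", "v"), n, TRUE)))
  eta_med <- 0.3 + beta_a * x$a + 0.5 * (x$g == "v")
  eta_low <- -0.2 + beta_low * x$a
  p <- cbind(1, exp(eta_med), exp(eta_low))
  p <- p / rowSums(p)
  y <- apply(p, 1, function(pr) sample(c("high", "medium", "low"), 1,
                                       prob = pr))
  list(x = x, y = y)
}

test_that("two-level outcomes reduce to binary logistic regression", {
  set.seed(10)
  n <- 500
  x <- data.frame(a = rnorm(n), b = runif(n))
  y <- ifelse(runif(n) < plogis(-0.3 + x$a - 2 * x$b), "case", "ctrl")
  fit <- fit_multinomial(y, x, reference = "ctrl")
  oracle <- glm(I(y == "case") ~ a + b, data = x, family = binomial,
                control = glm.control(epsilon = 1e-12))
  expect_lt(max(abs(fit$coefficients[1, ] - coef(oracle))), 1e-6)
  expect_lt(max(abs(fit$standard_errors[1, ] -
                      summary(oracle)$coefficients[, 2])), 1e-6)
  expect_equal(fit$aic, AIC(oracle), tolerance = 1e-8)
  expect_equal(fit$log_likelihood, as.numeric(logLik(oracle)),
               tolerance = 1e-8)
})

test_that("three-level fits agree with nnet::multinom", {
  skip_if_not_installed("nnet")
  d <- sim_mnl(800, 3)
  fit <- fit_multinomial(d$y, d$x, reference = "high")
  nf <- nnet::multinom(factor(d$y, c("high", "medium", "low")) ~ a + g,
                       data = d$x, trace = FALSE, reltol = 1e-14,
                       maxit = 500)
  expect_lt(max(abs(fit$coefficients[c("medium-vs-high", "low-vs-high"), ] -
                      coef(nf))), 1e-5)
  expect_equal(fit$aic, AIC(nf), tolerance = 1e-6)
})

test_that("a saturated fit reproduces observed cell proportions", {
  # 2 x 3 table: one binary covariate, three outcomes
  x <- data.frame(g = factor(rep(c("u", "v"), c(60, 40))))
  y <- c(rep(c("high", "medium", "low"), c(30, 20, 10)),
         rep(c("high", "medium", "low"), c(10, 10, 20)))
  fit <- fit_multinomial(y, x, reference = "high")
  b <- fit$coefficients
  # P(medium | u) = 20/30 * P(high | u) etc: check via the log-odds
  expect_equal(unname(b["medium-vs-high", "(Intercept)"]), log(20 / 30),
               tolerance = 1e-6)
  expect_equal(unname(b["low-vs-high", "(Intercept)"]), log(10 / 30),
               tolerance = 1e-6)
  expect_equal(unname(b["low-vs-high", "gv"]), log(20 / 10) - log(10 / 30),
               tolerance = 1e-6)
})

test_that("relabelling non-reference outcomes permutes contrast rows", {
  d <- sim_mnl(600, 4)
  fit <- fit_multinomial(d$y, d$x, reference = "high")
  y_swap <- d$y
  fit2 <- fit_multinomial(factor(y_swap, c("high", "low", "medium")), d$x,
                          reference = "high")
  expect_equal(fit$coefficients["medium-vs-high", ],
               fit2$coefficients["medium-vs-high", ], tolerance = 1e-8)
  expect_equal(fit$coefficients["low-vs-high", ],
               fit2$coefficients["low-vs-high", ], tolerance = 1e-8)
  expect_equal(fit$log_likelihood, fit2$log_likelihood, tolerance = 1e-10)
})

test_that("AIC identity holds and separation is flagged", {
  d <- sim_mnl(400, 5)
  fit <- fit_multinomial(d$y, d$x, reference = "high")
  npar <- length(fit$coefficients)
  expect_equal(fit$aic, -2 * fit$log_likelihood + 2 * npar)
  # perfect separation triggers a warning
  xs <- data.frame(z = c(rep(0, 30), rep(1, 30)))
  ys <- rep(c("a", "b"), each = 30)
  expect_warning(fit_multinomial(ys, xs, reference = "a"), "separation")
})

test_that("Wald intervals cover the null at the nominal rate", {
  set.seed(20)
  hits <- 0L
  reps <- 120L
  for (i in seq_len(reps)) {
    n <- 400
    x <- data.frame(a = rnorm(n))
    y <- sample(c("high", "medium", "low"), n, TRUE, prob = c(0.4, 0.35, 0.25))
    fit <- fit_multinomial(y, x, reference = "high")
    or <- or_table(fit)
    row <- or[term == "a" & contrast == "low-vs-high"]
    hits <- hits + (row$ci_low <= 1 && row$ci_high >= 1)
  }
  expect_gt(hits / reps, 0.90)
  expect_lt(hits / reps, 0.995)
})

test_that("odds-ratio tables exponentiate coefficients with 1.96 SE bands", {
  d <- sim_mnl(500, 6)
  fit <- fit_multinomial(d$y, d$x, reference = "high")
  tab <- or_table(fit)
  expect_true(all(tab$ci_low <= tab$odds_ratio &
                    tab$odds_ratio <= tab$ci_high))
  expect_false("(Intercept)" %in% tab$term)
  b <- fit$coefficients["medium-vs-high", "a"]
  s <- fit$standard_errors["medium-vs-high", "a"]
  row <- tab[term == "a" & contrast == "medium-vs-high"]
  expect_equal(row$odds_ratio, exp(b))
  expect_equal(row$ci_low, exp(b - 1.96 * s))
  expect_equal(row$ci_high, exp(b + 1.96 * s))
  # closed form: coefficient 0, SE 0.1 -> OR 1.00, CI (0.82, 1.22)
  expect_equal(round(exp(c(-1.96, 1.96) * 0.1), 2), c(0.82, 1.22))
  fake <- fit
  fake$converged <- FALSE
  expect_error(or_table(fake), "converge")
})

test_that("stepwise AIC keeps strong effects and usually drops pure noise", {
  # a strong covariate is always selected
  for (s in 1:3) {
    d <- sim_mnl(1500, 100 + s, beta_a = 1.2)
    d$x$noise1 <- rnorm(1500)
    sw <- stepwise_aic(d$y, d$x, reference = "high")
    expect_true("a" %in% sw$selected)
  }
  # with pure-noise candidates the intercept-only model usually wins
  set.seed(7)
  kept <- 0L
  for (s in 1:8) {
    n <- 1500
    y <- sample(c("high", "medium", "low"), n, TRUE, prob = c(0.3, 0.4, 0.3))
    x <- data.frame(n1 = rnorm(n), n2 = rnorm(n),
                    n3 = factor(sample(c("p", "q"), n, TRUE)))
    sw <- stepwise_aic(y, x, reference = "high")
    kept <- kept + length(sw$selected)
  }
  expect_lt(kept, 6L)  # AIC's known false-inclusion rate allows a few
  # empty candidate set returns the intercept-only model
  y <- sample(c("a", "b"), 60, TRUE)
  sw0 <- stepwise_aic(y, data.frame(row.names = 1:60), reference = "a")
  expect_length(sw0$selected, 0L)
  expect_equal(sw0$path$action[1], "start")
})

test_that("the stepwise path records visited AIC values in order", {
  d <- sim_mnl(800, 8, beta_a = 1.0)
  sw <- stepwise_aic(d$y, d$x, reference = "high")
  expect_true(all(diff(sw$path$aic) < 0))
  expect_equal(sw$fit$aic, sw$path$aic[nrow(sw$path)])
})

test_that("ORs estimated on the generator's own cohorts recover the DGP", {
  cfg <- sim_config(n_subjects = 20000, seed = 31)
  sub <- simulate_subjects(cfg)
  covs <- data.frame(
    sex = factor(sub$sex, c("M", "F")),
    age_band = factor(sub$age_band,
                      c("18-44", "<18", "45-64", "65-79", ">=80")),
    index_drug = factor(sub$index_drug,
                        c("adalimumab", "golimumab", "infliximab",
                          "ustekinumab", "vedolizumab")),
    index_type = factor(sub$index_type, c("originator", "biosimilar")),
    indication = factor(sub$indication, c("UC", "CD")),
    region = factor(sub$region)
  )
  fit <- fit_multinomial(sub$true_class, covs, reference = "high")
  or <- or_table(fit)
  expect_lt(abs(or[term == "sexF" & contrast == "low-vs-high",
                   odds_ratio] - 1.52), 0.15)
  expect_lt(abs(or[term == "index_typebiosimilar" & contrast == "low-vs-high",
                   odds_ratio] - 0.47), 0.05)
  expect_lt(abs(or[term == "indicationCD" & contrast == "medium-vs-high",
                   odds_ratio] - 1.35), 0.15)
  # Wald intervals have plausible width at this n
  row <- or[term == "sexF" & contrast == "low-vs-high"]
  expect_lt(row$ci_high / row$ci_low, 1.5)
})
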