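# Shared helpers: independent oracles and small hand-built fixtures.

# Adjusted Rand index between two partitions (independent of any package
# clustering code).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Brute-force recomputation of the 24 change measures for one series,
# written straight from the definitions with base-R fits (kept independent
# of the package's vectorized implementation).
brute_measures <- function(y, den = NULL) {
  T_len <- length(y)
  d <- y[-1] - y[-T_len]
  s <- d[-1] - d[-length(d)]
  fit <- stats::lm(y ~ seq_len(T_len))
  slope <- unname(stats::coef(fit)[2])
  r2 <- if (stats::var(y) > 0) {
    suppressWarnings(summary(fit)$r.squared)  # exact fits trip lm's summary
  } else 0
  # denominators with the package's documented zero-substitution applied
  # externally through `den` (list m2, y1, m9, m14); identity when NULL
  m2 <- mean(y); y1 <- y[1]; m14 <- mean(abs(d))
  dn <- list(m2 = m2, y1 = y1, m9 = slope, m14 = m14)
  if (!is.null(den)) dn <- den
  rat <- function(num, dd) if (dd == 0) 0 else num / dd
  c(
    m1 = max(y) - min(y), m2 = m2, m3 = stats::sd(y),
    m4 = rat(100 * stats::sd(y), dn$m2),
    m5 = y[T_len] - y[1], m6 = (y[T_len] - y[1]) / (T_len - 1),
    m7 = rat(y[T_len] - y[1], dn$y1), m8 = rat(y[T_len] - y[1], dn$m2),
    m9 = slope, m10 = r2,
    m11 = max(d), m12 = stats::sd(d), m13 = stats::sd(d),
    m14 = m14, m15 = max(abs(d)),
    m16 = rat(max(abs(d)), dn$m2), m17 = rat(max(abs(d)), dn$m9),
    m18 = rat(stats::sd(d), dn$m9),
    m19 = mean(s), m20 = mean(abs(s)), m21 = max(abs(s)),
    m22 = rat(max(abs(s)), dn$m2), m23 = rat(max(abs(s)), dn$m14),
    m24 = rat(mean(abs(s)), dn$m14)
  )
}

# Brute-force 24-measure matrix for a cohort, including the cohort-level
# zero-denominator substitution the package documents.
brute_measures_matrix <- function(m) {
  n <- nrow(m)
  raw_den <- t(apply(m, 1, function(y) {
    d <- diff(y)
    fit <- stats::lm(y ~ seq_along(y))
    c(m2 = mean(y), y1 = y[1], m9 = unname(stats::coef(fit)[2]),
      m14 = mean(abs(d)))
  }))
  sub <- apply(raw_den, 2, function(x) {
    nz <- abs(x) > 0
    if (!any(nz)) return(rep(0, length(x)))
    x[!nz] <- min(abs(x[nz]))
    x
  })
  if (n == 1) sub <- matrix(sub, 1, dimnames = list(NULL, colnames(raw_den)))
  out <- t(vapply(seq_len(n), function(i) {
    brute_measures(m[i, ], den = as.list(sub[i, ]))
  }, numeric(24)))
  out
}

# A small synthetic claims database shared by several test files.
small_sim <- local({
  memo <- NULL
  function(n = 600, seed = 42) {
    if (is.null(memo)) {
      memo <<- simulate_population(sim_config(n_subjects = n, seed = seed))
    }
    memo
  }
})

# A registry row builder for hand-built cohort fixtures.
reg_row <- function(id, entry, exit, birth = "1980-06-15", sex = "M",
                    region = "Tuscany") {
  data.table::data.table(
    patient_id = id, sex = sex, birth_date = as.Date(birth),
    region = region, registry_entry = as.Date(entry),
    registry_exit = as.Date(exit)
  )
}

disp_row <- function(id, date, atc = "L04AB04", substance = "adalimumab",
                     type = "originator", q = 30, route = "SC") {
  data.table::data.table(
    patient_id = id, dispense_date = as.Date(date), atc_code = atc,
    substance = substance, product_type = type, quantity_ddd = q,
    route = route
  )
}

event_row <- function(id, date, code, system = "ICD9CM") {
  data.table::data.table(
    patient_id = id, event_date = as.Date(date), code_system = system,
    code = code
  )
}
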