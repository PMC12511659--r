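# The 24 longitudinal measures of change summarizing each adherence series.
#
# Four families: basic descriptives of the scores; elementary change
# (last-minus-first and relatives); nonlinearity/inconsistency of change
# (first differences d_t = y_{t+1} - y_t); and nonmonotonicity (second
# differences s_t = d_{t+1} - d_t). Ratio measures with a zero denominator
# are made finite by substituting the smallest nonzero absolute value of
# that denominator observed across the cohort (if the denominator is zero
# for everyone, the ratio is set to 0).

MEASURE_NAMES <- paste0("m", 1:24)

# Raw measures for one series; ratio measures returned as numerator and
# denominator so cohort-level zero handling can be applied afterwards.
#' @keywords internal
measures_raw <- function(y) {
  T_len <- length(y)
  t_idx <- seq_len(T_len)
  d <- diff(y)
  s <- diff(d)
  m2 <- mean(y)
  m3 <- stats::sd(y)
  m5 <- y[T_len] - y[1]
  # OLS of y on t: slope and R^2
  tc <- t_idx - mean(t_idx)
  sxx <- sum(tc^2)
  m9 <- sum(tc * (y - m2)) / sxx
  sst <- sum((y - m2)^2)
  m10 <- if (sst > 0) (m9^2 * sxx) / sst else 0
  m12 <- stats::sd(d)
  m14 <- mean(abs(d))
  m15 <- max(abs(d))
  m20 <- mean(abs(s))
  m21 <- max(abs(s))
  list(
    values = c(
      m1 = max(y) - min(y), m2 = m2, m3 = m3, m4 = NA, m5 = m5,
      m6 = m5 / (T_len - 1), m7 = NA, m8 = NA, m9 = m9, m10 = m10,
      m11 = max(d), m12 = m12, m13 = m12, m14 = m14, m15 = m15,
      m16 = NA, m17 = NA, m18 = NA, m19 = mean(s), m20 = m20,
      m21 = m21, m22 = NA, m23 = NA, m24 = NA
    ),
    denoms = c(m2 = m2, y1 = y[1], m9 = m9, m14 = m14),
    numers = c(m4 = 100 * m3, m7 = m5, m8 = m5, m16 = m15, m17 = m15,
               m18 = m12, m22 = m21, m23 = m21, m24 = m20)
  )
}

#' Compute the 24 change measures for adherence series
#'
#' @param series either a long series table from [monthly_pdc()] or a
#'   numeric matrix (rows = patients, columns = months).
#' @return data.table with `patient_id` and columns `m1`..`m24`:
#'   m1 range; m2 mean; m3 SD (denominator T-1); m4 coefficient of
#'   variation (100 m3/m2); m5 last minus first; m6 m5/(T-1); m7 m5/y1;
#'   m8 m5/m2; m9 OLS slope of y on time; m10 R^2 of that fit; m11 max
#'   first difference; m12 SD of first differences; m13 SD of first
#'   differences per unit time (= m12 at monthly spacing); m14 mean
#'   absolute first difference; m15 max absolute first difference;
#'   m16 m15/m2; m17 m15/m9; m18 m12/m9; m19 mean second difference;
#'   m20 mean absolute second difference; m21 max absolute second
#'   difference; m22 m21/m2; m23 m21/m14; m24 m20/m14.
#' @export
compute_measures <- function(series) {
  m <- if (is.matrix(series)) series else pdc_matrix(series)
  if (ncol(m) < 3L) {
    stop("change measures need at least 3 consecutive adherence values",
         call. = FALSE)
  }
  if (any(!is.finite(m))) {
    stop("series contain non-finite values", call. = FALSE)
  }
  n <- nrow(m)
  raw <- apply(m, 1L, measures_raw)
  vals <- t(vapply(raw, `[[`, numeric(24), "values"))
  dens <- t(vapply(raw, `[[`, numeric(4), "denoms"))
  nums <- t(vapply(raw, `[[`, numeric(9), "numers"))
  colnames(dens) <- c("m2", "y1", "m9", "m14")
  colnames(nums) <- c("m4", "m7", "m8", "m16", "m17", "m18", "m22", "m23", "m24")

  # Cohort-level zero-denominator substitution.
  sub_den <- function(x) {
    nz <- abs(x) > 0
    if (!any(nz)) return(rep(0, length(x)))  # signal: all-zero denominator
    x[!nz] <- min(abs(x[nz]))
    x
  }
  den_sub <- apply(dens, 2L, sub_den)
  if (n == 1L) den_sub <- matrix(den_sub, 1L, dimnames = list(NULL, colnames(dens)))
  ratio <- function(num, den) ifelse(den == 0, 0, num / den)
  vals[, "m4"] <- ratio(nums[, "m4"], den_sub[, "m2"])
  vals[, "m7"] <- ratio(nums[, "m7"], den_sub[, "y1"])
  vals[, "m8"] <- ratio(nums[, "m8"], den_sub[, "m2"])
  vals[, "m16"] <- ratio(nums[, "m16"], den_sub[, "m2"])
  vals[, "m17"] <- ratio(nums[, "m17"], den_sub[, "m9"])
  vals[, "m18"] <- ratio(nums[, "m18"], den_sub[, "m9"])
  vals[, "m22"] <- ratio(nums[, "m22"], den_sub[, "m2"])
  vals[, "m23"] <- ratio(nums[, "m23"], den_sub[, "m14"])
  vals[, "m24"] <- ratio(nums[, "m24"], den_sub[, "m14"])
  stopifnot(all(is.finite(vals)))
  out <- data.table::data.table(
    patient_id = if (!is.null(rownames(m))) rownames(m) else as.character(seq_len(n))
  )
  out <- cbind(out, data.table::as.data.table(vals))
  data.table::setnames(out, c("patient_id", MEASURE_NAMES))
  out[]
}
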