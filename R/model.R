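# Multinomial logistic regression of trajectory-group membership, with
# Wald intervals and bidirectional stepwise AIC selection.

#' Fit a multinomial logistic model by Newton-Raphson
#'
#' Maximum-likelihood multinomial logit against a reference outcome level,
#' fitted by Newton iteration on the full log-likelihood with step-halving.
#' Standard errors are Wald, from the inverse observed information.
#' Convergence requires a relative log-likelihood change below `1e-10` or a
#' gradient max-norm below `1e-8`. Terms with |coefficient| > 15 or
#' SE > 100 are flagged as possibly separated.
#'
#' @param outcome factor (or character) of outcome labels.
#' @param covariates data.frame of covariates; categorical columns are
#'   dummy-encoded against their first factor level.
#' @param reference reference outcome level (default `"high"` if present,
#'   else the first level).
#' @param maxit Newton iteration budget.
#' @return object of class `multinom_fit`: `coefficients` and
#'   `standard_errors` ((K-1) x p matrices, rows named
#'   `"<level>-vs-<reference>"`), `vcov`, `log_likelihood`, `aic`, `n`,
#'   `converged`, `flagged_terms`.
#' @export
fit_multinomial <- function(outcome, covariates, reference = NULL,
                            maxit = 100L) {
  y <- factor(outcome)
  if (is.null(reference)) {
    reference <- if ("high" %in% levels(y)) "high" else levels(y)[1L]
  }
  if (nlevels(y) < 2L) stop("outcome needs at least 2 levels", call. = FALSE)
  y <- stats::relevel(y, ref = reference)
  covariates <- as.data.frame(covariates)
  for (nm in names(covariates)) {
    if (is.character(covariates[[nm]]) || is.logical(covariates[[nm]])) {
      covariates[[nm]] <- factor(covariates[[nm]])
    }
    if (is.factor(covariates[[nm]]) &&
        any(table(covariates[[nm]]) == 0L)) {
      warning("dropping empty level(s) of ", nm, call. = FALSE)
      covariates[[nm]] <- droplevels(covariates[[nm]])
    }
    if (is.factor(covariates[[nm]]) && nlevels(covariates[[nm]]) < 2L) {
      warning("dropping constant covariate ", nm, call. = FALSE)
      covariates[[nm]] <- NULL
    }
  }
  X <- if (ncol(covariates) == 0L) {
    matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ ., data = covariates)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[-seq_len(qr_x$rank)]
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    warning("dropping aliased column(s): ",
            paste(colnames(X)[setdiff(seq_len(ncol(X)), keep)],
                  collapse = ", "), call. = FALSE)
    X <- X[, sort(keep), drop = FALSE]
  }
  n <- nrow(X)
  p <- ncol(X)
  K <- nlevels(y)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1

  B <- matrix(0, K - 1L, p)  # contrasts x terms
  loglik <- function(B) {
    eta <- X %*% t(B)                       # n x (K-1)
    denom <- 1 + rowSums(exp(eta))
    sum(eta[Y[, -1L, drop = FALSE] == 1]) - sum(log(denom))
  }
  probs <- function(B) {
    eta <- X %*% t(B)
    e <- exp(cbind(0, eta))
    e / rowSums(e)
  }
  ll <- loglik(B)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    P <- probs(B)
    G <- t(X) %*% (Y[, -1L, drop = FALSE] - P[, -1L, drop = FALSE])  # p x (K-1)
    g <- as.vector(G)
    if (max(abs(g)) < 1e-8) { converged <- TRUE; break }
    H <- matrix(0, (K - 1L) * p, (K - 1L) * p)
    for (c1 in seq_len(K - 1L)) {
      for (c2 in c1:(K - 1L)) {
        w <- if (c1 == c2) P[, c1 + 1L] * (1 - P[, c1 + 1L]) else
          -P[, c1 + 1L] * P[, c2 + 1L]
        blk <- crossprod(X, X * w)
        ri <- (c1 - 1L) * p + seq_len(p)
        ci <- (c2 - 1L) * p + seq_len(p)
        H[ri, ci] <- blk
        H[ci, ri] <- t(blk)
      }
    }
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8, nrow(H)), g)
    })
    new_B <- B
    lam <- 1
    repeat {
      # step is stacked contrast-major: reshape p x (K-1), then transpose
      cand <- B + lam * t(matrix(step, p, K - 1L))
      ll_new <- loglik(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) { new_B <- cand; break }
      lam <- lam / 2
      if (lam < 1e-10) { new_B <- B; ll_new <- ll; break }
    }
    rel <- abs(ll_new - ll) / (abs(ll) + 1e-10)
    B <- new_B
    if (rel < 1e-10 && it > 1L) { ll <- ll_new; converged <- TRUE; break }
    ll <- ll_new
  }
  P <- probs(B)
  H <- matrix(0, (K - 1L) * p, (K - 1L) * p)
  for (c1 in seq_len(K - 1L)) {
    for (c2 in c1:(K - 1L)) {
      w <- if (c1 == c2) P[, c1 + 1L] * (1 - P[, c1 + 1L]) else
        -P[, c1 + 1L] * P[, c2 + 1L]
      blk <- crossprod(X, X * w)
      ri <- (c1 - 1L) * p + seq_len(p)
      ci <- (c2 - 1L) * p + seq_len(p)
      H[ri, ci] <- blk
      H[ci, ri] <- t(blk)
    }
  }
  V <- tryCatch(solve(H), error = function(e) {
    warning("information matrix is singular; SEs are unreliable",
            call. = FALSE)
    MASS_ginv(H)
  })
  se <- t(matrix(sqrt(pmax(diag(V), 0)), p, K - 1L))
  contrasts <- paste0(levels(y)[-1L], "-vs-", reference)
  dimnames(B) <- list(contrasts, colnames(X))
  dimnames(se) <- list(contrasts, colnames(X))
  flagged <- colnames(X)[apply(abs(B) > 15 | se > 100, 2L, any)]
  if (length(flagged)) {
    warning("possible separation in term(s): ",
            paste(flagged, collapse = ", "), call. = FALSE)
  }
  npar <- (K - 1L) * p
  structure(list(
    coefficients = B, standard_errors = se, vcov = V,
    log_likelihood = ll, aic = -2 * ll + 2 * npar, n = n,
    reference_outcome = reference, outcome_levels = levels(y),
    converged = converged, flagged_terms = flagged,
    terms = colnames(X)
  ), class = "multinom_fit")
}

# Minimal Moore-Penrose fallback (avoids importing MASS for one edge case).
#' @keywords internal
MASS_ginv <- function(M) {
  s <- svd(M)
  pos <- s$d > max(s$d) * 1e-12
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.multinom_fit <- function(x, ...) {
  cat("Multinomial logit fit: n =", x$n,
      "| logLik =", format(x$log_likelihood, digits = 8),
      "| AIC =", format(x$aic, digits = 8),
      "| converged:", x$converged, "\n")
  cat("Reference outcome:", x$reference_outcome, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Odds-ratio table with Wald 95% confidence intervals
#'
#' One row per non-intercept term and outcome contrast:
#' `OR = exp(coef)`, `CI = exp(coef +/- 1.96 SE)`.
#'
#' @param fit a converged [fit_multinomial()] object.
#' @return data.table with `term`, `contrast`, `odds_ratio`, `ci_low`,
#'   `ci_high`.
#' @export
or_table <- function(fit) {
  stopifnot(inherits(fit, "multinom_fit"))
  if (!fit$converged) {
    stop("fit did not converge; refusing to report odds ratios",
         call. = FALSE)
  }
  B <- fit$coefficients
  S <- fit$standard_errors
  terms <- setdiff(colnames(B), "(Intercept)")
  out <- data.table::CJ(contrast = rownames(B), term = terms, sorted = FALSE)
  out[, `:=`(
    odds_ratio = exp(B[cbind(contrast, term)]),
    ci_low = exp(B[cbind(contrast, term)] - 1.96 * S[cbind(contrast, term)]),
    ci_high = exp(B[cbind(contrast, term)] + 1.96 * S[cbind(contrast, term)])
  )]
  data.table::setcolorder(out, c("term", "contrast"))
  out[]
}

#' Bidirectional stepwise model selection by AIC
#'
#' Starts from the intercept-only model and repeatedly applies the single
#' variable addition or removal that most lowers the AIC, with categorical
#' variables entering and leaving as whole blocks, until no move lowers it.
#' Ties in AIC prefer the smaller model, then alphabetical term order.
#'
#' @param outcome outcome labels.
#' @param covariates data.frame of candidate covariates (each column is one
#'   candidate block).
#' @param reference reference outcome level.
#' @param trace print the path as it is walked.
#' @return list with `fit` (final [fit_multinomial()]), `selected`
#'   (variable names), `path` (data.table of visited moves and AICs).
#' @export
stepwise_aic <- function(outcome, covariates, reference = NULL,
                         trace = FALSE) {
  covariates <- as.data.frame(covariates)
  candidates <- names(covariates)
  current <- character(0)
  fit_for <- function(vars) {
    if (length(vars) == 0L) {
      fit_multinomial(outcome,
                      data.frame(row.names = seq_along(outcome)),
                      reference = reference)
    } else {
      fit_multinomial(outcome, covariates[, vars, drop = FALSE],
                      reference = reference)
    }
  }
  cache <- new.env(parent = emptyenv())
  aic_of <- function(vars) {
    key <- paste0("m|", paste(sort(vars), collapse = "|"))
    if (is.null(cache[[key]])) cache[[key]] <- fit_for(vars)$aic
    cache[[key]]
  }
  cur_aic <- aic_of(current)
  path <- list(data.table::data.table(step = 0L, action = "start",
                                      term = "", aic = cur_aic))
  step_i <- 0L
  repeat {
    moves <- data.table::rbindlist(c(
      lapply(sort(setdiff(candidates, current)), function(v) {
        data.table::data.table(action = "add", term = v,
                               aic = aic_of(c(current, v)),
                               size = length(current) + 1L)
      }),
      lapply(sort(current), function(v) {
        data.table::data.table(action = "drop", term = v,
                               aic = aic_of(setdiff(current, v)),
                               size = length(current) - 1L)
      })
    ))
    if (nrow(moves) == 0L) break
    data.table::setorder(moves, aic, size, term)
    best <- moves[1L]
    if (best$aic >= cur_aic - 1e-9) break
    current <- if (best$action == "add") c(current, best$term) else
      setdiff(current, best$term)
    cur_aic <- best$aic
    step_i <- step_i + 1L
    path[[length(path) + 1L]] <- data.table::data.table(
      step = step_i, action = best$action, term = best$term, aic = cur_aic
    )
    if (trace) {
      message(sprintf("step %d: %s %s -> AIC %.2f", step_i, best$action,
                      best$term, cur_aic))
    }
  }
  list(fit = fit_for(current), selected = sort(current),
       path = data.table::rbindlist(path))
}
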