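# Principal-component selection of a non-redundant measure subset.

#' Select the measure subset explaining most variance
#'
#' Three-stage reduction of the 24-measure matrix: (a) drop zero-variance
#' measures; (b) among pairs with |Pearson r| >= `cor_cut` drop the
#' higher-indexed member; (c) standardize, run PCA on the correlation
#' matrix, retain components by a sampling-guarded Kaiser criterion,
#' varimax-rotate the retained loadings, and pick per component the measure
#' with the largest absolute rotated loading (deduplicated, components in
#' order of retained variance).
#'
#' The retention threshold is the Kaiser eigenvalue-greater-than-1 rule
#' guarded against sampling fluctuation: a component is kept when its
#' eigenvalue exceeds the null upper edge `(1 + sqrt(p/n))^2` of the
#' eigenvalue distribution of uncorrelated data (Horn's parallel analysis
#' in its asymptotic Marchenko-Pastur form). Raw Kaiser retains any
#' measure that happens to be uncorrelated with the rest as its own
#' component, because a singleton's eigenvalue fluctuates around exactly 1;
#' the guard removes that knife-edge without affecting genuinely shared
#' components.
#'
#' @param measures data.table from [compute_measures()] or a numeric matrix
#'   of measures (columns named).
#' @param cor_cut correlation threshold for the redundancy prune
#'   (default 0.95).
#' @return list of class `traj_selection`: `selected` (measure names),
#'   `eigenvalues`, `loadings` (rotated, retained components),
#'   `dropped_zero_variance`, `dropped_correlated`, `n_components`,
#'   `eigen_threshold`.
#' @export
select_measures <- function(measures, cor_cut = 0.95) {
  M <- if (is.matrix(measures)) measures else
    as.matrix(data.table::as.data.table(measures)[, !"patient_id"])
  if (nrow(M) < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (any(!is.finite(M))) stop("measure matrix must be finite", call. = FALSE)

  sds <- apply(M, 2L, stats::sd)
  zero_var <- colnames(M)[sds < 1e-12]
  keep <- setdiff(colnames(M), zero_var)
  M1 <- M[, keep, drop = FALSE]

  # Redundancy prune: keep the lower-indexed member of any highly
  # correlated pair (column order = measure order).
  r <- abs(stats::cor(M1))
  dropped_cor <- character()
  retained <- rep(TRUE, ncol(M1))
  for (j in seq_len(ncol(M1))[-1]) {
    if (any(retained[seq_len(j - 1L)] & r[seq_len(j - 1L), j] >= cor_cut)) {
      retained[j] <- FALSE
      dropped_cor <- c(dropped_cor, colnames(M1)[j])
    }
  }
  M2 <- M1[, retained, drop = FALSE]
  if (ncol(M2) < 1L) stop("no measures left after pruning", call. = FALSE)

  cmat <- stats::cor(M2)
  ev_min <- min(eigen(cmat, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-12) {
    stop("correlation matrix is singular after pruning; ",
         "lower cor_cut or inspect the measures", call. = FALSE)
  }
  pca <- stats::prcomp(M2, center = TRUE, scale. = TRUE)
  eigenvalues <- pca$sdev^2
  thr <- max(1, (1 + sqrt(ncol(M2) / nrow(M2)))^2)
  n_comp <- max(1L, sum(eigenvalues > thr))
  load_raw <- pca$rotation[, seq_len(n_comp), drop = FALSE] %*%
    diag(pca$sdev[seq_len(n_comp)], n_comp)
  loadings <- if (n_comp > 1L) {
    rot <- stats::varimax(load_raw)
    unclass(rot$loadings)
  } else {
    load_raw
  }
  dimnames(loadings) <- list(colnames(M2), paste0("PC", seq_len(n_comp)))

  selected <- character(0)
  for (pc in seq_len(n_comp)) {
    ord <- order(abs(loadings[, pc]), decreasing = TRUE)
    pick <- setdiff(rownames(loadings)[ord], selected)
    if (length(pick)) selected <- c(selected, pick[1L])
  }
  structure(list(
    selected = selected,
    eigenvalues = eigenvalues,
    loadings = loadings,
    dropped_zero_variance = zero_var,
    dropped_correlated = dropped_cor,
    n_components = n_comp,
    eigen_threshold = thr
  ), class = "traj_selection")
}

#' @export
print.traj_selection <- function(x, ...) {
  cat("Measure selection:", x$n_components, "components (eigenvalue > 1),",
      "selected:", paste(x$selected, collapse = ", "), "\n")
  if (length(x$dropped_zero_variance)) {
    cat("  dropped (zero variance):",
        paste(x$dropped_zero_variance, collapse = ", "), "\n")
  }
  if (length(x$dropped_correlated)) {
    cat("  dropped (|r| >= cut):",
        paste(x$dropped_correlated, collapse = ", "), "\n")
  }
  invisible(x)
}
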