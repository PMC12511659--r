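# k-means trajectory clustering with a majority vote of validity indices.

#' Cluster a standardized measure matrix with k-means
#'
#' Thin deterministic wrapper around [stats::kmeans()]: `nstart` random
#' restarts from a fixed seed, best within-cluster sum of squares kept.
#'
#' @param X numeric matrix (rows = patients).
#' @param k number of clusters (>= 2).
#' @param seed RNG seed.
#' @param nstart restarts (default 50).
#' @return list with `assignments` (integer vector), `centroids`, `wss`
#'   (total within-cluster sum of squares).
#' @export
cluster_kmeans <- function(X, k, seed = 1L, nstart = 50L) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite values in input", call. = FALSE)
  stopifnot(k >= 2, nrow(X) >= k)
  if (nrow(X) == k) {
    # one point per cluster; stats::kmeans refuses this trivial case
    return(list(assignments = seq_len(k), centroids = X, wss = 0))
  }
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = nstart, iter.max = 200L)
  list(assignments = km$cluster, centroids = km$centers,
       wss = km$tot.withinss)
}

# ---- validity indices -------------------------------------------------

# Centroid-based quantities for one partition.
#' @keywords internal
partition_stats <- function(X, cl, k) {
  n <- nrow(X)
  cen <- matrix(0, k, ncol(X))
  for (j in seq_len(k)) {
    cen[j, ] <- colMeans(X[cl == j, , drop = FALSE])
  }
  d2 <- rowSums((X - cen[cl, , drop = FALSE])^2)
  wss_j <- tapply(d2, cl, sum)
  gmean <- colMeans(X)
  bss <- sum(tabulate(cl, k) * rowSums((cen - matrix(gmean, k, ncol(X),
                                                     byrow = TRUE))^2))
  cen_d2 <- as.matrix(stats::dist(cen))^2
  list(cen = cen, wss = sum(d2), wss_j = wss_j, bss = bss, d2 = d2,
       cen_d2 = cen_d2, sizes = tabulate(cl, k), n = n)
}

# Pairwise-distance indices computed on a (possibly subsampled) partition.
#' @keywords internal
pairwise_indices <- function(X, cl) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(D)
  same <- outer(cl, cl, "==")
  ut <- upper.tri(D)
  dw <- D[ut & same]
  db <- D[ut & !same]
  # silhouette
  sil <- mean(cluster::silhouette(cl, dmatrix = D)[, "sil_width"])
  # Dunn: min between-cluster distance / max within-cluster diameter
  dunn <- if (length(dw) && length(db)) min(db) / max(dw) else NA_real_
  # C-index
  nw <- length(dw)
  alld <- sort(D[ut])
  smin <- sum(alld[seq_len(nw)])
  smax <- sum(alld[seq.int(length(alld) - nw + 1L, length(alld))])
  cindex <- if (smax > smin) (sum(dw) - smin) / (smax - smin) else 0
  # McClain-Rao: mean within / mean between
  mcr <- mean(dw) / mean(db)
  list(silhouette = sil, dunn = dunn, c_index = cindex, mcclain = mcr)
}

#' Choose the number of clusters by majority rule
#'
#' Clusters the matrix for each candidate `k`, scores each partition with a
#' battery of cluster-validity indices (Calinski-Harabasz, mean silhouette,
#' Davies-Bouldin, Dunn, C-index, McClain-Rao, Ball-Hall, Xie-Beni,
#' Hartigan rule, PBM), lets each index vote for its optimal `k`, and
#' returns the modal vote (ties resolved to the smaller `k`). A `forced_k`
#' override implements the clinical-plausibility criterion: the vote tally
#' is still computed and reported, but the returned `k` is the forced one.
#'
#' Pairwise-distance indices (silhouette, Dunn, C-index, McClain-Rao) are
#' computed on a seeded subsample of at most `subsample` rows to bound the
#' quadratic cost; centroid-based indices use all rows.
#'
#' @param X standardized selected-measure matrix.
#' @param k_range candidate cluster counts (default 2:10).
#' @param seed RNG seed.
#' @param nstart k-means restarts per k.
#' @param subsample row cap for pairwise indices (default 2000).
#' @param forced_k optional override of the voted k.
#' @return list with `k`, `index_votes` (named integer vector), `votes_k`
#'   (tally), `fits` (per-k clustering results).
#' @export
choose_k <- function(X, k_range = 2:10, seed = 1L, nstart = 50L,
                     subsample = 2000L, forced_k = NULL) {
  X <- as.matrix(X)
  n_distinct <- nrow(unique(X))
  if (n_distinct < 2L) {
    stop("fewer than 2 distinct rows; clustering is degenerate", call. = FALSE)
  }
  k_range <- k_range[k_range <= n_distinct - 1L & k_range >= 2L]
  if (!length(k_range)) stop("no feasible k in k_range", call. = FALSE)
  k_all <- c(k_range, max(k_range) + 1L)  # extra k for the Hartigan rule
  k_all <- k_all[k_all <= n_distinct]

  n <- nrow(X)
  set.seed(stage_seed(seed, "subsample"))
  sub <- if (n > subsample) sort(sample.int(n, subsample)) else seq_len(n)

  fits <- list()
  stats_k <- list()
  pw_k <- list()
  for (k in k_all) {
    fit <- cluster_kmeans(X, k, seed = stage_seed(seed, paste0("k", k)),
                          nstart = nstart)
    fits[[as.character(k)]] <- fit
    ps <- partition_stats(X, fit$assignments, k)
    stats_k[[as.character(k)]] <- ps
    if (k %in% k_range) {
      cl_sub <- fit$assignments[sub]
      pw_k[[as.character(k)]] <- if (length(unique(cl_sub)) >= 2L) {
        pairwise_indices(X[sub, , drop = FALSE], cl_sub)
      } else {
        list(silhouette = -Inf, dunn = -Inf, c_index = Inf, mcclain = Inf)
      }
    }
  }
  tss <- sum(scale(X, scale = FALSE)^2)

  score <- function(fun) vapply(as.character(k_range), fun, numeric(1))
  ch <- score(function(kk) {
    ps <- stats_k[[kk]]; k <- as.integer(kk)
    (ps$bss / (k - 1)) / (ps$wss / (ps$n - k))
  })
  db <- score(function(kk) {
    ps <- stats_k[[kk]]; k <- as.integer(kk)
    sbar <- sqrt(ps$wss_j / ps$sizes)
    mx <- 0
    for (i in seq_len(k)) {
      rij <- (sbar[i] + sbar[-i]) / sqrt(ps$cen_d2[i, -i])
      mx <- mx + max(rij)
    }
    mx / k
  })
  xb <- score(function(kk) {
    ps <- stats_k[[kk]]
    off <- ps$cen_d2[upper.tri(ps$cen_d2)]
    ps$wss / (ps$n * min(off))
  })
  pbm <- score(function(kk) {
    ps <- stats_k[[kk]]; k <- as.integer(kk)
    e1 <- sum(sqrt(rowSums(scale(X, scale = FALSE)^2)))
    ek <- sum(sqrt(ps$d2))
    dk <- sqrt(max(ps$cen_d2))
    ((1 / k) * (e1 / ek) * dk)^2
  })
  bh <- vapply(as.character(k_all), function(kk) {
    stats_k[[kk]]$wss / as.integer(kk)
  }, numeric(1))
  bh_prev <- c(tss, bh[-length(bh)])[seq_along(k_range)]
  bh_diff <- bh_prev - bh[seq_along(k_range)]
  hart <- vapply(seq_along(k_range), function(i) {
    k <- k_range[i]
    w_k <- stats_k[[as.character(k)]]$wss
    nxt <- as.character(k + 1L)
    if (is.null(stats_k[[nxt]])) return(NA_real_)
    (w_k / stats_k[[nxt]]$wss - 1) * (n - k - 1)
  }, numeric(1))
  sil <- vapply(pw_k, `[[`, numeric(1), "silhouette")
  dunn <- vapply(pw_k, `[[`, numeric(1), "dunn")
  cind <- vapply(pw_k, `[[`, numeric(1), "c_index")
  mcr <- vapply(pw_k, `[[`, numeric(1), "mcclain")

  vote_max <- function(v) k_range[which.max(v)]
  vote_min <- function(v) k_range[which.min(v)]
  hart_ok <- which(!is.na(hart) & hart <= 10)
  index_votes <- c(
    calinski_harabasz = vote_max(ch),
    silhouette = vote_max(sil),
    davies_bouldin = vote_min(db),
    dunn = vote_max(dunn),
    c_index = vote_min(cind),
    mcclain_rao = vote_min(mcr),
    ball_hall = vote_max(bh_diff),
    xie_beni = vote_min(xb),
    hartigan = if (length(hart_ok)) k_range[min(hart_ok)] else max(k_range),
    pbm = vote_max(pbm)
  )
  tally <- table(index_votes)
  k_voted <- as.integer(names(tally)[tally == max(tally)])
  k_voted <- min(k_voted)  # tie -> smaller k
  k_final <- if (!is.null(forced_k)) as.integer(forced_k) else k_voted
  list(k = k_final, k_voted = k_voted, index_votes = index_votes,
       votes_k = tally, fits = fits[as.character(k_range)])
}

#' Order and name clusters by mean adherence
#'
#' Clusters are ordered by descending overall mean PDC; with three clusters
#' they are labelled `high`/`medium`/`low`, otherwise `cluster-1..k`. Ties
#' in mean PDC break by descending cluster size, then cluster id.
#'
#' @param assignments integer cluster vector (named by patient id or aligned
#'   with `pdc` rows).
#' @param pdc numeric PDC matrix (rows aligned with `assignments`).
#' @return list with `labels` (character vector per patient), `map`
#'   (data.table cluster -> label -> mean_pdc -> n).
#' @export
label_clusters <- function(assignments, pdc) {
  k <- length(unique(assignments))
  patient_mean <- rowMeans(pdc)
  map <- data.table::data.table(
    cluster = sort(unique(assignments)),
    mean_pdc = as.numeric(tapply(patient_mean, assignments, mean)),
    n = as.integer(table(assignments))
  )
  data.table::setorder(map, -mean_pdc, -n, cluster)
  map[, label := if (k == 3L) c("high", "medium", "low") else
    paste0("cluster-", seq_len(k))]
  labels <- map$label[match(assignments, map$cluster)]
  if (!is.null(rownames(pdc))) names(labels) <- rownames(pdc)
  list(labels = labels, map = map[])
}

#' Fit the full trajectory model
#'
#' Runs the three-stage trajectory procedure on a monthly PDC series table:
#' 24 change measures, PCA measure selection, choice of k by majority rule,
#' k-means on the standardized selected measures, and adherence-ordered
#' cluster labels.
#'
#' @param series long PDC series table from [monthly_pdc()].
#' @param k_range candidate numbers of clusters.
#' @param forced_k optional clinical-plausibility override.
#' @param seed RNG seed for clustering.
#' @param nstart k-means restarts.
#' @return object of class `traj_model`: selection report, standardization
#'   parameters, `k`, `index_votes`, centroids, per-patient `assignments`
#'   table (patient_id, cluster, label), and the label map.
#' @export
fit_trajectories <- function(series, k_range = 2:10, forced_k = NULL,
                             seed = 1L, nstart = 50L) {
  pdcm <- pdc_matrix(series)
  meas <- compute_measures(pdcm)
  sel <- select_measures(meas)
  M <- as.matrix(meas[, sel$selected, with = FALSE])
  ctr <- colMeans(M)
  scl <- apply(M, 2L, stats::sd)
  Z <- scale(M, center = ctr, scale = scl)
  ck <- choose_k(Z, k_range = k_range, seed = seed, nstart = nstart,
                 forced_k = forced_k)
  fit <- if (as.character(ck$k) %in% names(ck$fits)) {
    ck$fits[[as.character(ck$k)]]
  } else {
    cluster_kmeans(Z, ck$k, seed = stage_seed(seed, paste0("k", ck$k)),
                   nstart = nstart)
  }
  lab <- label_clusters(fit$assignments, pdcm)
  assignments <- data.table::data.table(
    patient_id = meas$patient_id,
    cluster = fit$assignments,
    label = lab$labels
  )
  structure(list(
    selected_measures = sel$selected,
    selection = sel,
    standardization = data.table::data.table(
      measure = sel$selected, mean = ctr, sd = scl
    ),
    k = ck$k, k_voted = ck$k_voted, index_votes = ck$index_votes,
    centroids = fit$centroids,
    assignments = assignments,
    label_map = lab$map,
    measures = meas,
    seed = seed
  ), class = "traj_model")
}

#' @export
print.traj_model <- function(x, ...) {
  cat("Trajectory model: k =", x$k,
      sprintf("(majority vote: %d)", x$k_voted), "\n")
  cat("Selected measures:", paste(x$selected_measures, collapse = ", "), "\n")
  cat("Cluster shares:\n")
  shr <- x$assignments[, .N, by = label][, pct := 100 * N / sum(N)]
  print(shr)
  invisible(x)
}
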