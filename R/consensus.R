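#' K-medoids clustering on a distance matrix
#'
#' PAM-style alternation: start from k random medoids, assign every point to
#' its nearest medoid, recompute each cluster's medoid as the member with the
#' smallest within-cluster distance sum, and repeat until the medoid set is
#' stable. The best of `n_init` seeded random restarts (by total
#' distance-to-medoid cost) is returned; results are deterministic given
#' `seed`. When the number of possible medoid sets is small (`choose(n, k)
#' <= 256`) every subset is used as a starting point instead, which makes
#' the returned cost the exact optimum on such problems.
#'
#' @param dist symmetric non-negative distance matrix with zero diagonal.
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed integer seed for the restarts.
#' @param n_init number of random restarts (default 10).
#' @return list with `labels` (1..k, relabeled by first appearance),
#'   `medoids` (indices into `dist`), and `cost` (total distance to medoid).
#' @export
k_medoids <- function(dist, k, seed = 1L, n_init = 10L) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (ncol(dist) != n || max(abs(dist - t(dist))) > 1e-8) stopf("dist must be symmetric")
  if (any(abs(diag(dist)) > 1e-12)) stopf("dist must have a zero diagonal")
  if (any(dist < -1e-12)) stopf("dist must be non-negative")
  if (k < 1 || k > n) stopf("k = %d outside 1..n (n = %d)", k, n)
  res <- kmedoids_cpp(dist, as.integer(k), as.integer(n_init), as.double(seed))
  if (length(unique(res$labels)) != k) stopf("k_medoids produced an empty cluster")
  res
}

# 1 - Pearson correlation between samples across the feature rows; the
# pipeline's sample-sample distance for expression clustering.
correlation_distance <- function(feature_matrix) {
  # crossprod-based Pearson correlation (hot path of the consensus loop)
  X <- feature_matrix - rep(colMeans(feature_matrix), each = nrow(feature_matrix))
  ss <- sqrt(colSums(X^2))
  d <- 1 - crossprod(X) / outer(ss, ss)
  d[is.na(d)] <- 1       # zero-variance column: maximally distant
  d[d < 0] <- 0          # clamp tiny negatives from rounding
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Consensus matrix from resampled K-medoids runs
#'
#' Each of `n_reps` repetitions draws `ceiling(sample_frac * n)` samples and
#' `ceiling(feature_frac * g)` genes without replacement, clusters the
#' subsample with [k_medoids()] on the correlation distance, and tallies
#' co-cluster events. `consensus[i, j]` is the fraction of repetitions in
#' which i and j were clustered together among those where both were drawn;
#' pairs never co-drawn get 0.5 with a warning; the diagonal is 1.
#'
#' @param zm `ExpressionMatrix` with `scale = "zscored"`.
#' @param k number of clusters per repetition.
#' @param n_reps number of resampled repetitions (default 100).
#' @param sample_frac,feature_frac resampling fractions in (0, 1]
#'   (default 0.8 each).
#' @param seed master seed; each repetition uses a derived substream.
#' @param n_init restarts per K-medoids run.
#' @return symmetric n x n consensus matrix in `[0, 1]`.
#' @export
build_consensus <- function(zm, k, n_reps = 100L, sample_frac = 0.8,
                            feature_frac = 0.8, seed = 1L, n_init = 10L) {
  stopifnot(inherits(zm, "ExpressionMatrix"), zm$scale == "zscored",
            n_reps >= 1, sample_frac > 0, sample_frac <= 1,
            feature_frac > 0, feature_frac <= 1)
  n <- length(zm$sample_ids)
  g <- length(zm$gene_ids)
  ns <- ceiling(sample_frac * n)
  ng <- ceiling(feature_frac * g)
  if (ns < k) stopf("each repetition draws %d samples, fewer than k = %d", ns, k)
  co <- matrix(0, n, n)
  tot <- matrix(0, n, n)
  for (r in seq_len(n_reps)) {
    rs <- derive_seed(seed, 1000L * k + r)
    draw <- with_seed(rs, list(s = sort(sample.int(n, ns)), f = sort(sample.int(g, ng))))
    d <- correlation_distance(zm$values[draw$f, draw$s, drop = FALSE])
    lab <- k_medoids(d, k, seed = rs, n_init = n_init)$labels
    same <- outer(lab, lab, "==")
    co[draw$s, draw$s] <- co[draw$s, draw$s] + same
    tot[draw$s, draw$s] <- tot[draw$s, draw$s] + 1
  }
  cons <- ifelse(tot > 0, co / pmax(tot, 1), 0.5)
  if (any(tot == 0 & upper.tri(tot))) {
    warnf("%d sample pair(s) never co-drawn; consensus set to 0.5",
          sum(tot == 0 & upper.tri(tot)))
  }
  diag(cons) <- 1
  dimnames(cons) <- list(zm$sample_ids, zm$sample_ids)
  cons
}

#' Silhouette widths for a clustering on a distance matrix
#'
#' Standard silhouette: for sample i with mean within-cluster distance `a`
#' and mean distance `b` to the nearest other cluster,
#' `s(i) = (b - a) / max(a, b)`; members of singleton clusters get 0.
#'
#' @param dist symmetric distance matrix.
#' @param labels integer cluster labels covering at least 2 clusters.
#' @return list with `widths` (per sample) and `mean` width.
#' @export
silhouette_width <- function(dist, labels) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  stopifnot(length(labels) == n)
  cl <- sort(unique(labels))
  if (length(cl) < 2) stopf("silhouette needs at least 2 clusters")
  sizes <- table(factor(labels, levels = cl))
  # mean distance from each point to each cluster
  means <- vapply(cl, function(c) rowSums(dist[, labels == c, drop = FALSE]) / sizes[[as.character(c)]],
                  numeric(n))
  widths <- numeric(n)
  for (i in seq_len(n)) {
    ci <- match(labels[i], cl)
    sz <- sizes[[ci]]
    if (sz == 1) { widths[i] <- 0; next }
    a <- means[i, ci] * sz / (sz - 1)          # exclude self from own-cluster mean
    b <- min(means[i, -ci])
    widths[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  list(widths = widths, mean = mean(widths))
}

#' Consensus-clustering configuration
#'
#' @param k_range candidate cluster numbers (default 2:8).
#' @param n_reps resampled repetitions per k (default 100).
#' @param sample_frac,feature_frac resampling fractions (default 0.8).
#' @param n_init K-medoids restarts per run (default 10).
#' @param seed master seed.
#' @return list of class `consensus_config`.
#' @export
consensus_config <- function(k_range = 2:8, n_reps = 100L, sample_frac = 0.8,
                             feature_frac = 0.8, n_init = 10L, seed = 1L) {
  stopifnot(all(k_range >= 2), n_reps >= 1)
  structure(list(k_range = as.integer(k_range), n_reps = as.integer(n_reps),
                 sample_frac = sample_frac, feature_frac = feature_frac,
                 n_init = as.integer(n_init), seed = as.integer(seed)),
            class = "consensus_config")
}

#' Per-cohort consensus clustering with silhouette-based k selection
#'
#' For every k in `cfg$k_range`: build the consensus matrix, cluster the
#' consensus distance `1 - consensus` with [k_medoids()], and record the mean
#' silhouette width on that distance. The chosen k maximizes the mean
#' silhouette (ties go to the smallest k) and the final labels are those
#' computed at the chosen k.
#'
#' @param zm `ExpressionMatrix` with `scale = "zscored"`.
#' @param cfg a [consensus_config()].
#' @return A `ConsensusResult`: list with `cohort_id`, `k_range`, `chosen_k`,
#'   `consensus` (matrix at the chosen k), `labels` (named integer vector),
#'   `mean_silhouette_by_k`, and the resampling parameters.
#' @export
select_k_and_cluster <- function(zm, cfg = consensus_config()) {
  stopifnot(inherits(zm, "ExpressionMatrix"), zm$scale == "zscored")
  n <- length(zm$sample_ids)
  if (n < max(cfg$k_range) + 1) {
    stopf("%d samples cannot support k up to %d; shrink k_range", n, max(cfg$k_range))
  }
  sil <- stats::setNames(numeric(length(cfg$k_range)), cfg$k_range)
  fits <- vector("list", length(cfg$k_range))
  for (i in seq_along(cfg$k_range)) {
    k <- cfg$k_range[i]
    cons <- build_consensus(zm, k, cfg$n_reps, cfg$sample_frac, cfg$feature_frac,
                            seed = cfg$seed, n_init = cfg$n_init)
    dcons <- 1 - cons
    diag(dcons) <- 0
    fit <- k_medoids(dcons, k, seed = derive_seed(cfg$seed, 7L * k), n_init = cfg$n_init)
    sil[i] <- silhouette_width(dcons, fit$labels)$mean
    fits[[i]] <- list(consensus = cons, labels = fit$labels)
  }
  best <- which(sil == max(sil))[1]          # ties -> smallest k
  chosen_k <- cfg$k_range[best]
  labels <- stats::setNames(fits[[best]]$labels, zm$sample_ids)
  structure(
    list(cohort_id = zm$cohort_id, k_range = cfg$k_range, chosen_k = chosen_k,
         consensus = fits[[best]]$consensus, labels = labels,
         mean_silhouette_by_k = sil, n_reps = cfg$n_reps,
         sample_frac = cfg$sample_frac, feature_frac = cfg$feature_frac,
         seed = cfg$seed),
    class = "ConsensusResult"
  )
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf("<ConsensusResult> cohort '%s': chosen k = %d (silhouette %.3f), %d samples\n",
              x$cohort_id, x$chosen_k,
              x$mean_silhouette_by_k[[as.character(x$chosen_k)]], length(x$labels)))
  invisible(x)
}
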