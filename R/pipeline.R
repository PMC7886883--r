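#' Multi-cohort subtype discovery, end to end
#'
#' Convenience driver chaining the per-cohort steps (zero-fraction gene
#' filter, size-factor log normalization, top-variance z-scored feature
#' matrix, consensus K-medoids with silhouette-selected k) with the
#' cross-cohort steps (shared-gene centroids, Pearson centroid network,
#' label-propagation meta-clustering, stemness-signature annotation).
#'
#' @param cohorts list of raw-count `ExpressionMatrix` objects.
#' @param signature character vector of stemness signature gene ids used to
#'   orient the primitive/committed annotation.
#' @param pre_cfg a [preprocess_config()].
#' @param k_range,n_reps,sample_frac,feature_frac,n_init consensus-clustering
#'   settings, see [consensus_config()].
#' @param min_edge_corr centroid-network edge threshold.
#' @param seed master seed; per-cohort clustering and community detection
#'   use derived substreams.
#' @return list with `per_cohort` (named list of `ConsensusResult`),
#'   `log_matrices` (log-normalized matrices, for the DE step), `centroids`,
#'   `network`, `communities`, `subtype_map`, `scores`, `assignments`
#'   (data.frame `cohort_id`, `sample_id`, `cluster_id`, `meta_cluster_id`,
#'   `subtype`) and `subtypes` (named vector sample id -> subtype).
#' @export
discover_subtypes <- function(cohorts, signature,
                              pre_cfg = preprocess_config(),
                              k_range = 2:8, n_reps = 100L,
                              sample_frac = 0.8, feature_frac = 0.8,
                              n_init = 10L, min_edge_corr = 0.5, seed = 1L) {
  stopifnot(length(cohorts) >= 2)
  zms <- list(); logs <- list(); results <- list()
  for (i in seq_along(cohorts)) {
    em <- cohorts[[i]]
    em_f <- filter_low_expressed_genes(em, pre_cfg)
    em_log <- normalize_log(em_f, pre_cfg)
    zm <- prepare_clustering_matrix(em_log, pre_cfg)
    cfg <- consensus_config(k_range = k_range, n_reps = n_reps,
                            sample_frac = sample_frac, feature_frac = feature_frac,
                            n_init = n_init, seed = derive_seed(seed, 500L + i))
    res <- select_k_and_cluster(zm, cfg)
    zms[[em$cohort_id]] <- zm
    logs[[em$cohort_id]] <- em_log
    results[[em$cohort_id]] <- res
  }
  labels_list <- lapply(results, `[[`, "labels")
  centroids <- compute_centroids(zms, labels_list)
  network <- build_centroid_network(centroids, min_edge_corr = min_edge_corr)
  communities <- label_propagation_communities(network, seed = derive_seed(seed, 900L))
  assignments <- do.call(rbind, lapply(results, function(r) {
    data.frame(cohort_id = r$cohort_id, sample_id = names(r$labels),
               cluster_id = unname(r$labels), stringsAsFactors = FALSE)
  }))
  rownames(assignments) <- NULL
  ann <- annotate_subtypes(communities, centroids, signature, assignments)
  subtypes <- stats::setNames(ann$assignments$subtype, ann$assignments$sample_id)
  list(per_cohort = results, log_matrices = logs, z_matrices = zms,
       centroids = centroids, network = network, communities = communities,
       subtype_map = ann$subtype_map, scores = ann$scores,
       assignments = ann$assignments, subtypes = subtypes)
}

#' Drug prioritization against transferred subtype labels
#'
#' Trains the elastic-net subtype classifier on one patient cohort, predicts
#' primitive probabilities for the cell-line panel after feature
#' harmonization, fits Hill curves to the screen, and ranks drugs by
#' concordance index with a permutation null.
#'
#' @param train_log log-normalized `ExpressionMatrix` of the training
#'   cohort.
#' @param subtypes named subtype vector covering the training samples.
#' @param cellline_counts raw-count `ExpressionMatrix` of the panel.
#' @param dose_response long screen table (see
#'   [read_dose_response_table()]).
#' @param n_perm permutations per drug.
#' @param seed master seed.
#' @param pre_cfg preprocessing applied to the cell-line counts.
#' @return list with `model`, `probabilities`, `curves` (per line x drug
#'   fit table) and `ranking` (from [rank_drugs()]).
#' @export
prioritize_drugs <- function(train_log, subtypes, cellline_counts, dose_response,
                             n_perm = 1000L, seed = 1L,
                             pre_cfg = preprocess_config()) {
  cl_f <- filter_low_expressed_genes(cellline_counts, pre_cfg)
  cl_log <- normalize_log(cl_f, pre_cfg)
  harm <- harmonize_features(train_log, cl_log)
  y <- subtypes[harm$train$sample_ids]
  model <- fit_elasticnet_classifier(t(harm$train$values), y,
                                     seed = derive_seed(seed, 41L))
  prob <- predict_subtype_prob(model, t(harm$test$values))
  curves <- fit_hill_table(dose_response)
  ranking <- rank_drugs(prob, curves, n_perm = n_perm,
                        seed = derive_seed(seed, 42L))
  list(model = model, probabilities = prob, curves = curves, ranking = ranking)
}
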