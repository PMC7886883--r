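#' Per-cluster centroids on the shared gene universe
#'
#' For every cluster in every cohort, the centroid is the arithmetic mean of
#' its member samples' z-scored expression restricted to the genes shared by
#' all cohorts.
#'
#' @param zm_list named list of z-scored `ExpressionMatrix` objects, one per
#'   cohort.
#' @param labels_list list (same order) of integer cluster labels named by
#'   sample id.
#' @param min_shared minimum size of the shared gene universe (default 50).
#' @return A `ClusterCentroids` object: list with `gene_ids`, `values`
#'   (genes x nodes matrix) and `nodes` (data.frame `cohort_id`, `cluster_id`,
#'   `n_samples`). Node names are `"<cohort>:<cluster>"`.
#' @export
compute_centroids <- function(zm_list, labels_list, min_shared = 50L) {
  stopifnot(length(zm_list) == length(labels_list), length(zm_list) >= 1)
  shared <- Reduce(intersect, lapply(zm_list, function(z) z$gene_ids))
  if (length(shared) < min_shared) {
    counts <- vapply(zm_list, function(z) length(z$gene_ids), integer(1))
    stopf("shared gene universe has %d genes (< %d); per-cohort gene counts: %s",
          length(shared), min_shared,
          paste(sprintf("%s=%d", vapply(zm_list, `[[`, "", "cohort_id"), counts), collapse = ", "))
  }
  vals <- list(); nodes <- list()
  for (i in seq_along(zm_list)) {
    zm <- zm_list[[i]]
    lab <- labels_list[[i]]
    stopifnot(!is.null(names(lab)), all(names(lab) %in% zm$sample_ids))
    sub <- zm$values[shared, names(lab), drop = FALSE]
    for (cl in sort(unique(lab))) {
      members <- sub[, lab == cl, drop = FALSE]
      vals[[length(vals) + 1L]] <- rowMeans(members)
      nodes[[length(nodes) + 1L]] <- data.frame(
        cohort_id = zm$cohort_id, cluster_id = cl, n_samples = ncol(members),
        stringsAsFactors = FALSE)
    }
  }
  nodes <- do.call(rbind, nodes)
  values <- do.call(cbind, vals)
  colnames(values) <- paste0(nodes$cohort_id, ":", nodes$cluster_id)
  rownames(values) <- shared
  structure(list(gene_ids = shared, values = values, nodes = nodes),
            class = "ClusterCentroids")
}

#' Cross-cohort centroid correlation network
#'
#' Connects every pair of centroids from *different* cohorts whose Pearson
#' correlation is at least `min_edge_corr`; edge weight is the correlation.
#' Same-cohort pairs are never connected.
#'
#' @param centroids a `ClusterCentroids` object from [compute_centroids()].
#' @param min_edge_corr edge inclusion threshold (default 0.5), used when
#'   `edge_gate = "threshold"`.
#' @param edge_gate `"threshold"` keeps edges with `r >= min_edge_corr`;
#'   `"permutation"` instead keeps a pair when its correlation clears an
#'   empirical null built by shuffling one centroid's gene labels
#'   (one-sided p < `perm_alpha`).
#' @param n_perm,perm_alpha,seed permutation-gate settings (1000 shuffles,
#'   alpha 0.05).
#' @return A `MetaClusterNetwork`: list with `nodes` (the centroid table),
#'   `edges` (data.frame `node_a`, `node_b`, `weight`) and `min_edge_corr`.
#' @export
build_centroid_network <- function(centroids, min_edge_corr = 0.5,
                                   edge_gate = c("threshold", "permutation"),
                                   n_perm = 1000L, perm_alpha = 0.05, seed = 1L) {
  edge_gate <- match.arg(edge_gate)
  stopifnot(inherits(centroids, "ClusterCentroids"))
  if (length(unique(centroids$nodes$cohort_id)) < 2) stopf("need centroids from >= 2 cohorts")
  sds <- apply(centroids$values, 2, sd)
  if (any(sds == 0)) stopf("zero-variance centroid(s): %s",
                           paste(colnames(centroids$values)[sds == 0], collapse = ", "))
  r <- cor(centroids$values)
  ids <- colnames(centroids$values)
  cohorts <- centroids$nodes$cohort_id
  keep_pair <- function(i, j) {
    if (edge_gate == "threshold") return(r[i, j] >= min_edge_corr)
    p <- perm_gate_p(centroids$values[, i], centroids$values[, j],
                     derive_seed(seed, 10000L * i + j), n_perm)
    p < perm_alpha
  }
  edges <- list()
  for (i in seq_len(ncol(r) - 1)) {
    for (j in seq(i + 1, ncol(r))) {
      if (cohorts[i] == cohorts[j]) next
      if (keep_pair(i, j)) {
        edges[[length(edges) + 1L]] <- data.frame(
          node_a = ids[i], node_b = ids[j], weight = r[i, j],
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(node_a = character(), node_b = character(), weight = numeric())
  structure(list(nodes = centroids$nodes, node_ids = ids, edges = edges,
                 min_edge_corr = min_edge_corr),
            class = "MetaClusterNetwork")
}

# empirical one-sided p for cor(a, b) against gene-label shuffles of b
perm_gate_p <- function(a, b, seed, n_perm) {
  r_obs <- cor(a, b)
  with_seed(seed, {
    g <- length(b)
    perms <- replicate(n_perm, b[sample.int(g)])
    r_null <- as.numeric(cor(a, perms))
    (1 + sum(r_null >= r_obs)) / (1 + n_perm)
  })
}

# one asynchronous label-propagation sweep sequence until stable
lpa_run <- function(node_ids, nbr, w, seed) {
  lab <- stats::setNames(seq_along(node_ids), node_ids)
  with_seed(seed, {
    for (sweep in seq_len(101L)) {
      changed <- FALSE
      for (v in sample(node_ids)) {
        if (!length(nbr[[v]])) next
        ws <- tapply(w[[v]], lab[nbr[[v]]], sum)
        best <- names(ws)[ws == max(ws)]
        new <- as.integer(if (length(best) > 1) sample(best, 1) else best)
        if (new != lab[[v]]) { lab[[v]] <- new; changed <- TRUE }
      }
      if (!changed) break
    }
  })
  lab
}

# canonical form: communities renumbered 1,2,... by first appearance
canonical_partition <- function(lab) {
  match(lab, unique(lab))
}

#' Label-propagation communities on the centroid network
#'
#' Asynchronous weighted label propagation: nodes start in their own
#' community and repeatedly adopt the label with the largest total edge
#' weight among neighbours until no label changes. Because plain label
#' propagation depends on visit order, `n_restarts` seeded runs are performed
#' and the most frequent canonical partition is kept (ties broken by the
#' lexicographically smallest canonical form). Isolated nodes become
#' singleton communities with a warning.
#'
#' @param network a `MetaClusterNetwork`.
#' @param seed integer seed driving visit orders and tie-breaks.
#' @param n_restarts number of seeded restarts (default 101).
#' @return named integer vector: node id -> meta-cluster id (1-based, in
#'   order of first appearance).
#' @export
label_propagation_communities <- function(network, seed = 1L, n_restarts = 101L) {
  stopifnot(inherits(network, "MetaClusterNetwork"))
  node_ids <- network$node_ids
  if (!length(node_ids)) stopf("empty network")
  nbr <- stats::setNames(vector("list", length(node_ids)), node_ids)
  w <- stats::setNames(vector("list", length(node_ids)), node_ids)
  for (e in seq_len(nrow(network$edges))) {
    a <- network$edges$node_a[e]; b <- network$edges$node_b[e]
    wt <- network$edges$weight[e]
    nbr[[a]] <- c(nbr[[a]], b); w[[a]] <- c(w[[a]], wt)
    nbr[[b]] <- c(nbr[[b]], a); w[[b]] <- c(w[[b]], wt)
  }
  isolated <- node_ids[vapply(nbr, length, integer(1)) == 0]
  if (length(isolated)) {
    warnf("%d isolated node(s) become singleton communities: %s",
          length(isolated), paste(isolated, collapse = ", "))
  }
  parts <- character(n_restarts)
  part_list <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    lab <- lpa_run(node_ids, nbr, w, derive_seed(seed, 31L * r))
    cp <- canonical_partition(lab)
    part_list[[r]] <- cp
    parts[r] <- paste(cp, collapse = ",")
  }
  freq <- table(parts)
  winners <- names(freq)[freq == max(freq)]
  winner <- sort(winners)[1]
  cp <- part_list[[match(winner, parts)]]
  stats::setNames(cp, node_ids)
}

#' Annotate meta-clusters as primitive or committed
#'
#' Scores each meta-cluster by the mean, over its member centroids, of the
#' mean z-score of the stemness signature genes. With exactly two
#' meta-clusters the higher-scoring one is labeled `primitive` and the other
#' `committed`; with more, only the two extreme-score communities are labeled
#' and the rest stay `unlabeled` with a warning. An exact score tie is an
#' error (enlarge the signature).
#'
#' @param communities named vector from [label_propagation_communities()].
#' @param centroids the `ClusterCentroids` the communities were built from.
#' @param signature character vector of stemness signature gene ids.
#' @param assignments data.frame with `cohort_id`, `sample_id`, `cluster_id`
#'   (per-sample cluster membership from the per-cohort clustering).
#' @return list with `subtype_map` (meta-cluster id -> subtype), `scores`
#'   (meta-cluster signature scores) and `assignments` (the input with
#'   `meta_cluster_id` and `subtype` columns added).
#' @export
annotate_subtypes <- function(communities, centroids, signature, assignments) {
  stopifnot(inherits(centroids, "ClusterCentroids"))
  sig <- intersect(signature, centroids$gene_ids)
  if (!length(sig)) stopf("signature shares no genes with the centroid universe")
  node_score <- colMeans(centroids$values[sig, , drop = FALSE])
  mc_ids <- sort(unique(communities))
  scores <- vapply(mc_ids, function(m) mean(node_score[names(communities)[communities == m]]),
                   numeric(1))
  names(scores) <- mc_ids
  if (anyDuplicated(round(scores, 12))) {
    stopf("exact signature-score tie between meta-clusters; supply a larger signature")
  }
  subtype_map <- stats::setNames(rep("unlabeled", length(mc_ids)), mc_ids)
  subtype_map[names(which.max(scores))] <- "primitive"
  subtype_map[names(which.min(scores))] <- "committed"
  if (length(mc_ids) > 2) {
    warnf("%d meta-clusters detected; only the extreme-score pair is labeled", length(mc_ids))
  }
  node_key <- paste0(assignments$cohort_id, ":", assignments$cluster_id)
  miss <- setdiff(unique(node_key), names(communities))
  if (length(miss)) stopf("assignment rows reference unknown cluster node(s): %s",
                          paste(miss, collapse = ", "))
  assignments$meta_cluster_id <- unname(communities[node_key])
  assignments$subtype <- unname(subtype_map[as.character(assignments$meta_cluster_id)])
  list(subtype_map = subtype_map, scores = scores, assignments = assignments)
}
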