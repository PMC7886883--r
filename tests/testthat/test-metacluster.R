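make_zm <- function(values, cohort) {
  expression_matrix(values, cohort, rownames(values), colnames(values), scale = "zscored")
}

test_that("centroids are member means on the shared gene universe", {
  set.seed(4)
  g <- sprintf("g%03d", 1:60)
  v1 <- matrix(rnorm(60 * 7), 60, 7, dimnames = list(g, paste0("a", 1:7)))
  v2 <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(g, paste0("b", 1:6)))
  zm1 <- make_zm(v1, "c1"); zm2 <- make_zm(v2, "c2")
  lab1 <- stats::setNames(c(1, 1, 1, 1, 1, 2, 2), colnames(v1))  # 5-sample + 2-sample
  lab2 <- stats::setNames(c(1, 2, 2, 2, 2, 2), colnames(v2))     # singleton + rest
  cent <- compute_centroids(list(zm1, zm2), list(lab1, lab2), min_shared = 50)
  expect_equal(cent$values[, "c1:1"], rowMeans(v1[, 1:5]))       # direct averaging
  expect_equal(cent$values[, "c1:2"], (v1[, 6] + v1[, 7]) / 2)   # two-sample midpoint
  expect_equal(cent$values[, "c2:1"], v2[, 1])                   # singleton = the sample
  expect_equal(cent$nodes$n_samples, c(5L, 2L, 1L, 5L))

  small <- make_zm(v1[1:10, ], "c1")
  expect_error(compute_centroids(list(small, small), list(lab1, lab1)), "gene counts")
})

test_that("centroid network links only sufficiently correlated cross-cohort pairs", {
  g <- sprintf("g%03d", 1:60)
  set.seed(9)
  base <- rnorm(60)
  noise <- rnorm(60)
  vals <- cbind("c1:1" = base, "c1:2" = -base,
                "c2:1" = base + 1e-8 * noise,     # r ~ 1 with c1:1
                "c2:2" = scale(noise)[, 1])
  rownames(vals) <- g
  cent <- structure(list(gene_ids = g, values = vals,
                         nodes = data.frame(cohort_id = c("c1", "c1", "c2", "c2"),
                                            cluster_id = c(1, 2, 1, 2),
                                            n_samples = c(3, 3, 3, 3))),
                    class = "ClusterCentroids")
  net <- build_centroid_network(cent, min_edge_corr = 0.5)
  key <- paste(net$edges$node_a, net$edges$node_b)
  expect_true("c1:1 c2:1" %in% key)
  expect_equal(net$edges$weight[key == "c1:1 c2:1"], 1, tolerance = 1e-6)
  # anti-correlated pair (r = -1) and sub-threshold pairs excluded
  expect_false("c1:2 c2:1" %in% key)
  # never an edge within one cohort
  expect_false(any(net$edges$node_a == "c1:1" & net$edges$node_b == "c1:2"))
  # symmetric in its arguments
  r_ab <- cor(vals[, "c1:1"], vals[, "c2:1"])
  expect_equal(r_ab, cor(vals[, "c2:1"], vals[, "c1:1"]))

  bad <- cent; bad$values[, 2] <- 1
  expect_error(build_centroid_network(bad), "zero-variance")

  # permutation gate: a genuinely correlated pair clears the empirical null,
  # an unrelated pair does not
  pnet <- build_centroid_network(cent, edge_gate = "permutation",
                                 n_perm = 200, seed = 3)
  pkey <- paste(pnet$edges$node_a, pnet$edges$node_b)
  expect_true("c1:1 c2:1" %in% pkey)
  expect_false("c1:1 c2:2" %in% pkey)
  expect_identical(pnet$edges,
                   build_centroid_network(cent, edge_gate = "permutation",
                                          n_perm = 200, seed = 3)$edges)
})

test_that("label propagation finds clique communities deterministically", {
  nodes <- c(paste0("cA", 1:4), paste0("cB", 1:4))
  cohorts <- rep(c("x", "y", "z", "w"), 2)
  clique_edges <- function(ids) {
    pairs <- t(utils::combn(ids, 2))
    data.frame(node_a = pairs[, 1], node_b = pairs[, 2], weight = 0.9,
               stringsAsFactors = FALSE)
  }
  net <- structure(list(nodes = data.frame(cohort_id = cohorts,
                                           cluster_id = rep(1:2, each = 4),
                                           n_samples = 5),
                        node_ids = nodes,
                        edges = rbind(clique_edges(nodes[1:4]), clique_edges(nodes[5:8])),
                        min_edge_corr = 0.5),
                   class = "MetaClusterNetwork")
  comm <- label_propagation_communities(net, seed = 2)
  expect_equal(length(unique(comm)), 2L)
  expect_equal(length(unique(comm[1:4])), 1L)
  expect_equal(length(unique(comm[5:8])), 1L)
  expect_identical(comm, label_propagation_communities(net, seed = 2))

  # complete equal-weight graph collapses to one community
  net1 <- net; net1$edges <- clique_edges(nodes)
  expect_equal(length(unique(label_propagation_communities(net1, seed = 2))), 1L)

  # isolated node becomes a singleton with a warning
  net2 <- net; net2$edges <- clique_edges(nodes[1:4])
  expect_warning(comm2 <- label_propagation_communities(net2, seed = 2), "isolated")
  expect_equal(length(unique(comm2[5:8])), 4L)

  # independent cross-check on the two-clique graph
  ig <- igraph::graph_from_data_frame(net$edges, directed = FALSE)
  ig_comm <- igraph::membership(igraph::cluster_label_prop(ig, weights = igraph::E(ig)$weight))
  expect_equal(length(unique(ig_comm)), 2L)
})

test_that("subtype annotation follows the planted stem signature", {
  g <- sprintf("g%03d", 1:60)
  sig <- g[1:10]
  up <- c(rep(1, 10), rep(0, 50)); down <- -up
  set.seed(1)
  vals <- cbind("c1:1" = up + rnorm(60, sd = 0.01), "c1:2" = down + rnorm(60, sd = 0.01),
                "c2:1" = up + rnorm(60, sd = 0.01), "c2:2" = down + rnorm(60, sd = 0.01))
  rownames(vals) <- g
  cent <- structure(list(gene_ids = g, values = vals,
                         nodes = data.frame(cohort_id = c("c1", "c1", "c2", "c2"),
                                            cluster_id = c(1, 2, 1, 2), n_samples = 4)),
                    class = "ClusterCentroids")
  comm <- stats::setNames(c(1L, 2L, 1L, 2L), colnames(vals))
  asg <- data.frame(cohort_id = rep(c("c1", "c2"), each = 2),
                    sample_id = paste0("s", 1:4), cluster_id = c(1, 2, 1, 2))
  ann <- annotate_subtypes(comm, cent, sig, asg)
  expect_equal(unname(ann$subtype_map[c("1", "2")]), c("primitive", "committed"))
  expect_equal(ann$assignments$subtype, c("primitive", "committed", "primitive", "committed"))

  # exact score tie -> error
  tie <- cent; tie$values[, ] <- rep(c(1, -1), each = 30)
  expect_error(annotate_subtypes(comm, tie, sig, asg), "tie")

  # three communities: middle one stays unlabeled
  vals3 <- cbind(vals[, 1:2], "c2:1" = rnorm(60, sd = 0.01), "c2:2" = vals[, 4])
  colnames(vals3) <- c("c1:1", "c1:2", "c2:1", "c2:2")
  cent3 <- cent; cent3$values <- vals3
  comm3 <- stats::setNames(c(1L, 2L, 3L, 2L), colnames(vals3))
  expect_warning(ann3 <- annotate_subtypes(comm3, cent3, sig, asg), "extreme")
  expect_equal(unname(ann3$subtype_map["3"]), "unlabeled")

  expect_error(annotate_subtypes(comm, cent, c("nope1", "nope2"), asg), "no genes")
})
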