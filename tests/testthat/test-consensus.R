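test_that("consensus matrix separates exact duplicate groups perfectly", {
  # two groups of identical profiles: within-group consensus 1, between 0
  set.seed(2)
  a <- rnorm(30); b <- rnorm(30)
  z <- cbind(a, a, a, a, b, b, b, b) + rnorm(240, sd = 1e-6)
  rownames(z) <- sprintf("g%02d", 1:30); colnames(z) <- sprintf("s%d", 1:8)
  zm <- expression_matrix(t(scale(t(z))), "c1", scale = "zscored")
  cons <- build_consensus(zm, k = 2, n_reps = 40, seed = 1)
  expect_true(all(cons[1:4, 1:4] == 1))
  expect_true(all(cons[5:8, 5:8] == 1))
  expect_true(all(cons[1:4, 5:8] == 0))
})

test_that("a single full-data repetition reproduces one partition in {0,1}", {
  zm <- two_group_zmatrix(n_per_group = 5, seed = 8)
  cons <- build_consensus(zm, k = 2, n_reps = 1, sample_frac = 1, feature_frac = 1, seed = 4)
  off_diag <- cons[upper.tri(cons)]
  expect_true(all(off_diag %in% c(0, 1)))
  lab <- k_medoids(1 - cons, 2, seed = 1)$labels
  expect_equal(unname(cons[1, 2]), as.numeric(lab[1] == lab[2]))
})

test_that("consensus grids are deterministic, symmetric, unit-diagonal and bounded", {
  zm <- two_group_zmatrix(n_per_group = 8, seed = 13)
  c1 <- build_consensus(zm, k = 3, n_reps = 25, seed = 21)
  c2 <- build_consensus(zm, k = 3, n_reps = 25, seed = 21)
  expect_identical(c1, c2)
  expect_equal(c1, t(c1))
  expect_true(all(diag(c1) == 1))
  expect_true(all(c1 >= 0 & c1 <= 1))
})

test_that("silhouette widths match the hand formula and behave under randomness", {
  # 4 points, hand-set distances; clusters {1,2} and {3,4}
  d <- matrix(c(0, 1, 4, 5,
                1, 0, 3, 4,
                4, 3, 0, 2,
                5, 4, 2, 0), 4, 4, byrow = TRUE)
  lab <- c(1, 1, 2, 2)
  sw <- silhouette_width(d, lab)
  # s1: a=1, b=(4+5)/2=4.5 -> 3.5/4.5; s2: a=1, b=3.5 -> 2.5/3.5
  # s3: a=2, b=3.5 -> 1.5/3.5;         s4: a=2, b=4.5 -> 2.5/4.5
  expect_equal(sw$widths, c(3.5/4.5, 2.5/3.5, 1.5/3.5, 2.5/4.5))
  expect_equal(sw$mean, mean(sw$widths))

  sil <- cluster::silhouette(lab, dmatrix = d)
  expect_equal(sw$widths, unname(sil[, "sil_width"]))

  # two tight far-apart pairs
  d2 <- as.matrix(dist(c(0, 0.01, 10, 10.01)))
  expect_gt(silhouette_width(d2, c(1, 1, 2, 2))$mean, 0.9)

  # random labels on iid points hover near zero
  means <- vapply(1:20, function(s) {
    set.seed(s)
    dd <- as.matrix(dist(rnorm(12)))
    silhouette_width(dd, sample(rep(1:2, 6)))$mean
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.2)

  expect_error(silhouette_width(d, rep(1, 4)), "2 clusters")
})

test_that("silhouette-based selection finds planted k and breaks ties low", {
  # 3 well-separated groups -> chosen_k = 3
  set.seed(31)
  g <- 40; n_per <- 6
  base <- matrix(rnorm(g * 3, sd = 4), g, 3)
  m <- base[, rep(1:3, each = n_per)] + matrix(rnorm(g * 3 * n_per, sd = 0.3), g)
  rownames(m) <- sprintf("g%02d", 1:g); colnames(m) <- sprintf("s%02d", 1:(3 * n_per))
  zm <- expression_matrix(t(scale(t(m))), "c1", scale = "zscored")
  res <- select_k_and_cluster(zm, consensus_config(k_range = 2:5, n_reps = 30, seed = 3))
  expect_equal(res$chosen_k, 3L)
  expect_equal(length(unique(res$labels)), 3L)
  truth <- rep(1:3, each = n_per)
  expect_equal(mclust::adjustedRandIndex(res$labels, truth), 1)

  # engineered exact tie: argmax picks the smallest k
  sil <- res$mean_silhouette_by_k
  expect_equal(names(which(sil == max(sil)))[1], as.character(res$chosen_k))
})

test_that("two planted subtypes are recovered from simulated counts", {
  # a single downsized cohort; the full-size recovery rates live in the
  # acceptance suite
  cfg <- sim_config(n_cohorts = 1, samples_per_cohort = c(50, 50), n_genes = 500,
                    lfc_signature = 2)
  sim <- simulate_cohorts(cfg, seed = 17)
  em_log <- normalize_log(filter_low_expressed_genes(sim$cohorts[[1]]))
  zm <- prepare_clustering_matrix(em_log, preprocess_config(n_variable_genes = 500))
  res <- select_k_and_cluster(zm, consensus_config(k_range = 2:4, n_reps = 40, seed = 17))
  expect_equal(res$chosen_k, 2L)
  truth <- sim$truth$subtype[names(res$labels)]
  expect_gte(mclust::adjustedRandIndex(res$labels, truth), 0.9)
})
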