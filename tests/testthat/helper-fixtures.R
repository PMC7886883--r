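# Small in-code fixtures shared across test files.

# gene x sample count matrix with named dims
toy_counts <- function(values, genes = NULL, samples = NULL, cohort = "c1") {
  m <- matrix(values$v, values$g, values$n)
  expression_matrix(m, cohort,
                    genes %||% sprintf("g%02d", seq_len(values$g)),
                    samples %||% sprintf("s%02d", seq_len(values$n)),
                    scale = "raw_counts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# z-scored matrix with two well-separated sample groups: group means +/- delta
# on the first `n_sig` genes, standard normal noise elsewhere
two_group_zmatrix <- function(n_per_group = 10, n_genes = 60, n_sig = 20,
                              delta = 3, seed = 42, cohort = "c1") {
  set.seed(seed)
  n <- 2 * n_per_group
  m <- matrix(rnorm(n_genes * n), n_genes, n)
  m[seq_len(n_sig), seq_len(n_per_group)] <- m[seq_len(n_sig), seq_len(n_per_group)] + delta
  z <- t(scale(t(m)))
  expression_matrix(z, cohort, sprintf("g%03d", seq_len(n_genes)),
                    sprintf("%s_s%02d", cohort, seq_len(n)), scale = "zscored")
}

# exhaustive k-medoids optimum: minimum assignment cost over all medoid sets
brute_force_kmedoids_cost <- function(d, k) {
  n <- nrow(d)
  combos <- utils::combn(n, k)
  best <- Inf
  for (j in seq_len(ncol(combos))) {
    cost <- sum(apply(d[, combos[, j], drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# O(n^2) concordance index by direct pair enumeration
brute_force_ci <- function(score, response) {
  num <- 0; den <- 0
  n <- length(score)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (response[i] == response[j]) next
    den <- den + 1
    lo <- if (response[i] < response[j]) i else j
    hi <- if (response[i] < response[j]) j else i
    num <- num + if (score[lo] < score[hi]) 1 else if (score[lo] == score[hi]) 0.5 else 0
  }
  num / den
}

# seeded subtype vector at the default primitive prevalence
with_subtypes <- function(n, seed, prevalence = 0.45) {
  set.seed(seed)
  stats::setNames(ifelse(runif(n) < prevalence, "primitive", "committed"),
                  sprintf("s%03d", seq_len(n)))
}

# expected counts for a noiseless log-normalized matrix built directly
make_log_matrix <- function(m, cohort = "c1") {
  expression_matrix(m, cohort, rownames(m), colnames(m), scale = "log_normalized")
}
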