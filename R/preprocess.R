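#' Preprocessing configuration
#'
#' @param max_zero_fraction genes whose zero-count fraction is strictly
#'   greater than this are removed (default 0.10, i.e. "zero in more than 10%
#'   of samples").
#' @param pseudocount added before the log2 transform (default 1).
#' @param n_variable_genes number of top-variance genes kept for clustering
#'   (default 5000; capped at the number available).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(max_zero_fraction = 0.10, pseudocount = 1,
                              n_variable_genes = 5000) {
  stopifnot(is.finite(max_zero_fraction), max_zero_fraction >= 0, max_zero_fraction <= 1,
            is.finite(pseudocount), pseudocount > 0,
            is.finite(n_variable_genes), n_variable_genes >= 2)
  structure(list(max_zero_fraction = max_zero_fraction,
                 pseudocount = pseudocount,
                 n_variable_genes = as.integer(n_variable_genes)),
            class = "preprocess_config")
}

#' Remove genes with too many zero counts
#'
#' Drops every gene whose fraction of zero-count samples is strictly greater
#' than `cfg$max_zero_fraction`; a gene with zeros in exactly that fraction is
#' kept. Gene order is preserved.
#'
#' @param em `ExpressionMatrix` with `scale = "raw_counts"`.
#' @param cfg a [preprocess_config()].
#' @return Filtered `ExpressionMatrix`, still raw counts.
#' @export
filter_low_expressed_genes <- function(em, cfg = preprocess_config()) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (em$scale != "raw_counts") stopf("zero-fraction filter expects raw counts, got '%s'", em$scale)
  zero_frac <- rowMeans(em$values == 0)
  keep <- zero_frac <= cfg$max_zero_fraction
  if (!any(keep)) {
    stopf("no gene passes the zero-fraction filter (%.0f%%); raise max_zero_fraction",
          100 * cfg$max_zero_fraction)
  }
  expression_matrix(em$values[keep, , drop = FALSE], em$cohort_id,
                    em$gene_ids[keep], em$sample_ids, scale = "raw_counts")
}

# Median-of-ratios size factors: geometric mean per gene over genes with no
# zero anywhere, then per-sample median of count/geomean. Falls back to
# library-size factors when fewer than `min_ref_genes` all-nonzero genes exist.
size_factors <- function(counts, min_ref_genes = 50L) {
  all_nonzero <- rowSums(counts == 0) == 0
  if (sum(all_nonzero) >= min_ref_genes) {
    ref <- counts[all_nonzero, , drop = FALSE]
    log_geo <- rowMeans(log(ref))
    sf <- apply(ref, 2, function(col) exp(median(log(col) - log_geo)))
  } else {
    libs <- colSums(counts)
    sf <- libs / mean(libs)
  }
  sf
}

#' Size-factor normalization and log2 transform
#'
#' Per-sample size factors are the median over all-nonzero genes of
#' count / geometric-mean-count (library-size factors when fewer than 50 such
#' genes exist); the normalized value is `log2(count / sf + pseudocount)`.
#'
#' @inheritParams filter_low_expressed_genes
#' @param min_ref_genes minimum number of all-nonzero reference genes
#'   required for median-of-ratios factors (default 50); below it the
#'   library-size fallback is used.
#' @return `ExpressionMatrix` with `scale = "log_normalized"`; the size
#'   factors are attached as attribute `"size_factors"`.
#' @export
normalize_log <- function(em, cfg = preprocess_config(), min_ref_genes = 50L) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (em$scale != "raw_counts") stopf("normalize_log expects raw counts, got '%s'", em$scale)
  if (length(em$sample_ids) < 2) stopf("need at least 2 samples")
  zero_samp <- colSums(em$values) == 0
  if (any(zero_samp)) stopf("sample(s) with all-zero counts: %s",
                            paste(em$sample_ids[zero_samp], collapse = ", "))
  sf <- size_factors(em$values, min_ref_genes)
  norm <- log2(sweep(em$values, 2, sf, "/") + cfg$pseudocount)
  out <- expression_matrix(norm, em$cohort_id, em$gene_ids, em$sample_ids,
                           scale = "log_normalized")
  attr(out, "size_factors") <- stats::setNames(sf, em$sample_ids)
  out
}

#' Build the clustering feature matrix
#'
#' Keeps the `n_variable_genes` genes with largest variance on the log scale
#' (constant genes excluded first) and z-scores each gene to mean 0, sd 1
#' across samples.
#'
#' @param em `ExpressionMatrix` with `scale = "log_normalized"`.
#' @param cfg a [preprocess_config()].
#' @return `ExpressionMatrix` with `scale = "zscored"`.
#' @export
prepare_clustering_matrix <- function(em, cfg = preprocess_config()) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (em$scale != "log_normalized") stopf("expected log-normalized input, got '%s'", em$scale)
  if (length(em$gene_ids) < 2 || length(em$sample_ids) < 3) {
    stopf("need >= 2 genes and >= 3 samples")
  }
  v <- apply(em$values, 1, var)
  nonconst <- v > 0
  if (!any(nonconst)) stopf("all genes are constant; nothing to cluster on")
  idx <- which(nonconst)
  ord <- idx[order(v[idx], decreasing = TRUE)]
  keep <- sort(ord[seq_len(min(cfg$n_variable_genes, length(ord)))])
  z <- t(scale(t(em$values[keep, , drop = FALSE])))
  expression_matrix(z, em$cohort_id, em$gene_ids[keep], em$sample_ids, scale = "zscored")
}
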