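#' Per-cohort subtype effect sizes on the log scale
#'
#' For each gene: `lfc` = mean log2 expression in primitive samples minus
#' mean in committed samples, with the Welch standard error
#' `sqrt(s1^2/n1 + s2^2/n2)`. Genes with zero variance in both groups get
#' their standard error floored at 1e-8 and are flagged.
#'
#' @param em_log `ExpressionMatrix` with `scale = "log_normalized"`.
#' @param subtypes character vector named by sample id with values
#'   `"primitive"` / `"committed"`; samples absent from it are ignored.
#' @return data.frame: `gene_id`, `lfc`, `se`, `zero_variance` (logical).
#' @export
per_cohort_effect <- function(em_log, subtypes) {
  stopifnot(inherits(em_log, "ExpressionMatrix"), em_log$scale == "log_normalized")
  subtypes <- subtypes[names(subtypes) %in% em_log$sample_ids]
  prim <- names(subtypes)[subtypes == "primitive"]
  comm <- names(subtypes)[subtypes == "committed"]
  if (length(prim) < 3 || length(comm) < 3) {
    stopf("cohort '%s': need >= 3 samples per subtype (primitive %d, committed %d)",
          em_log$cohort_id, length(prim), length(comm))
  }
  x1 <- em_log$values[, prim, drop = FALSE]
  x0 <- em_log$values[, comm, drop = FALSE]
  n1 <- length(prim); n0 <- length(comm)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  se <- sqrt(v1 / n1 + v0 / n0)
  zero_var <- se == 0
  se[zero_var] <- 1e-8
  data.frame(gene_id = em_log$gene_ids, lfc = m1 - m0, se = se,
             zero_variance = zero_var, row.names = NULL, stringsAsFactors = FALSE)
}

#' Fixed-effect inverse-variance meta-estimate
#'
#' Combines per-cohort log fold changes with weights `w_i = 1/se_i^2`:
#' the meta estimate is `sum(w * lfc) / sum(w)`, its standard error
#' `sqrt(1 / sum(w))`, `z = estimate / se`, and `p` the two-sided normal
#' tail.
#'
#' @param lfc,se numeric vectors of per-cohort effects for one gene
#'   (cohorts with the gene absent should simply be omitted).
#' @return list with `meta_estimate`, `meta_se`, `z`, `p`.
#' @export
meta_combine <- function(lfc, se) {
  stopifnot(length(lfc) == length(se), length(lfc) >= 1, all(se > 0))
  w <- 1 / se^2
  est <- sum(w * lfc) / sum(w)
  mse <- sqrt(1 / sum(w))
  z <- est / mse
  list(meta_estimate = est, meta_se = mse, z = z, p = 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (the pipeline's "FDR" convention), with input
#' order preserved and values capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Cross-cohort differential-expression table
#'
#' Runs [per_cohort_effect()] in every cohort and [meta_combine()] per gene
#' across the cohorts where the gene is present, then applies [bh_adjust()].
#' Genes absent from every cohort are dropped (count reported via message).
#'
#' @param em_log_list named list of log-normalized `ExpressionMatrix`
#'   objects.
#' @param subtypes named character vector (`sample id -> subtype`) covering
#'   all cohorts.
#' @return data.frame: `gene_id`, `lfc_<cohort>` and `se_<cohort>` per
#'   cohort, `n_cohorts`, `meta_estimate`, `meta_se`, `z`, `p`, `q`.
#' @export
run_de_meta <- function(em_log_list, subtypes) {
  stopifnot(length(em_log_list) >= 1)
  effects <- lapply(em_log_list, per_cohort_effect, subtypes = subtypes)
  cohorts <- vapply(em_log_list, `[[`, "", "cohort_id")
  genes <- unique(unlist(lapply(effects, `[[`, "gene_id")))
  lfc_mat <- matrix(NA_real_, length(genes), length(cohorts),
                    dimnames = list(genes, cohorts))
  se_mat <- lfc_mat
  for (i in seq_along(effects)) {
    lfc_mat[effects[[i]]$gene_id, i] <- effects[[i]]$lfc
    se_mat[effects[[i]]$gene_id, i] <- effects[[i]]$se
  }
  w <- 1 / se_mat^2
  w[is.na(w)] <- 0
  wsum <- rowSums(w)
  est <- rowSums(w * ifelse(is.na(lfc_mat), 0, lfc_mat)) / wsum
  mse <- sqrt(1 / wsum)
  z <- est / mse
  p <- 2 * pnorm(-abs(z))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (j in seq_along(cohorts)) {
    out[[paste0("lfc_", cohorts[j])]] <- lfc_mat[, j]
    out[[paste0("se_", cohorts[j])]] <- se_mat[, j]
  }
  out$n_cohorts <- rowSums(!is.na(lfc_mat))
  out$meta_estimate <- est
  out$meta_se <- mse
  out$z <- z
  out$p <- p
  out$q <- bh_adjust(p)
  out
}
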