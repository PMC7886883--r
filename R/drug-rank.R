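#' Concordance index between a score and a response
#'
#' Over all pairs with distinct responses, a pair is concordant (credit 1)
#' when the ordering of the scores matches the ordering of the responses,
#' discordant (credit 0) otherwise, and score ties get credit 0.5. The index
#' is total credit over comparable pairs; 0.5 means no association.
#'
#' @param score numeric vector (e.g. predicted primitive probability).
#' @param response numeric vector of the same length (e.g. `auc_d`).
#' @return concordance index in `[0, 1]`.
#' @export
concordance_index <- function(score, response) {
  keep <- is.finite(score) & is.finite(response)
  score <- score[keep]; response <- response[keep]
  if (length(score) < 2) stopf("need >= 2 usable (score, response) pairs")
  comp <- outer(response, response, "<")         # response_i < response_j
  n_comp <- sum(comp)
  if (n_comp == 0) stopf("all responses tied; no comparable pairs")
  s_lt <- outer(score, score, "<")
  s_eq <- outer(score, score, "==")
  credit <- sum(s_lt & comp) + 0.5 * sum(s_eq & comp)
  credit / n_comp
}

#' Rank drugs by subtype-association of their response
#'
#' For every drug, computes the concordance index between the per-line
#' predicted primitive probability and the drug's `auc_d`, a two-sided
#' permutation p-value (`p = (1 + #{|ci_perm - 0.5| >= |ci_obs - 0.5|}) /
#' (1 + n_perm)` over seeded shuffles of the probability vector), and BH
#' q-values across drugs. Drugs are ranked by ascending q, then by
#' descending `|ci - 0.5|`, then by drug id. `ci < 0.5` means higher
#' primitive probability goes with lower viability AUC, i.e.
#' `sensitive_in_primitive`.
#'
#' @param probabilities named numeric vector: cell line -> primitive
#'   probability.
#' @param auc_table data.frame with `sample_id`, `drug_id`, `auc_d`
#'   (one row per line x drug, e.g. from [fit_hill_table()]).
#' @param n_perm permutations per drug (default 1000).
#' @param seed permutation seed.
#' @param min_lines minimum screened lines per drug (default 10).
#' @return data.frame: `drug_id`, `ci`, `n`, `p`, `q`, `direction`, `rank`,
#'   ordered by rank.
#' @export
rank_drugs <- function(probabilities, auc_table, n_perm = 1000L, seed = 1L,
                       min_lines = 10L) {
  stopifnot(all(c("sample_id", "drug_id", "auc_d") %in% colnames(auc_table)))
  drugs <- sort(unique(auc_table$drug_id))
  if (length(drugs) < 2) stopf("need >= 2 drugs to rank")
  rows <- vector("list", length(drugs))
  for (d in seq_along(drugs)) {
    sub <- auc_table[auc_table$drug_id == drugs[d], ]
    sub <- sub[sub$sample_id %in% names(probabilities), ]
    if (nrow(sub) < min_lines) {
      stopf("drug '%s' screened on %d lines (< %d)", drugs[d], nrow(sub), min_lines)
    }
    prob <- probabilities[sub$sample_id]
    resp <- sub$auc_d
    ci <- concordance_index(prob, resp)
    # permutation null: fixed comparable pairs, shuffled scores
    comp <- which(outer(resp, resp, "<"), arr.ind = TRUE)
    n_comp <- nrow(comp)
    perm_ci <- with_seed(derive_seed(seed, d), {
      P <- replicate(n_perm, sample(prob))
      Pi <- P[comp[, 1], , drop = FALSE]
      Pj <- P[comp[, 2], , drop = FALSE]
      (colSums(Pi < Pj) + 0.5 * colSums(Pi == Pj)) / n_comp
    })
    p <- (1 + sum(abs(perm_ci - 0.5) >= abs(ci - 0.5))) / (1 + n_perm)
    rows[[d]] <- data.frame(
      drug_id = drugs[d], ci = ci, n = nrow(sub), p = p,
      direction = if (ci < 0.5) "sensitive_in_primitive" else "resistant_in_primitive",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$q, -abs(out$ci - 0.5), out$drug_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("drug_id", "ci", "n", "p", "q", "direction", "rank")]
}
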