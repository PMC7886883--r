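#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction. The reported statistic is the rank sum of `x` in the pooled
#' sample (midranks for ties).
#'
#' @param x,y numeric samples, each non-empty.
#' @param mode `"auto"` (default switch described above), `"exact"`, or
#'   `"normal"`.
#' @return list with `statistic` (rank sum of x) and `p` (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
                  auto = (length(x) + length(y) <= 12) && !ties,
                  exact = TRUE,
                  normal = FALSE)
  if (exact && ties) stopf("exact mode is not available with ties")
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE,
                                     alternative = "two.sided"))
  rank_sum <- sum(rank(c(x, y))[seq_along(x)])
  list(statistic = rank_sum, p = unname(ht$p.value))
}

#' Kaplan-Meier survival curve for one group
#'
#' Product-limit estimator; censored times do not drop the curve, which
#' starts at 1.
#'
#' @param time event/censoring times in days (>= 0).
#' @param event 1 = event, 0 = censored.
#' @return data.frame: `time`, `n_risk`, `n_event`, `surv` (step-function
#'   values after each observed time).
#' @export
km_curve <- function(time, event) {
  if (any(time < 0)) stopf("negative survival time")
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Log-rank test between two subtype groups
#'
#' Standard observed-minus-expected log-rank statistic with hypergeometric
#' variance, referred to a chi-square with 1 degree of freedom.
#'
#' @param time,event as in [km_curve()].
#' @param group two-level factor/character (e.g. primitive vs committed).
#' @return list with `chisq`, `p`, `df = 1`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) != 2 || any(table(group) == 0)) stopf("need two non-empty groups")
  if (sum(event) == 0) stopf("no events; log-rank undefined")
  if (any(time < 0)) stopf("negative survival time")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chisq = unname(sd$chisq), p = pchisq(sd$chisq, df = 1, lower.tail = FALSE), df = 1L)
}

#' Matthews correlation coefficient between two binary vectors
#'
#' Pairs with a missing value in either vector are dropped first. Errors if
#' either remaining vector is constant (a zero margin leaves the MCC
#' undefined).
#'
#' @param binary_a,binary_b 0/1 vectors of equal length (NA = missing).
#' @return list with `mcc` and `contingency` (2 x 2 table, rows = a,
#'   cols = b).
#' @export
matthews_cc <- function(binary_a, binary_b) {
  stopifnot(length(binary_a) == length(binary_b))
  keep <- !is.na(binary_a) & !is.na(binary_b)
  a <- binary_a[keep]; b <- binary_b[keep]
  stopifnot(all(a %in% c(0, 1)), all(b %in% c(0, 1)))
  if (length(unique(a)) < 2 || length(unique(b)) < 2) {
    stopf("constant vector: MCC undefined (zero margin)")
  }
  tp <- as.numeric(sum(a == 1 & b == 1)); tn <- as.numeric(sum(a == 0 & b == 0))
  fp <- as.numeric(sum(a == 1 & b == 0)); fn <- as.numeric(sum(a == 0 & b == 1))
  mcc <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  list(mcc = mcc, contingency = matrix(c(tn, fn, fp, tp), 2, 2,
                                       dimnames = list(a = c(0, 1), b = c(0, 1))))
}

#' Area under the precision-recall curve
#'
#' Thresholds descend through the distinct score values (ties grouped);
#' the area uses the step-wise (rectangular) rule
#' `sum((recall_i - recall_{i-1}) * precision_i)`.
#'
#' @param scores numeric predictor.
#' @param labels 0/1 outcome with both classes present.
#' @return AUPRC in (0, 1].
#' @export
au_prc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2) stopf("both label values must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_recall <- 0; area <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    precision <- tp / sum(sel)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

#' Per-mutation association with the subtype
#'
#' For every mutation flag column in the metadata, computes the MCC between
#' the flag and the primitive indicator and the AUPRC of the flag as a
#' predictor of the primitive subtype, dropping unassayed samples per flag.
#'
#' @param metadata data.frame from [read_sample_metadata()] (or equivalent).
#' @param assignments data.frame with `sample_id` and `subtype`.
#' @return data.frame: `mutation`, `n`, `mcc`, `auprc`.
#' @export
mutation_subtype_association <- function(metadata, assignments) {
  stopifnot(all(c("sample_id", "subtype") %in% colnames(assignments)))
  merged <- merge(metadata, assignments[, c("sample_id", "subtype")], by = "sample_id")
  prim <- as.integer(merged$subtype == "primitive")
  mut_cols <- setdiff(colnames(metadata),
                      c("sample_id", "cohort_id", "os_time", "os_event"))
  rows <- lapply(mut_cols, function(m) {
    keep <- !is.na(merged[[m]])
    flag <- merged[[m]][keep]; y <- prim[keep]
    if (length(unique(flag)) < 2 || length(unique(y)) < 2) {
      return(data.frame(mutation = m, n = sum(keep), mcc = NA_real_, auprc = NA_real_))
    }
    data.frame(mutation = m, n = sum(keep),
               mcc = matthews_cc(flag, y)$mcc,
               auprc = au_prc(flag, y), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
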