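# exact two-sided rank-sum p by enumerating all C(n, nx) group assignments
enumerate_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  obs <- sum(rank(pooled)[seq_len(nx)])
  null_mean <- nx * (n + 1) / 2
  combos <- utils::combn(n, nx)
  stats <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]))
  mean(abs(stats - null_mean) >= abs(obs - null_mean) - 1e-9)
}

test_that("exact Wilcoxon matches full enumeration", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  res <- wilcoxon_rank_sum(x, y)
  expect_equal(res$statistic, 6)              # ranks 1+2+3
  expect_equal(res$p, 2 / 20)                 # 2 of C(6,3)=20 assignments as extreme
  expect_equal(res$p, enumerate_wilcoxon_p(x, y))

  # full sweep: every two-group split of n <= 8 distinct values
  vals <- c(0.3, 1.1, 2.7, 3.1, 4.9, 5.2, 6.8, 7.5)
  for (n in 4:8) {
    v <- vals[seq_len(n)]
    for (nx in 2:(n - 2)) {
      combos <- utils::combn(n, nx)
      for (j in seq_len(min(ncol(combos), 12))) {
        xx <- v[combos[, j]]; yy <- v[-combos[, j]]
        expect_equal(wilcoxon_rank_sum(xx, yy)$p, enumerate_wilcoxon_p(xx, yy),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("Wilcoxon approximate mode is symmetric and near 1 under identity", {
  set.seed(2)
  x <- rnorm(30); y <- rnorm(25)
  expect_equal(wilcoxon_rank_sum(x, y)$p, wilcoxon_rank_sum(y, x)$p)
  same <- wilcoxon_rank_sum(x, x, mode = "normal")
  expect_gte(same$p, 0.99)
  expect_equal(same$statistic, sum(rank(c(x, x))[1:30]))
  expect_error(wilcoxon_rank_sum(numeric(0), y), "non-empty")
  expect_error(wilcoxon_rank_sum(c(1, 1, 2), c(2, 3), mode = "exact"), "ties")
})

test_that("Kaplan-Meier estimates follow the product-limit formula", {
  # all censored: flat at 1
  km0 <- km_curve(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  # n = 4, one event at t = 10
  km1 <- km_curve(c(10, 12, 14, 16), c(1, 0, 0, 0))
  expect_equal(km1$surv[km1$time == 10], 3 / 4)

  # 6-record mixed example, hand product of (1 - d/n):
  # events at 2 (n=6), 4 (n=4, after censor at 3), 7 (n=2, after censor at 5)
  km2 <- km_curve(c(2, 3, 4, 5, 7, 8), c(1, 0, 1, 0, 1, 0))
  expect_equal(km2$surv[km2$time == 2], 5 / 6)
  expect_equal(km2$surv[km2$time == 4], 5 / 6 * 3 / 4)
  expect_equal(km2$surv[km2$time == 7], 5 / 6 * 3 / 4 * 1 / 2)
  expect_true(all(diff(km2$surv) <= 0))      # non-increasing

  expect_error(km_curve(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank test matches the O-E / V table walk and its invariances", {
  # identical groups: statistic 0, p = 1
  t0 <- c(3, 5, 8, 12); e0 <- c(1, 1, 0, 1)
  same <- logrank_test(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 4))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  # 8-record example: hand O-E and hypergeometric variance per event time
  tm <- c(1, 2, 3, 4, 5, 6, 7, 8)
  ev <- c(1, 1, 1, 0, 1, 1, 0, 1)
  gr <- c("a", "b", "a", "a", "b", "a", "b", "b")
  got <- logrank_test(tm, ev, gr)
  oe <- 0; v <- 0
  at_risk <- function(t) which(tm >= t)
  for (t in tm[ev == 1]) {
    r <- at_risk(t); n <- length(r); n1 <- sum(gr[r] == "a")
    d <- 1
    o1 <- as.numeric(ev[tm == t] == 1 && gr[tm == t] == "a")
    oe <- oe + o1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(got$chisq, oe^2 / v, tolerance = 1e-10)

  # invariance to relabeling and to a common monotone time transform
  swapped <- logrank_test(tm, ev, ifelse(gr == "a", "b", "a"))
  expect_equal(got$chisq, swapped$chisq)
  mono <- logrank_test(sqrt(tm), ev, gr)
  expect_equal(got$chisq, mono$chisq)

  expect_error(logrank_test(tm, rep(0, 8), gr), "no events")
})

test_that("MCC matches the closed formula on hand tables", {
  a <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_equal(matthews_cc(a, a)$mcc, 1)
  expect_equal(matthews_cc(a, 1 - a)$mcc, -1)

  # TP=4, FP=2, FN=1, TN=3
  pred <- c(rep(1, 6), rep(0, 4))
  truth <- c(rep(1, 4), 0, 0, 1, 0, 0, 0)
  got <- matthews_cc(pred, truth)
  expect_equal(got$mcc, (4 * 3 - 2 * 1) / sqrt(6 * 5 * 5 * 4))
  expect_equal(sum(got$contingency), 10)

  # missing pairs dropped first
  predNA <- pred; predNA[1] <- NA
  expect_equal(sum(matthews_cc(predNA, truth)$contingency), 9)
  expect_error(matthews_cc(rep(1, 4), c(0, 1, 0, 1)), "constant")
})

test_that("AUPRC follows the step-wise rule", {
  # perfect ranking
  expect_equal(au_prc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)

  # 4-item toy: thresholds walked by hand
  # scores desc: 0.9(+), 0.7(-), 0.5(+), 0.3(-)
  # t=0.9: P=1, R=1/2 -> area 1/2
  # t=0.7: R unchanged -> no area
  # t=0.5: P=2/3, R=1 -> area (1/2)(2/3)
  got <- au_prc(c(0.9, 0.7, 0.5, 0.3), c(1, 0, 1, 0))
  expect_equal(got, 0.5 + 0.5 * 2 / 3)

  # reversed perfect ranking: minimum for this prevalence, below prevalence + 0.01
  rev_auprc <- au_prc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_lt(rev_auprc, 0.5 + 0.01)

  # tied scores are grouped at one threshold
  tied <- au_prc(c(0.5, 0.5, 0.1), c(1, 0, 0))
  expect_equal(tied, 0.5)

  expect_error(au_prc(1:3, c(1, 1, 1)), "both label")
})

test_that("per-mutation association table handles unassayed samples", {
  md <- data.frame(sample_id = paste0("s", 1:8), cohort_id = "c1",
                   FLT3_ITD = c(1, 1, 1, 0, 0, 0, NA, NA),
                   DNMT3A = c(0, 0, 1, 1, 1, 0, 1, 0))
  asg <- data.frame(sample_id = paste0("s", 1:8),
                    subtype = rep(c("primitive", "committed"), each = 4))
  tab <- mutation_subtype_association(md, asg)
  expect_equal(tab$n[tab$mutation == "FLT3_ITD"], 6L)
  expect_equal(tab$n[tab$mutation == "DNMT3A"], 8L)
  flt3 <- matthews_cc(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 1, 0, 0))$mcc
  expect_equal(tab$mcc[tab$mutation == "FLT3_ITD"], flt3)
})
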