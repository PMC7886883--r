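small_cfg <- function(...) {
  sim_config(n_cohorts = 2, samples_per_cohort = c(30, 40), n_genes = 300, ...)
}

test_that("the generator is deterministic and internally consistent", {
  a <- simulate_cohorts(small_cfg(), seed = 9)
  b <- simulate_cohorts(small_cfg(), seed = 9)
  expect_identical(a, b)
  c <- simulate_cohorts(small_cfg(), seed = 10)
  expect_false(identical(a$cohorts[[1]]$values, c$cohorts[[1]]$values))

  # emitted data validate against the type invariants
  for (em in a$cohorts) {
    expect_s3_class(em, "ExpressionMatrix")
    expect_true(all(em$values >= 0 & is.finite(em$values)))
  }
  expect_equal(nrow(a$metadata), sum(vapply(a$cohorts, function(e) length(e$sample_ids), 1L)))
  # truth suffices to recompute the planted lfc without re-simulation
  expect_true(all(a$truth$true_lfc[a$truth$stem_up] == a$truth$config$lfc_signature))
  expect_true(all(a$truth$true_lfc[a$truth$committed_up] == -a$truth$config$lfc_signature))
  expect_true(all(a$truth$true_lfc[setdiff(names(a$truth$true_lfc),
                                           c(a$truth$stem_up, a$truth$committed_up))] == 0))
})

test_that("a null generator yields null effect estimates", {
  cfg <- sim_config(n_cohorts = 1, samples_per_cohort = c(200, 200), n_genes = 300,
                    lfc_signature = 0)
  sim <- simulate_cohorts(cfg, seed = 4)
  em_log <- normalize_log(filter_low_expressed_genes(sim$cohorts[[1]]))
  eff <- per_cohort_effect(em_log, sim$truth$subtype)
  # estimates center on zero; their spread is the sampling noise of the
  # negative-binomial log scale at ~100 samples per arm
  expect_lt(abs(mean(eff$lfc)), 0.02)
  expect_lt(mean(abs(eff$lfc)), 0.1)
  expect_lt(mean(eff$se < abs(eff$lfc) / 3), 0.05)   # |lfc| rarely exceeds 3 se
})

test_that("planted stem genes rise in primitive samples in every cohort", {
  sim <- simulate_cohorts(small_cfg(), seed = 21)
  for (em in sim$cohorts) {
    zm <- prepare_clustering_matrix(normalize_log(filter_low_expressed_genes(em)),
                                    preprocess_config(n_variable_genes = 300))
    stem <- intersect(sim$truth$stem_up, zm$gene_ids)
    prim <- names(sim$truth$subtype[zm$sample_ids])[sim$truth$subtype[zm$sample_ids] == "primitive"]
    comm <- setdiff(zm$sample_ids, prim)
    expect_gt(mean(zm$values[stem, prim]), mean(zm$values[stem, comm]))
  }
})

test_that("the mutation flag lands near its target association", {
  cfg <- sim_config(n_cohorts = 5, samples_per_cohort = c(150, 150), n_genes = 50)
  sim <- simulate_cohorts(cfg, seed = 2)
  prim <- as.integer(sim$truth$subtype[sim$metadata$sample_id] == "primitive")
  mcc <- matthews_cc(sim$metadata$FLT3_ITD, prim)$mcc
  expect_equal(mcc, 0.32, tolerance = 0.2)   # stochastic, n = 750
  expect_error(sim_config(mutation_mcc_target = 2) |> simulate_cohorts(seed = 1),
               "infeasible")
})

test_that("cell-line panel plants the dose-response structure it promises", {
  cfg <- small_cfg(n_cell_lines = 50, n_drugs = 4, n_active_drugs = 1)
  sim <- simulate_cohorts(cfg, seed = 6)
  panel <- simulate_cellline_panel(sim$truth, cfg, seed = 6)
  drc <- panel$dose_response
  one <- drc[drc$sample_id == "line001" & drc$drug_id == "drug01", ]
  expect_equal(nrow(one), 30L)                       # 10 doses x 3 replicates
  expect_equal(length(unique(one$concentration_uM)), 10L)

  curves <- fit_hill_table(drc)
  st <- panel$line_subtype[curves$sample_id]
  gap <- function(d) {
    sub <- curves$drug_id == d
    mean(curves$auc_d[sub & st == "primitive"]) - mean(curves$auc_d[sub & st == "committed"])
  }
  expect_equal(gap("drug01"), cfg$drug_effect, tolerance = 0.07)  # active
  expect_equal(gap("drug03"), 0, tolerance = 0.07)                # inactive
  expect_true(all(panel$drug_truth$active == c(TRUE, FALSE, FALSE, FALSE)))
})

test_that("survival simulation respects hazard ratio and censoring controls", {
  subtype <- stats::setNames(rep(c("primitive", "committed"), 75), sprintf("s%03d", 1:150))
  cfg <- sim_config(hr_subtype = 2.2)
  surv <- simulate_survival(subtype, cfg, seed = 3)
  expect_equal(mean(surv$event == 0), cfg$censor_frac, tolerance = 0.1)
  # primitive curve sits below committed at median follow-up
  med <- median(surv$time)
  s_at <- function(g) {
    km <- km_curve(surv$time[surv$group == g], surv$event[surv$group == g])
    tail(km$surv[km$time <= med], 1)
  }
  expect_lt(s_at("primitive"), s_at("committed"))

  none <- simulate_survival(subtype, sim_config(censor_frac = 0), seed = 3)
  expect_true(all(none$event == 1))

  # null hazard ratio: log-rank holds its size (cheap 20-seed check)
  hits <- 0
  for (s in 1:20) {
    sv <- simulate_survival(subtype, sim_config(hr_subtype = 1), seed = s)
    if (logrank_test(sv$time, sv$event, sv$group)$p < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 3)
})
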