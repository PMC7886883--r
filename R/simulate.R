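#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is exercised under:
#' five cohorts of 60-100 samples, 2000 genes of which 10% are
#' subtype-informative at one log2 unit (half of them the "stem" signature,
#' up in the primitive subtype), negative-binomial counts with dispersion
#' 0.2, per-(cohort, gene) batch shifts of sd 0.3 log2 units, primitive
#' prevalence 0.45, a FLT3-ITD-like mutation flag targeting MCC 0.32 with
#' the subtype, a 60-line cell panel screened with 20 drugs of which 3 shift
#' `auc_d` by -0.25 in primitive-like lines, and subtype survival hazard
#' ratio 2.2 with 20% censoring.
#'
#' @param n_cohorts number of patient cohorts.
#' @param samples_per_cohort inclusive range the per-cohort sample count is
#'   drawn from.
#' @param n_genes genes per cohort.
#' @param frac_signature fraction of genes that are subtype-informative.
#' @param lfc_signature planted log2 fold change (primitive vs committed).
#' @param nb_dispersion negative-binomial dispersion (`size = 1/dispersion`).
#' @param batch_sd sd of per-(cohort, gene) log2 batch shifts.
#' @param prevalence_primitive P(primitive) per sample.
#' @param mutation_mcc_target expected MCC of the FLT3-ITD-like flag vs the
#'   subtype.
#' @param mutation_prevalence overall frequency of the flag.
#' @param n_cell_lines,n_drugs,n_active_drugs cell-line panel dimensions.
#' @param drug_effect planted `auc_d` shift in primitive-like lines for
#'   active drugs.
#' @param ec50_range,hill_range dose-response parameter ranges (uM; unitless).
#' @param dose_range tested concentration range in uM (10 log-spaced doses).
#' @param hr_subtype survival hazard ratio, primitive vs committed.
#' @param censor_frac expected fraction of censored records.
#' @param baseline_median_days median overall survival of the committed
#'   group (days).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 5L, samples_per_cohort = c(60L, 100L),
                       n_genes = 2000L, frac_signature = 0.10,
                       lfc_signature = 1.0, nb_dispersion = 0.2,
                       batch_sd = 0.3, prevalence_primitive = 0.45,
                       mutation_mcc_target = 0.32, mutation_prevalence = 0.35,
                       n_cell_lines = 60L, n_drugs = 20L, n_active_drugs = 3L,
                       drug_effect = -0.25, ec50_range = c(0.05, 5),
                       hill_range = c(0.7, 2.5), dose_range = c(0.005, 50),
                       hr_subtype = 2.2, censor_frac = 0.2,
                       baseline_median_days = 730) {
  stopifnot(frac_signature >= 0, frac_signature <= 1,
            prevalence_primitive > 0, prevalence_primitive < 1,
            censor_frac >= 0, censor_frac < 1,
            n_active_drugs <= n_drugs, ec50_range[1] > 0, dose_range[1] > 0)
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              samples_per_cohort = as.integer(samples_per_cohort),
              n_genes = as.integer(n_genes), frac_signature = frac_signature,
              lfc_signature = lfc_signature, nb_dispersion = nb_dispersion,
              batch_sd = batch_sd, prevalence_primitive = prevalence_primitive,
              mutation_mcc_target = mutation_mcc_target,
              mutation_prevalence = mutation_prevalence,
              n_cell_lines = as.integer(n_cell_lines), n_drugs = as.integer(n_drugs),
              n_active_drugs = as.integer(n_active_drugs), drug_effect = drug_effect,
              ec50_range = ec50_range, hill_range = hill_range,
              dose_range = dose_range, hr_subtype = hr_subtype,
              censor_frac = censor_frac, baseline_median_days = baseline_median_days)
  class(cfg) <- "sim_config"
  cfg
}

# conditional flag probabilities hitting an expected phi (= MCC) between the
# flag and the subtype given subtype prevalence p and flag prevalence f:
# phi = (a - b) sqrt(p (1 - p)) / sqrt(f (1 - f)) with p a + (1 - p) b = f.
mutation_design <- function(mcc, p, f) {
  d <- mcc * sqrt(f * (1 - f)) / sqrt(p * (1 - p))
  a <- f + (1 - p) * d
  b <- f - p * d
  if (a < 0 || a > 1 || b < 0 || b > 1) {
    stopf("MCC target %.2f infeasible at prevalence %.2f / flag frequency %.2f", mcc, p, f)
  }
  c(primitive = a, committed = b)
}

# log2 expression mean per (gene, sample): baseline + subtype effect
subtype_effect_matrix <- function(truth_genes, subtype, n_genes) {
  eff <- matrix(0, n_genes, length(subtype))
  half <- truth_genes$lfc_signature / 2
  prim <- subtype == "primitive"
  eff[truth_genes$stem_up, prim] <- half
  eff[truth_genes$stem_up, !prim] <- -half
  eff[truth_genes$committed_up, prim] <- -half
  eff[truth_genes$committed_up, !prim] <- half
  eff
}

#' Simulate a multi-cohort patient compendium with planted subtypes
#'
#' Per gene, a baseline log2 mean is drawn from Uniform(3, 10); signature
#' genes receive a +/- `lfc_signature / 2` subtype effect (stem genes up in
#' primitive, the other half up in committed); every (cohort, gene) gets an
#' additive Normal(0, `batch_sd`) log2 batch shift; counts are negative
#' binomial with mean `2^(log2 mean)` and `size = 1 / nb_dispersion`.
#' A FLT3-ITD-like mutation flag is sampled per subtype so its expected MCC
#' with the subtype equals `mutation_mcc_target`.
#'
#' @param cfg a [sim_config()].
#' @param seed master seed; all draws are derived from it.
#' @return list with `cohorts` (list of raw-count `ExpressionMatrix`),
#'   `metadata` (data.frame `sample_id`, `cohort_id`, `FLT3_ITD`, `os_time`,
#'   `os_event`), and `truth` (subtypes, signature gene ids, per-gene true
#'   lfc, batch shifts, baseline means, config, seed).
#' @export
simulate_cohorts <- function(cfg = sim_config(), seed = 1L) {
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  truth <- with_seed(derive_seed(seed, 1L), {
    n_sig <- round(cfg$frac_signature * cfg$n_genes)
    sig <- sample.int(cfg$n_genes, n_sig)
    stem_up <- sort(sig[seq_len(floor(n_sig / 2))])
    committed_up <- sort(sig[-seq_len(floor(n_sig / 2))])
    list(baseline_log2 = runif(cfg$n_genes, 3, 10),
         stem_up = stem_up, committed_up = committed_up,
         lfc_signature = cfg$lfc_signature)
  })
  true_lfc <- numeric(cfg$n_genes)
  true_lfc[truth$stem_up] <- cfg$lfc_signature
  true_lfc[truth$committed_up] <- -cfg$lfc_signature
  pflag <- mutation_design(cfg$mutation_mcc_target, cfg$prevalence_primitive,
                           cfg$mutation_prevalence)
  cohorts <- vector("list", cfg$n_cohorts)
  meta <- list(); subtype_all <- character(); batch <- list()
  for (ci in seq_len(cfg$n_cohorts)) {
    cohort_id <- sprintf("cohort%d", ci)
    out <- with_seed(derive_seed(seed, 100L + ci), {
      rng <- cfg$samples_per_cohort
      n <- rng[1] + sample.int(rng[2] - rng[1] + 1, 1) - 1
      subtype <- ifelse(runif(n) < cfg$prevalence_primitive, "primitive", "committed")
      shift <- rnorm(cfg$n_genes, 0, cfg$batch_sd)
      eff <- subtype_effect_matrix(truth, subtype, cfg$n_genes)
      mu <- 2^(truth$baseline_log2 + shift + eff)
      counts <- matrix(rnbinom(cfg$n_genes * n, mu = mu, size = 1 / cfg$nb_dispersion),
                       cfg$n_genes, n)
      flag <- rbinom(n, 1, pflag[subtype])
      list(n = n, subtype = subtype, shift = shift, counts = counts, flag = flag)
    })
    sample_ids <- sprintf("%s_s%03d", cohort_id, seq_len(out$n))
    cohorts[[ci]] <- expression_matrix(out$counts, cohort_id, genes, sample_ids,
                                       scale = "raw_counts")
    names(out$subtype) <- sample_ids
    subtype_all <- c(subtype_all, out$subtype)
    batch[[cohort_id]] <- out$shift
    meta[[ci]] <- data.frame(sample_id = sample_ids, cohort_id = cohort_id,
                             FLT3_ITD = out$flag, os_time = NA_real_,
                             os_event = NA_integer_, stringsAsFactors = FALSE)
  }
  names(cohorts) <- vapply(cohorts, `[[`, "", "cohort_id")
  list(cohorts = cohorts, metadata = do.call(rbind, meta),
       truth = list(subtype = subtype_all,
                    stem_up = genes[truth$stem_up],
                    committed_up = genes[truth$committed_up],
                    true_lfc = stats::setNames(true_lfc, genes),
                    baseline_log2 = stats::setNames(truth$baseline_log2, genes),
                    batch_shifts = batch, flag_probs = pflag,
                    config = cfg, seed = seed))
}

# normalized Hill AUC over [u1, u2] as a function of m = log10(EC50)
auc_of_m <- function(m, h, u1, u2) {
  (hill_antideriv(u2, m, h) - hill_antideriv(u1, m, h)) / (u2 - u1)
}

# EC50 midpoint m' such that the curve's normalized AUC hits `target`
solve_m_for_auc <- function(target, h, u1, u2) {
  target <- min(max(target, 0.02), 0.98)
  uniroot(function(m) auc_of_m(m, h, u1, u2) - target,
          lower = u1 - 8, upper = u2 + 8, tol = 1e-10)$root
}

#' Simulate the cell-line transfer panel with planted drug effects
#'
#' Cell-line expression follows the same subtype model as the patient
#' cohorts (own batch shift). Each of `n_drugs` drugs gets one Hill
#' coefficient and per-line EC50s drawn log-uniformly; for the
#' `n_active_drugs` active drugs, the EC50 of primitive-like lines is moved
#' so the line's closed-form `auc_d` drops by exactly `drug_effect`
#' (clamped to [0.02, 0.98]). Viabilities are Hill-curve values plus
#' Normal(0, 0.05) noise (floored at 0) at 10 log-spaced doses in
#' triplicate.
#'
#' @param truth the `truth` element of [simulate_cohorts()] output.
#' @param cfg a [sim_config()].
#' @param seed master seed.
#' @return list with `expression` (raw-count `ExpressionMatrix`, cohort id
#'   `"celllines"`), `dose_response` (long data.frame), `line_subtype`
#'   (named vector) and `drug_truth` (data.frame `drug_id`, `active`,
#'   `effect`, `hill`).
#' @export
simulate_cellline_panel <- function(truth, cfg = truth$config, seed = 1L) {
  genes <- names(truth$true_lfc)
  n <- cfg$n_cell_lines
  gen <- with_seed(derive_seed(seed, 7001L), {
    subtype <- ifelse(runif(n) < cfg$prevalence_primitive, "primitive", "committed")
    shift <- rnorm(cfg$n_genes, 0, cfg$batch_sd)
    tg <- list(stem_up = match(truth$stem_up, genes),
               committed_up = match(truth$committed_up, genes),
               lfc_signature = cfg$lfc_signature)
    eff <- subtype_effect_matrix(tg, subtype, cfg$n_genes)
    mu <- 2^(truth$baseline_log2 + shift + eff)
    counts <- matrix(rnbinom(cfg$n_genes * n, mu = mu, size = 1 / cfg$nb_dispersion),
                     cfg$n_genes, n)
    list(subtype = subtype, counts = counts)
  })
  line_ids <- sprintf("line%03d", seq_len(n))
  em <- expression_matrix(gen$counts, "celllines", genes, line_ids, scale = "raw_counts")
  line_subtype <- stats::setNames(gen$subtype, line_ids)

  doses <- 10^seq(log10(cfg$dose_range[1]), log10(cfg$dose_range[2]), length.out = 10)
  u1 <- log10(min(doses)); u2 <- log10(max(doses))
  drug_ids <- sprintf("drug%02d", seq_len(cfg$n_drugs))
  drc <- list(); drug_truth <- list()
  for (di in seq_len(cfg$n_drugs)) {
    active <- di <= cfg$n_active_drugs
    rec <- with_seed(derive_seed(seed, 8000L + di), {
      h <- runif(1, cfg$hill_range[1], cfg$hill_range[2])
      # active drugs draw baseline EC50 from the top decade so the planted
      # auc_d drop never clips at the sensitive end
      lo <- if (active) cfg$ec50_range[2] / 10 else cfg$ec50_range[1]
      m <- runif(n, log10(lo), log10(cfg$ec50_range[2]))
      if (active) {
        prim <- which(line_subtype == "primitive")
        for (i in prim) {
          m[i] <- solve_m_for_auc(auc_of_m(m[i], h, u1, u2) + cfg$drug_effect, h, u1, u2)
        }
      }
      viab <- vapply(seq_len(n), function(i) hill_viability(doses, 10^m[i], h), numeric(10))
      reps <- lapply(1:3, function(r) pmax(viab + rnorm(length(viab), 0, 0.05), 0))
      list(h = h, reps = reps)
    })
    for (r in 1:3) {
      drc[[length(drc) + 1L]] <- data.frame(
        sample_id = rep(line_ids, each = 10), drug_id = drug_ids[di],
        concentration_uM = rep(doses, n), viability = as.vector(rec$reps[[r]]),
        replicate = r, stringsAsFactors = FALSE)
    }
    drug_truth[[di]] <- data.frame(drug_id = drug_ids[di], active = active,
                                   effect = if (active) cfg$drug_effect else 0,
                                   hill = rec$h, stringsAsFactors = FALSE)
  }
  list(expression = em, dose_response = do.call(rbind, drc),
       line_subtype = line_subtype, drug_truth = do.call(rbind, drug_truth))
}

#' Simulate subtype-dependent overall survival
#'
#' Exponential event times with hazard `h0 = log(2) / baseline_median_days`
#' for committed samples and `h0 * hr_subtype` for primitive samples;
#' independent Uniform(0, tau) censoring with tau solved so the expected
#' censored fraction equals `censor_frac`.
#'
#' @param subtypes named character vector, sample id -> subtype.
#' @param cfg a [sim_config()].
#' @param seed master seed.
#' @return data.frame: `sample_id`, `time` (days), `event`, `group`.
#' @export
simulate_survival <- function(subtypes, cfg = sim_config(), seed = 1L) {
  h0 <- log(2) / cfg$baseline_median_days
  haz <- ifelse(subtypes == "primitive", h0 * cfg$hr_subtype, h0)
  n <- length(subtypes)
  with_seed(derive_seed(seed, 9001L), {
    t_event <- rexp(n, rate = haz)
    if (cfg$censor_frac > 0) {
      # P(C < T) for C ~ U(0, tau) and T ~ Exp(h) is (1 - exp(-h tau)) / (h tau)
      frac <- function(tau) mean((1 - exp(-haz * tau)) / (haz * tau)) - cfg$censor_frac
      tau <- uniroot(frac, lower = 1e-3, upper = 1e7, tol = 1e-8)$root
      t_cens <- runif(n, 0, tau)
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    } else {
      event <- rep(1L, n)
      time <- t_event
    }
    data.frame(sample_id = names(subtypes), time = time, event = event,
               group = unname(subtypes), stringsAsFactors = FALSE)
  })
}
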