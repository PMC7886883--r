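#' Align a training and a test expression matrix on shared genes
#'
#' Restricts both matrices to the gene intersection (same order), drops genes
#' that are constant in either dataset (with a warning), and z-scores every
#' remaining gene within its own dataset. This is the harmonization used to
#' carry a patient-trained subtype model onto a cell-line panel without
#' cross-dataset batch correction.
#'
#' @param train,test `ExpressionMatrix` objects on the log scale (or any
#'   common scale; each gene is re-standardized per dataset).
#' @param min_shared minimum usable gene intersection (default 50).
#' @return list with `train` and `test`, both `scale = "zscored"`.
#' @export
harmonize_features <- function(train, test, min_shared = 50L) {
  stopifnot(inherits(train, "ExpressionMatrix"), inherits(test, "ExpressionMatrix"))
  shared <- intersect(train$gene_ids, test$gene_ids)
  if (length(shared) < min_shared) {
    stopf("gene intersection has %d genes (< %d)", length(shared), min_shared)
  }
  tr <- train$values[shared, , drop = FALSE]
  te <- test$values[shared, , drop = FALSE]
  const <- apply(tr, 1, sd) == 0 | apply(te, 1, sd) == 0
  if (any(const)) {
    warnf("%d constant gene(s) dropped from both datasets", sum(const))
    if (sum(!const) < min_shared) stopf("fewer than %d non-constant shared genes", min_shared)
    tr <- tr[!const, , drop = FALSE]
    te <- te[!const, , drop = FALSE]
  }
  z <- function(m) t(scale(t(m)))
  list(
    train = expression_matrix(z(tr), train$cohort_id, rownames(tr),
                              train$sample_ids, scale = "zscored"),
    test = expression_matrix(z(te), test$cohort_id, rownames(te),
                             test$sample_ids, scale = "zscored")
  )
}

# stratified fold ids: samples of each class dealt round-robin after a
# seeded shuffle, so every fold holds both classes
stratified_folds <- function(y, nfolds, seed) {
  foldid <- integer(length(y))
  with_seed(seed, {
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
    }
  })
  foldid
}

#' Elastic-net subtype classifier with (alpha, lambda) cross-validation
#'
#' Penalized logistic regression of subtype on expression. For every alpha
#' on `alpha_grid`, a 50-value lambda path is cross-validated with seeded,
#' class-balanced 10-fold splits; the (alpha, lambda) pair minimizing the
#' mean CV binomial deviance wins and the model is refit on all samples.
#'
#' @param X numeric matrix, samples x genes (z-scored features).
#' @param y factor or character subtype labels with exactly two levels;
#'   `"primitive"` (or the second factor level) is the positive class.
#' @param alpha_grid elastic-net mixing values (default 0.1, 0.2, ..., 1.0).
#' @param n_lambda lambda path length per alpha (default 50).
#' @param nfolds CV folds (default 10).
#' @param seed fold-assignment seed.
#' @return An `ElasticNetModel`: list with `gene_ids`, `coefficients`,
#'   `intercept`, `alpha`, `lambda`, `cv_table`, `train_scaling`, `levels`
#'   (negative, positive class).
#' @export
fit_elasticnet_classifier <- function(X, y, alpha_grid = seq(0.1, 1, by = 0.1),
                                      n_lambda = 50L, nfolds = 10L, seed = 1L) {
  y <- factor(y)
  if (nlevels(y) != 2) stopf("y must have exactly 2 classes, got %d", nlevels(y))
  if ("primitive" %in% levels(y)) y <- stats::relevel(y, ref = setdiff(levels(y), "primitive")[1])
  if (min(table(y)) < nfolds) stopf("each class needs >= %d members for %d-fold CV",
                                    nfolds, nfolds)
  X <- as.matrix(X)
  foldid <- stratified_folds(y, nfolds, seed)
  cv_rows <- list(); best <- NULL
  for (a in alpha_grid) {
    cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = a,
                            nlambda = n_lambda, foldid = foldid,
                            type.measure = "deviance", standardize = FALSE)
    i <- which.min(cv$cvm)
    cv_rows[[length(cv_rows) + 1L]] <- data.frame(alpha = a, lambda = cv$lambda[i],
                                                  cv_deviance = cv$cvm[i])
    if (is.null(best) || cv$cvm[i] < best$cvm) {
      best <- list(alpha = a, lambda = cv$lambda[i], cvm = cv$cvm[i])
    }
  }
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = best$alpha,
                        lambda = best$lambda, standardize = FALSE)
  beta <- as.numeric(coef(fit))
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  structure(
    list(gene_ids = colnames(X), coefficients = stats::setNames(beta[-1], colnames(X)),
         intercept = beta[1], alpha = best$alpha, lambda = best$lambda,
         cv_table = do.call(rbind, cv_rows),
         train_scaling = list(mean = mu, sd = sdv), levels = levels(y)),
    class = "ElasticNetModel")
}

#' Predicted probability of the primitive subtype
#'
#' Applies the training per-gene scaling to `X`, forms the linear score and
#' returns its logistic transform. Every model gene must be present.
#'
#' @param model an `ElasticNetModel`.
#' @param X samples x genes matrix (columns named by gene id), e.g. the
#'   `test` half of [harmonize_features()] transposed.
#' @return named numeric vector of probabilities in (0, 1).
#' @export
predict_subtype_prob <- function(model, X) {
  stopifnot(inherits(model, "ElasticNetModel"))
  X <- as.matrix(X)
  miss <- setdiff(model$gene_ids, colnames(X))
  if (length(miss)) stopf("%d model gene(s) missing from input (e.g. %s)",
                          length(miss), miss[1])
  X <- X[, model$gene_ids, drop = FALSE]
  sdv <- ifelse(model$train_scaling$sd > 0, model$train_scaling$sd, 1)
  Xs <- sweep(sweep(X, 2, model$train_scaling$mean), 2, sdv, "/")
  eta <- drop(model$intercept + Xs %*% model$coefficients)
  stats::setNames(plogis(eta), rownames(X))
}
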