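#' Cross-validation configuration
#'
#' @param k number of folds (default 10).
#' @param n_top_features number of lowest-p features kept per fold
#'   (default 50; the count is a tunable choice, not a published value).
#' @param classifier `"sparse_logistic"` (L1-penalised logistic regression,
#'   penalty chosen by inner 5-fold CV on the training fold only) or
#'   `"gradient_boosting"` (tree ensemble with fixed hyperparameters:
#'   depth 3, 200 rounds, learning rate 0.1, row subsample 0.8).
#' @param seed RNG seed controlling fold assignment and classifier RNG.
#' @param stratified keep the class ratio in every fold (default `TRUE`).
#' @return a `cv_config` list.
#' @export
cv_config <- function(k = 10, n_top_features = 50,
                      classifier = c("sparse_logistic", "gradient_boosting"),
                      seed = 1L, stratified = TRUE) {
  classifier <- match.arg(classifier)
  if (k < 2) abort_ims("k must be >= 2", "imsvoc_config_error")
  structure(list(k = as.integer(k),
                 n_top_features = as.integer(n_top_features),
                 classifier = classifier, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "cv_config")
}

#' Assign samples to cross-validation folds
#'
#' Produces folds whose sizes differ by at most one. In stratified mode
#' each class is distributed as evenly as possible and the per-class
#' remainders are placed on the currently least-loaded folds, so the class
#' ratio is preserved within rounding while overall sizes stay balanced.
#'
#' @param labels binary 0/1 vector.
#' @param k number of folds; at most the size of the smaller class when
#'   stratified, at most `length(labels)` otherwise.
#' @param seed RNG seed.
#' @param stratified logical.
#' @return integer vector of fold indices in `1:k`, one per sample.
#' @export
assign_folds <- function(labels, k, seed = 1L, stratified = TRUE) {
  n <- length(labels)
  if (k > n) abort_ims("more folds than samples", "imsvoc_config_error")
  withr::with_seed(as.integer(seed), {
    fold <- integer(n)
    if (!stratified) {
      fold <- rep_len(seq_len(k), n)[sample.int(n)]
    } else {
      if (k > min(table(labels))) {
        abort_ims("k exceeds the size of the smaller class",
                  "imsvoc_config_error")
      }
      load <- numeric(k)
      for (cl in sort(unique(labels))) {
        idx <- which(labels == cl)
        nc <- length(idx)
        q <- nc %/% k
        r <- nc %% k
        counts <- rep(q, k)
        if (r > 0) {
          extra <- order(load, sample.int(k))[seq_len(r)]
          counts[extra] <- counts[extra] + 1L
        }
        fold[idx[sample.int(nc)]] <- rep(seq_len(k), counts)
        load <- load + counts
      }
    }
    fold
  })
}

#' Select features on a training fold and score its validation fold
#'
#' The per-fold unit of the pipeline: rank-sum feature selection on the
#' training rows only, classifier fit on the selected columns, class-1
#' probabilities predicted for the held-out rows. Sparse logistic
#' regression tunes its L1 penalty by inner 5-fold CV inside the training
#' fold (the validation fold never enters); gradient boosting uses fixed,
#' seeded hyperparameters.
#'
#' @param table an `ims_feature_table`.
#' @param train_indices,test_indices disjoint row index vectors; training
#'   rows must contain both classes.
#' @param config a [cv_config].
#' @param fold_seed seed for this fold's classifier RNG.
#' @return list with `probabilities` (one per test row, in `[0,1]`),
#'   `selected` (feature indices) and `p_values` (their training p-values).
#' @export
fit_and_score_fold <- function(table, train_indices, test_indices, config,
                               fold_seed = config$seed) {
  if (length(intersect(train_indices, test_indices))) {
    abort_ims("train and test indices overlap", "imsvoc_config_error")
  }
  sel <- select_features(table, train_indices, config$n_top_features)
  xtr <- table$values[train_indices, sel, drop = FALSE]
  xte <- table$values[test_indices, sel, drop = FALSE]
  ytr <- table$labels[train_indices]
  prob <- withr::with_seed(as.integer(fold_seed), {
    tryCatch(
      fit_classifier(xtr, ytr, xte, config$classifier,
                     seed = as.integer(fold_seed)),
      error = function(e) {
        abort_ims(sprintf("classifier fit failed on fold with %d training samples: %s",
                          length(train_indices), conditionMessage(e)),
                  "imsvoc_fit_error")
      })
  })
  prob <- pmin(pmax(as.numeric(prob), 0), 1)
  list(probabilities = prob, selected = as.integer(sel),
       p_values = attr(sel, "p_values"))
}

fit_classifier <- function(xtr, ytr, xte, classifier, seed) {
  if (classifier == "sparse_logistic") {
    if (ncol(xtr) < 2L) {
      # glmnet needs >= 2 predictors; plain logistic fit on the single one
      df <- data.frame(y = ytr, x = xtr[, 1])
      fit <- suppressWarnings(glm(y ~ x, data = df, family = binomial()))
      return(predict(fit, data.frame(x = xte[, 1]), type = "response"))
    }
    foldid <- assign_folds(ytr, k = min(5L, min(table(ytr))), seed = seed,
                           stratified = TRUE)
    cvfit <- glmnet::cv.glmnet(xtr, ytr, family = "binomial", alpha = 1,
                               foldid = foldid, standardize = TRUE)
    as.numeric(predict(cvfit, xte, s = "lambda.min", type = "response"))
  } else {
    dtr <- xgboost::xgb.DMatrix(xtr, label = ytr, nthread = 1)
    booster <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3,
                    eta = 0.1, subsample = 0.8, nthread = 1,
                    tree_method = "exact", seed = seed),
      data = dtr, nrounds = 200, verbose = 0)
    predict(booster, xgboost::xgb.DMatrix(xte, nthread = 1))
  }
}

#' Run the leakage-guarded cross-validated pipeline
#'
#' Assigns every sample to exactly one validation fold, then, fold by
#' fold, selects features and fits the classifier on the remaining
#' training folds only and predicts the held-out samples. The out-of-fold
#' probabilities are pooled into a single vector aligned with the table's
#' samples, from which one ROC analysis is computed downstream. Fully
#' reproducible from `config$seed`.
#'
#' @param table an `ims_feature_table`.
#' @param config a [cv_config].
#' @return an `ims_cv_result`: list with `fold_assignment`,
#'   `oof_probability`, `selected` (per-fold list of feature indices),
#'   `selected_p` (their training p-values), `classifier`, `config`.
#' @export
run_cv <- function(table, config = cv_config()) {
  stopifnot(inherits(table, "ims_feature_table"),
            inherits(config, "cv_config"))
  fold <- assign_folds(table$labels, config$k,
                       seed = derive_seed(config$seed, 0L),
                       stratified = config$stratified)
  oof <- rep(NA_real_, nrow(table$values))
  selected <- vector("list", config$k)
  selected_p <- vector("list", config$k)
  for (f in seq_len(config$k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    res <- tryCatch(
      fit_and_score_fold(table, train_idx, test_idx, config,
                         fold_seed = derive_seed(config$seed, f)),
      error = function(e) {
        abort_ims(sprintf("fold %d: %s", f, conditionMessage(e)),
                  "imsvoc_fold_error")
      })
    oof[test_idx] <- res$probabilities
    selected[[f]] <- res$selected
    selected_p[[f]] <- res$p_values
  }
  structure(list(fold_assignment = fold, oof_probability = oof,
                 selected = selected, selected_p = selected_p,
                 classifier = config$classifier, config = config),
            class = "ims_cv_result")
}

#' @export
print.ims_cv_result <- function(x, ...) {
  cat(sprintf("<ims_cv_result> %d-fold CV, %s, %d samples, %d features/fold\n",
              x$config$k, x$classifier, length(x$oof_probability),
              x$config$n_top_features))
  invisible(x)
}
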