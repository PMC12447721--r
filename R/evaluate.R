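#' Per-output mean squared error
#'
#' Reconstruction error of each score, missing true values masked.
#' Categorical outputs are compared on the probability-weighted expected
#' level by default, or on the argmax level.
#'
#' @param y true [score_matrix()].
#' @param yhat `score_predictions` from [predict_scores()] (or a matrix of
#'   scalar summaries).
#' @param categorical `"expected"` or `"argmax"`.
#' @return named numeric vector of MSEs; an all-missing output is `NA`.
#' @export
mse_per_output <- function(y, yhat, categorical = c("expected", "argmax")) {
  categorical <- match.arg(categorical)
  stopifnot(inherits(y, "score_matrix"))
  S <- if (inherits(yhat, "score_predictions")) {
    s <- yhat$scores
    if (categorical == "argmax") {
      for (nm in names(yhat$probs)) {
        if (y$schema$dtype[y$schema$name == nm] == "categorical")
          s[, nm] <- max.col(yhat$probs[[nm]]) - 1
      }
    }
    s
  } else as.matrix(yhat)
  common <- intersect(rownames(y$values), rownames(S))
  if (!length(common)) stop_sym("no overlapping samples between y and yhat")
  Yv <- y$values[common, , drop = FALSE]
  Sv <- S[common, colnames(Yv), drop = FALSE]
  out <- vapply(seq_len(ncol(Yv)), function(i) {
    obs <- !is.na(Yv[, i])
    if (!any(obs)) return(NA_real_)
    mean((Yv[obs, i] - Sv[obs, i])^2)
  }, 0)
  names(out) <- colnames(Yv)
  out
}

#' Binary classification metrics
#'
#' Accuracy, precision, recall, F1 at the given probability threshold, and
#' AUC by the Mann-Whitney rank statistic (ties averaged).  With a single
#' class present, AUC is `NA`.
#'
#' @param labels 0/1 truth.
#' @param probabilities predicted probabilities.
#' @param threshold classification threshold (default 0.5).
#' @return named numeric vector.
#' @export
binary_metrics <- function(labels, probabilities, threshold = 0.5) {
  y <- as.numeric(labels)
  p <- as.numeric(probabilities)
  stopifnot(length(y) == length(p))
  pred <- as.numeric(p > threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- if (n1 > 0 && n0 > 0) {
    r <- rank(p)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else NA_real_
  c(accuracy = (tp + tn) / length(y), precision = precision, recall = recall,
    f1 = f1, auc = auc)
}

#' Align an external cohort to a model's feature list
#'
#' Reindexes the external matrix to exactly the model's features in model
#' order: features the external study measured are matched; features it
#' did not are imputed as zero columns (before standardization with the
#' model's stored statistics, which happens inside prediction); extra
#' external features are dropped.  Idempotent.
#'
#' @param x_ext external [omics_matrix()].
#' @param model_features ordered feature list of the trained model (or a
#'   trained `omics_nn`).
#' @return list with `x` (aligned `omics_matrix`) and `report` (class
#'   `alignment_report`: `coverage`, `matched`, `imputed`).
#' @export
align_external <- function(x_ext, model_features) {
  if (inherits(model_features, "omics_nn"))
    model_features <- model_features$feature_ids
  V <- as_omics_values(x_ext)
  matched <- intersect(model_features, colnames(V))
  if (!length(matched))
    stop_sym("no external features match the model (coverage 0)")
  imputed <- setdiff(model_features, matched)
  out <- matrix(0, nrow(V), length(model_features),
                dimnames = list(rownames(V), model_features))
  out[, matched] <- V[, matched]
  report <- structure(list(coverage = length(matched) / length(model_features),
                           matched = matched, imputed = imputed),
                      class = "alignment_report")
  list(x = omics_matrix_nocheck(out,
         if (inherits(x_ext, "omics_matrix")) x_ext$kind else "combined"),
       report = report)
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("<alignment_report> coverage %.1f%% (%d matched, %d zero-imputed)\n",
              100 * x$coverage, length(x$matched), length(x$imputed)))
  invisible(x)
}

#' Validate a trained model on an external cohort
#'
#' Aligns the external features ([align_external()]), predicts the score
#' panel with the model's stored normalization, collapses it to a disease
#' probability through the score layer, and reports binary metrics plus the
#' feature coverage.
#'
#' @param model a trained `omics_nn`.
#' @param layer a fitted [score_layer_fit()].
#' @param x_ext external [omics_matrix()].
#' @param labels external 0/1 labels.
#' @return list with `metrics`, `report`, `prob`.
#' @export
validate_external <- function(model, layer, x_ext, labels) {
  al <- align_external(x_ext, model)
  pred <- predict_scores(model, al$x)
  prob <- score_layer_predict(layer, pred)
  list(metrics = binary_metrics(labels, prob), report = al$report,
       prob = prob)
}

# Train RUS-averaged models on one training set and return a closure that
# predicts averaged score panels for new data.
train_rus_ensemble <- function(x_tr, y_tr, arch, hp, rus_iter, seed) {
  labels_attr <- attr(x_tr, "labels")
  models <- vector("list", rus_iter)
  plan <- rus_plan(labels_attr, n_iter = rus_iter, seed = seed)
  for (i in seq_len(rus_iter)) {
    model <- build_model(arch, seed = seed + i)
    models[[i]] <- train_model(model, x_tr, y_tr, hp,
                               sample_idx = plan$iterations[[i]])
  }
  models
}

predict_rus_average <- function(models, x) {
  preds <- lapply(models, predict_scores, x = x)
  avg <- Reduce(`+`, lapply(preds, `[[`, "scores")) / length(preds)
  structure(list(scores = avg, probs = preds[[1]]$probs,
                 schema = preds[[1]]$schema),
            class = "score_predictions")
}

#' Cross-validated training and evaluation
#'
#' Stratified k-fold evaluation of the full recipe: per fold, balanced
#' training sets are drawn by random under-sampling (`rus_iter` draws,
#' predictions averaged across the resulting models), the score layer is
#' fitted on the training predictions, and the held-out fold is scored.
#'
#' @param x [omics_matrix()].
#' @param y [score_matrix()] aligned to `x`.
#' @param labels 0/1 disease labels.
#' @param hp a [hyperparams()].
#' @param k folds (default 5).
#' @param rus_iter under-sampling iterations per fold.
#' @param seed seed controlling folds, resampling and model builds.
#' @param arch optional [architecture_spec()] (defaults to the standard
#'   64/32/8 architecture for `ncol(x)` features and `y`'s schema).
#' @return a `cv_report`: `binary` (per-fold metric matrix), `mse`
#'   (fold x output), `pooled` (held-out probabilities for every sample),
#'   `pooled_auc`, `folds`.
#' @export
evaluate_cv <- function(x, y, labels, hp = hyperparams(epochs = 100L),
                        k = 5L, rus_iter = 3L, seed = 1L, arch = NULL) {
  X <- as_omics_values(x)
  stopifnot(inherits(y, "score_matrix"), nrow(X) == length(labels))
  arch <- arch %||% architecture_spec(ncol(X), y$schema)
  folds <- stratified_kfold(labels, k = k, seed = seed)
  n_out <- nrow(y$schema)
  bin <- matrix(NA_real_, k, 5, dimnames = list(NULL, c("accuracy", "precision",
                                                        "recall", "f1", "auc")))
  mse <- matrix(NA_real_, k, n_out, dimnames = list(NULL, y$schema$name))
  pooled <- data.frame(sample = rownames(X), label = as.numeric(labels),
                       prob = NA_real_, fold = NA_integer_,
                       stringsAsFactors = FALSE)
  for (f in seq_len(k)) {
    te <- folds$test_idx[[f]]
    tr <- setdiff(seq_len(nrow(X)), te)
    x_tr <- omics_matrix_nocheck(X[tr, , drop = FALSE])
    attr(x_tr, "labels") <- labels[tr]
    y_tr <- score_matrix(y$values[tr, , drop = FALSE], y$schema)
    models <- train_rus_ensemble(x_tr, y_tr, arch, hp, rus_iter,
                                 seed = seed + 1000L * f)
    pred_tr <- predict_rus_average(models, x_tr)
    layer <- score_layer_fit(pred_tr, labels[tr], true_scores = y_tr)
    x_te <- omics_matrix_nocheck(X[te, , drop = FALSE])
    pred_te <- predict_rus_average(models, x_te)
    prob_te <- score_layer_predict(layer, pred_te)
    bin[f, ] <- binary_metrics(labels[te], prob_te)
    y_te <- score_matrix(y$values[te, , drop = FALSE], y$schema)
    mse[f, ] <- mse_per_output(y_te, pred_te)
    pooled$prob[te] <- prob_te
    pooled$fold[te] <- f
  }
  structure(list(binary = bin, mse = mse, pooled = pooled,
                 pooled_auc = unname(binary_metrics(pooled$label,
                                                    pooled$prob)["auc"]),
                 folds = folds, k = k, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold: AUC %.3f (pooled), mean fold AUC %.3f +/- %.3f\n",
              x$k, x$pooled_auc, mean(x$binary[, "auc"]),
              stats::sd(x$binary[, "auc"])))
  invisible(x)
}

#' Baseline classifier comparison
#'
#' Runs the reference comparators under identical folds: elastic-net
#' logistic regression (C = 0.5, i.e. penalty 1/(C n)), an RBF-kernel SVM
#' (C = 2), gradient-boosted trees (learning rate 0.05, depth 5), and the
#' ablated network whose heads attach directly to Z2 (no parallel
#' sub-layers, single binary output).  Features are standardized with each
#' fold's training statistics before fitting.
#'
#' @param x [omics_matrix()].
#' @param labels 0/1 labels.
#' @param folds a [stratified_kfold()] split.
#' @param hp [hyperparams()] for the ablated network.
#' @param nrounds boosting rounds (reference setting 1000).
#' @param seed seed for the network build.
#' @return list with `per_fold` (data frame: model, fold, metrics) and
#'   `summary` (mean metrics per model).
#' @export
benchmark_baselines <- function(x, labels, folds,
                                hp = hyperparams(epochs = 100L),
                                nrounds = 1000L, seed = 1L) {
  X <- as_omics_values(x)
  y <- as.numeric(labels)
  rows <- list()
  for (f in seq_along(folds$test_idx)) {
    te <- folds$test_idx[[f]]
    tr <- setdiff(seq_len(nrow(X)), te)
    st <- standardize(omics_matrix_nocheck(X[tr, , drop = FALSE]))
    Xtr <- st$x$values
    Xte <- standardize(omics_matrix_nocheck(X[te, , drop = FALSE]),
                       st$stats)$x$values
    probs <- list()
    fit_lr <- glmnet::glmnet(Xtr, y[tr], family = "binomial", alpha = 0.5,
                             lambda = 1 / (0.5 * length(tr)),
                             standardize = FALSE)
    probs$logistic_elasticnet <-
      as.numeric(stats::predict(fit_lr, Xte, type = "response"))
    fit_svm <- e1071::svm(Xtr, factor(y[tr], levels = c(0, 1)),
                          kernel = "radial", cost = 2, probability = TRUE)
    pr <- attr(stats::predict(fit_svm, Xte, probability = TRUE),
               "probabilities")
    probs$svm_rbf <- as.numeric(pr[, "1"])
    dtr <- xgboost::xgb.DMatrix(Xtr, label = y[tr])
    fit_gb <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = 0.05, max_depth = 5,
                    nthread = 1),
      data = dtr, nrounds = nrounds, verbose = 0)
    probs$gbdt <- as.numeric(stats::predict(fit_gb,
                                            xgboost::xgb.DMatrix(Xte)))
    sch_bin <- score_schema("disease", "binary")
    arch0 <- architecture_spec(ncol(X), sch_bin, use_z3 = FALSE)
    ymat <- matrix(y[tr], ncol = 1,
                   dimnames = list(rownames(Xtr), "disease"))
    dnn <- train_model(build_model(arch0, seed = seed + f),
                       omics_matrix_nocheck(Xtr),
                       score_matrix(ymat, sch_bin), hp,
                       standardize_input = FALSE)
    probs$dnn_no_z3 <- as.numeric(predict_scores(dnn, Xte)$scores[, 1])
    for (mname in names(probs)) {
      m <- binary_metrics(y[te], probs[[mname]])
      rows[[length(rows) + 1]] <- data.frame(model = mname, fold = f,
                                             t(m), stringsAsFactors = FALSE)
    }
  }
  per_fold <- do.call(rbind, rows)
  summary <- stats::aggregate(per_fold[, c("accuracy", "precision", "recall",
                                           "f1", "auc")],
                              by = list(model = per_fold$model), FUN = mean)
  list(per_fold = per_fold, summary = summary)
}
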