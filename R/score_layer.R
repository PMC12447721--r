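#' Fit the auxiliary score-to-diagnosis layer
#'
#' A single logistic unit attached on top of the predicted score panel:
#' `p = sigmoid(w . yhat + b)`.  It is never used to train the network
#' itself; it evaluates how well the reconstructed scores discriminate
#' cases from controls.  Weights start from the clinical data (a logistic
#' fit of the *true* scores on the disease label, rescaled to unit norm)
#' and are refined by plain gradient descent on the mean squared error
#' between the predicted probability and the label:
#' `w_new = w_old - eta * grad L_MSE`.
#'
#' @param scores predicted score panel: a `score_predictions` object or a
#'   samples x outputs numeric matrix.
#' @param labels 0/1 disease labels aligned to `scores`.
#' @param n_steps gradient steps (default 500).
#' @param eta learning step size (> 0 required; `eta = 0` is allowed and
#'   leaves the initial weights untouched).
#' @param init `"clinical"` (logistic fit of `true_scores` on the label) or
#'   `"uniform"` (equal weights).
#' @param true_scores the observed [score_matrix()] (or matrix), required
#'   for `init = "clinical"`.
#' @param w0 optionally, an explicit `score_layer` or weight vector to start
#'   from (overrides `init`).
#' @return a `score_layer`: list with `w`, `b`, `eta` and `loss_trace`.
#' @export
score_layer_fit <- function(scores, labels, n_steps = 500L, eta = 0.1,
                            init = c("clinical", "uniform"),
                            true_scores = NULL, w0 = NULL) {
  init <- match.arg(init)
  S <- if (inherits(scores, "score_predictions")) scores$scores else as.matrix(scores)
  y <- as.numeric(labels)
  stopifnot(length(y) == nrow(S))
  if (eta < 0) stop_sym("eta must be >= 0")
  if (!is.null(w0)) {
    w <- if (inherits(w0, "score_layer")) w0$w else as.numeric(w0)
    b <- if (inherits(w0, "score_layer")) w0$b else 0
    if (length(w) != ncol(S)) stop_sym("w0 length does not match score panel")
  } else if (init == "clinical") {
    if (is.null(true_scores))
      stop_sym("init = \"clinical\" needs `true_scores`")
    Tm <- if (inherits(true_scores, "score_matrix")) true_scores$values
          else as.matrix(true_scores)
    fit <- suppressWarnings(stats::glm.fit(cbind(1, Tm), y,
                                           family = stats::binomial()))
    co <- fit$coefficients[-1]
    co[!is.finite(co)] <- 0
    nrm <- sqrt(sum(co^2))
    w <- if (nrm > 0) co / nrm else rep(1 / sqrt(ncol(S)), ncol(S))
    b <- 0
  } else {
    w <- rep(1 / ncol(S), ncol(S))
    b <- 0
  }
  names(w) <- colnames(S)
  trace <- numeric(n_steps + 1)
  n <- nrow(S)
  p <- stats::plogis(as.numeric(S %*% w) + b)
  trace[1] <- mean((p - y)^2)
  if (n_steps > 0 && eta > 0) {
    for (s in seq_len(n_steps)) {
      dz <- 2 * (p - y) * p * (1 - p) / n
      w <- w - eta * as.numeric(crossprod(S, dz))
      b <- b - eta * sum(dz)
      p <- stats::plogis(as.numeric(S %*% w) + b)
      trace[s + 1] <- mean((p - y)^2)
    }
  } else trace <- trace[1]
  structure(list(w = w, b = b, eta = eta, loss_trace = trace, init = init),
            class = "score_layer")
}

#' Predict the disease probability from a score panel
#'
#' @param layer a `score_layer` from [score_layer_fit()].
#' @param scores a `score_predictions` object or numeric matrix.
#' @return numeric vector of probabilities.
#' @export
score_layer_predict <- function(layer, scores) {
  S <- if (inherits(scores, "score_predictions")) scores$scores else as.matrix(scores)
  stats::plogis(as.numeric(S %*% layer$w) + layer$b)
}

#' Assemble a combined 'omics matrix from per-assay attributions
#'
#' For each assay, features are ranked by their overall attribution
#' importance (mean |phi| across samples, averaged over outputs) in that
#' assay's model, and the requested number of top features is carried into
#' one integrated matrix.  The counts used for the reference 154-feature
#' panel were 50 immune + 32 species + 30 KEGG + 42 metabolite features.
#'
#' @param attributions named list (by assay kind) of attribution lists as
#'   returned by [explain_all()].
#' @param omics named list (by assay kind) of the corresponding
#'   [omics_matrix()] objects.
#' @param top_counts named integer vector: features to keep per kind.
#' @return an [omics_matrix()] of kind `"combined"`; feature ids are
#'   prefixed with their kind to stay unique.
#' @export
build_combined_omics <- function(attributions, omics, top_counts) {
  stopifnot(all(names(top_counts) %in% names(attributions)),
            all(names(top_counts) %in% names(omics)))
  blocks <- list()
  for (kind in names(top_counts)) {
    attr_list <- attributions[[kind]]
    imp <- Reduce(`+`, lapply(attr_list, function(a) colMeans(abs(a$phi))))
    imp <- imp / length(attr_list)
    k <- top_counts[[kind]]
    if (k > length(imp))
      stop_sym("requested ", k, " features from '", kind, "' but only ",
               length(imp), " available")
    top <- names(imp)[order(-imp, names(imp))][seq_len(k)]
    v <- as_omics_values(omics[[kind]])[, top, drop = FALSE]
    colnames(v) <- paste0(kind, ".", colnames(v))
    blocks[[kind]] <- v
  }
  omics_matrix(do.call(cbind, blocks), "combined")
}
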