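#' Extract a single-output sub-model
#'
#' The network's shared layers plus one output's sub-layer and head form a
#' standalone predictor (normalization + Z1 + Z2 + zi3 + head_i) that
#' agrees exactly with the full model's corresponding output.  The returned
#' closure maps a raw-scale feature matrix (model feature order) to the
#' output's scalar summary: head value for continuous scores, probability
#' for binary, expected level for categorical.
#'
#' @param model a trained `omics_nn`.
#' @param output_index integer in 1..n_outputs (or an output name).
#' @return `function(X)` returning one number per row of `X`.
#' @export
extract_submodel <- function(model, output_index) {
  schema <- model$schema
  if (is.character(output_index)) output_index <- match(output_index, schema$name)
  if (is.na(output_index) || output_index < 1 || output_index > nrow(schema))
    stop_sym("output index out of range (1..", nrow(schema), ")")
  i <- as.integer(output_index)
  arch <- model$arch
  w <- model$weights[c("W1", "b1", "W2", "b2",
                       paste0(c("W3_", "b3_", "W4_", "b4_"), i))]
  if (!arch$use_z3) w <- w[!grepl("^W3|^b3", names(w))]
  stats <- model$stats
  dtype <- schema$dtype[i]
  levels_vec <- if (dtype == "categorical") seq(0, schema$n_levels[i] - 1)
  function(X) {
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    if (!is.null(stats)) {
      div <- ifelse(stats$sigma > 0, stats$sigma, 1)
      X <- sweep(sweep(X, 2, stats$mu), 2, div, "/")
    }
    A1 <- relu(sweep(X %*% w$W1, 2, w$b1, "+"))
    A2 <- relu(sweep(A1 %*% w$W2, 2, w$b2, "+"))
    hin <- if (arch$use_z3)
      relu(sweep(A2 %*% w[[paste0("W3_", i)]], 2, w[[paste0("b3_", i)]], "+"))
    else A2
    H <- sweep(hin %*% w[[paste0("W4_", i)]], 2, w[[paste0("b4_", i)]], "+")
    switch(dtype,
           continuous = H[, 1],
           binary = stats::plogis(H[, 1]),
           categorical = as.numeric(softmax_rows(H) %*% levels_vec))
  }
}

shapley_kernel_weight <- function(m, s) (m - 1) / (choose(m, s) * s * (m - s))

# rows of the full coalition lattice as a 0/1 matrix, low bit = feature 1
coalition_matrix <- function(m, masks = seq(0, 2^m - 1)) {
  Z <- matrix(0L, length(masks), m)
  for (j in seq_len(m)) Z[, j] <- bitwAnd(masks %/% 2^(j - 1), 1L)
  Z
}

#' Exact Shapley values by subset enumeration
#'
#' Enumerates all 2^m coalitions; features absent from a coalition are
#' replaced by the background means.  Satisfies the efficiency axiom
#' exactly: `f(bg mean) + sum(phi) = f(x)`.
#'
#' @param f predictor: `function(X)` over rows of a feature matrix.
#' @param x numeric feature vector to explain.
#' @param background background matrix (rows = reference samples) or a
#'   single reference vector; column means define the absent-feature values.
#' @return numeric `phi` of length m with attribute `base_value`.
#' @export
exact_shapley <- function(f, x, background) {
  m <- length(x)
  if (m > 15)
    stop_sym("exact enumeration limited to 15 features (2^m model calls); ",
             "use kernel_shapley()")
  bg <- if (is.null(dim(background))) as.numeric(background)
        else colMeans(background)
  if (length(bg) != m) stop_sym("background width does not match x")
  masks <- seq(0, 2^m - 1)
  Z <- coalition_matrix(m, masks)
  inputs <- Z * rep(x, each = nrow(Z)) + (1 - Z) * rep(bg, each = nrow(Z))
  colnames(inputs) <- names(x)
  v <- as.numeric(f(inputs))
  sizes <- rowSums(Z)
  wt <- factorial(0:(m - 1)) * factorial(m - 1 - 0:(m - 1)) / factorial(m)
  phi <- numeric(m)
  for (j in seq_len(m)) {
    bit <- 2^(j - 1)
    without <- masks[bitwAnd(masks, bit) == 0L]
    s <- sizes[without + 1L]
    phi[j] <- sum(wt[s + 1L] * (v[without + bit + 1L] - v[without + 1L]))
  }
  names(phi) <- names(x)
  attr(phi, "base_value") <- v[1]
  phi
}

# Precompute the weighted-least-squares solver for a coalition design.
# Solves the Shapley regression with the efficiency constraint eliminated
# through the last feature; returns H such that phi[1..m-1] = H %*% y_adj.
kernel_solver <- function(Z, wts) {
  m <- ncol(Z)
  Xa <- Z[, -m, drop = FALSE] - Z[, m]
  XtW <- t(Xa * wts)
  A <- XtW %*% Xa
  diag(A) <- diag(A) + 1e-10
  solve(A, XtW)
}

# Size-stratified coalition design, following the reference kernel
# explainer: complete coalition sizes are enumerated outside-in (size 1 and
# m-1 first, then 2 and m-2, ...) for as long as the budget allows and get
# their exact aggregate kernel mass; the remaining budget is sampled from
# the leftover sizes in proportion to their mass, sharing the leftover mass
# equally.  This pins down main effects even at small budgets.
stratified_coalitions <- function(m, n_coalitions) {
  sizes <- seq_len(m - 1)
  mass <- (m - 1) / (sizes * (m - sizes))
  mass <- mass / sum(mass)
  order_sizes <- unique(as.vector(rbind(sizes, m - sizes)))
  budget <- n_coalitions
  Zs <- list(); wts <- numeric(0)
  enumerated <- logical(m - 1)
  for (s in order_sizes) {
    if (enumerated[s]) next
    cnt <- choose(m, s)
    if (cnt > budget) break
    idx <- utils::combn(m, s)
    Zb <- matrix(0L, ncol(idx), m)
    Zb[cbind(rep(seq_len(ncol(idx)), each = s), as.vector(idx))] <- 1L
    Zs[[length(Zs) + 1]] <- Zb
    wts <- c(wts, rep(mass[s] / cnt, ncol(idx)))
    enumerated[s] <- TRUE
    budget <- budget - cnt
  }
  left <- sizes[!enumerated]
  if (length(left) && budget > 0) {
    p <- mass[left] / sum(mass[left])
    s_draw <- left[sample.int(length(left), budget, replace = TRUE, prob = p)]
    Zb <- matrix(0L, budget, m)
    for (r in seq_len(budget)) Zb[r, sample(m, s_draw[r])] <- 1L
    Zs[[length(Zs) + 1]] <- Zb
    wts <- c(wts, rep(sum(mass[left]) / budget, budget))
  }
  list(Z = do.call(rbind, Zs), wts = wts)
}

# Shared machinery: choose the coalition design for kernel estimation.
kernel_design <- function(m, n_coalitions, seed) {
  full <- 2^m - 2
  if (m >= 2 && full <= n_coalitions) {
    Z <- coalition_matrix(m, seq(1, 2^m - 2))
    wts <- shapley_kernel_weight(m, rowSums(Z))
  } else {
    sc <- with_seed(seed, stratified_coalitions(m, n_coalitions))
    Z <- sc$Z
    wts <- sc$wts
  }
  list(Z = Z, wts = wts, H = kernel_solver(Z, wts))
}

#' Kernel estimator of Shapley values
#'
#' Weighted-least-squares regression over feature coalitions with the
#' Shapley kernel weights; the efficiency constraint is built into the
#' regression, so `base_value + sum(phi) = f(x)` holds exactly.  When
#' `n_coalitions` covers the full lattice (2^m - 2 non-trivial coalitions)
#' the estimate coincides with [exact_shapley()].
#'
#' @inheritParams exact_shapley
#' @param n_coalitions coalition budget; must be at least m + 2.
#' @param seed seed for coalition sampling.
#' @return numeric `phi` with attribute `base_value`.
#' @export
kernel_shapley <- function(f, x, background, n_coalitions = NULL, seed = 1L) {
  m <- length(x)
  bg <- if (is.null(dim(background))) as.numeric(background)
        else colMeans(background)
  if (length(bg) != m) stop_sym("background width does not match x")
  v0 <- as.numeric(f(matrix(bg, 1)))
  fx <- as.numeric(f(matrix(x, 1)))
  if (m == 1) {
    phi <- fx - v0
    names(phi) <- names(x)
    attr(phi, "base_value") <- v0
    return(phi)
  }
  n_coalitions <- n_coalitions %||% min(2^m - 2, max(2 * m + 16, 128))
  if (n_coalitions < m + 2)
    stop_sym("n_coalitions (", n_coalitions, ") under-determines ", m,
             " features; need at least m + 2")
  des <- kernel_design(m, n_coalitions, seed)
  Z <- des$Z
  inputs <- Z * rep(x, each = nrow(Z)) + (1 - Z) * rep(bg, each = nrow(Z))
  colnames(inputs) <- names(x)
  v <- as.numeric(f(inputs))
  y_adj <- v - v0 - Z[, m] * (fx - v0)
  phi <- numeric(m)
  phi[-m] <- as.numeric(des$H %*% y_adj)
  phi[m] <- (fx - v0) - sum(phi[-m])
  names(phi) <- names(x)
  attr(phi, "base_value") <- v0
  phi
}

#' Attribute every output over a cohort
#'
#' Runs the Shapley decoder for each output's sub-model across all samples
#' of `x`.  The background is a seeded fixed-size subset of `x` (its column
#' means define absent-feature values); one coalition design is drawn per
#' call and reused for every sample, so the whole map is deterministic
#' given the seed.
#'
#' @param model a trained `omics_nn`.
#' @param x [omics_matrix()] aligned to the model's features.
#' @param outputs outputs to explain (indices or names; default all).
#' @param mode `"auto"` picks exact enumeration when the model has at most
#'   15 features, otherwise the kernel estimator.
#' @param background_size background subset size (capped at `nrow(x)`;
#'   requesting more is an error).
#' @param n_coalitions kernel coalition budget (default as in
#'   [kernel_shapley()]).
#' @param seed seed for background choice and coalition sampling.
#' @return list of `attribution_matrix` objects (one per output): each has
#'   `phi` (samples x features), `base_value`, `output_name`, and the
#'   background/coalition metadata.
#' @export
explain_all <- function(model, x, outputs = NULL,
                        mode = c("auto", "exact", "kernel"),
                        background_size = 100L, n_coalitions = NULL,
                        seed = 1L) {
  mode <- match.arg(mode)
  X <- as_omics_values(x)
  if (!is.null(model$feature_ids) && !identical(colnames(X), model$feature_ids)) {
    if (!all(model$feature_ids %in% colnames(X)))
      stop_sym("input lacks model features: ",
               fmt_ids(setdiff(model$feature_ids, colnames(X))))
    X <- X[, model$feature_ids, drop = FALSE]
  }
  n <- nrow(X); m <- ncol(X)
  if (background_size > n)
    stop_sym("background_size (", background_size, ") exceeds the ", n,
             " available samples")
  bg_rows <- if (background_size == n) seq_len(n)
             else with_seed(seed, sort(sample(n, background_size)))
  bg <- colMeans(X[bg_rows, , drop = FALSE])
  if (mode == "auto") mode <- if (m <= 15) "exact" else "kernel"
  if (mode == "exact" && m > 15)
    stop_sym("exact mode limited to 15 features; use mode = \"kernel\"")
  schema <- model$schema
  outputs <- outputs %||% seq_len(nrow(schema))
  if (is.character(outputs)) outputs <- match(outputs, schema$name)

  if (mode == "kernel") {
    n_coalitions <- n_coalitions %||% min(2^m - 2, max(2 * m + 16, 128))
    if (n_coalitions < m + 2)
      stop_sym("n_coalitions must be at least m + 2 = ", m + 2)
    des <- kernel_design(m, n_coalitions, seed)
    Zk <- des$Z
    masked <- lapply(seq_len(nrow(Zk)), function(r) {
      keep <- Zk[r, ] == 1L
      Xi <- X
      Xi[, !keep] <- rep(bg[!keep], each = n)
      Xi
    })
  } else {
    Ze <- coalition_matrix(m)
  }

  lapply(outputs, function(i) {
    f <- extract_submodel(model, i)
    fx <- as.numeric(f(X))
    v0 <- as.numeric(f(matrix(bg, 1, dimnames = list(NULL, colnames(X)))))
    phi <- matrix(0, n, m, dimnames = list(rownames(X), colnames(X)))
    if (mode == "kernel") {
      v <- vapply(masked, function(Xi) as.numeric(f(Xi)), numeric(n))  # n x coal
      y_adj <- t(v) - v0 - outer(Zk[, m], fx - v0)                     # coal x n
      phi[, -m] <- t(des$H %*% y_adj)
      phi[, m] <- (fx - v0) - rowSums(phi[, -m, drop = FALSE])
    } else {
      sizes <- rowSums(Ze)
      wt <- factorial(0:(m - 1)) * factorial(m - 1 - 0:(m - 1)) / factorial(m)
      masks <- seq(0, 2^m - 1)
      v <- vapply(seq_len(nrow(Ze)), function(r) {
        keep <- Ze[r, ] == 1L
        Xi <- X
        Xi[, !keep] <- rep(bg[!keep], each = n)
        as.numeric(f(Xi))
      }, numeric(n))  # n x 2^m
      for (j in seq_len(m)) {
        bit <- 2^(j - 1)
        without <- masks[bitwAnd(masks, bit) == 0L]
        s <- sizes[without + 1L]
        phi[, j] <- as.numeric(
          v[, without + bit + 1L, drop = FALSE] %*% wt[s + 1L] -
          v[, without + 1L, drop = FALSE] %*% wt[s + 1L])
      }
    }
    structure(list(output_name = schema$name[i], phi = phi, base_value = v0,
                   background = list(size = length(bg_rows), mean = bg,
                                     rows = bg_rows),
                   mode = mode,
                   n_coalitions = if (mode == "kernel") nrow(Zk) else 2^m,
                   seed = as.integer(seed)),
              class = "attribution_matrix")
  })
}

#' Split features into disease- and symptom-specific biomarkers
#'
#' Each output ranks features by mean |phi| over samples (ties broken
#' lexicographically by feature id).  A feature ranking in the top `top_k`
#' for at least `cutoff` of the outputs (>= comparison: 9 of 12 outputs
#' qualifies at the default 75% cutoff) is a *disease-specific* biomarker;
#' a feature in the top `top_k` of fewer outputs is *symptom-specific* for
#' exactly those outputs.
#'
#' @param attributions list of `attribution_matrix` (one per output), from
#'   [explain_all()].
#' @param top_k contributors counted per output (default 10).
#' @param cutoff fraction of outputs required for disease-specific status
#'   (default 0.75).
#' @return a `biomarker_catalog`: `disease_specific` (character vector),
#'   `symptom_specific` (named list output -> features), `counts` (top-k
#'   appearances per feature), `top_sets`, `top_k`, `cutoff`.
#' @export
categorize_biomarkers <- function(attributions, top_k = 10L, cutoff = 0.75) {
  if (length(attributions) < 2)
    stop_sym("need at least two outputs to categorize biomarkers")
  feats <- colnames(attributions[[1]]$phi)
  if (top_k > length(feats))
    stop_sym("top_k (", top_k, ") exceeds the ", length(feats), " features")
  top_sets <- lapply(attributions, function(a) {
    imp <- colMeans(abs(a$phi))
    feats[order(-imp, feats)][seq_len(top_k)]
  })
  names(top_sets) <- vapply(attributions, `[[`, "", "output_name")
  counts <- table(factor(unlist(top_sets), levels = feats))
  n_out <- length(attributions)
  disease <- feats[counts >= cutoff * n_out - 1e-9]
  symptom <- lapply(top_sets, function(s) setdiff(s, disease))
  structure(list(disease_specific = disease,
                 symptom_specific = symptom,
                 counts = counts[counts > 0],
                 top_sets = top_sets,
                 top_k = as.integer(top_k), cutoff = cutoff,
                 n_outputs = n_out),
            class = "biomarker_catalog")
}

#' @export
print.biomarker_catalog <- function(x, ...) {
  cat(sprintf("<biomarker_catalog> top_k=%d cutoff=%.0f%%: %d disease-specific, %d symptom-specific assignments\n",
              x$top_k, 100 * x$cutoff, length(x$disease_specific),
              sum(lengths(x$symptom_specific))))
  invisible(x)
}

#' Variance explained by biomarker categories
#'
#' Decomposes one output's predictions into the share explained by the
#' summed attributions of disease-specific biomarkers, the incremental
#' share added by that output's symptom-specific biomarkers, and the
#' residual.  Shares are incremental R-squared values and sum to 1.
#'
#' @param attribution an `attribution_matrix` for the output.
#' @param catalog a [categorize_biomarkers()] result.
#' @param predictions the sub-model's predictions for the same samples.
#' @return named numeric vector `c(disease, symptom, residual)`.
#' @export
variance_decomposition <- function(attribution, catalog, predictions) {
  stopifnot(length(predictions) == nrow(attribution$phi))
  if (stats::var(predictions) < 1e-20)
    return(c(disease = 0, symptom = 0, residual = 1))
  out <- attribution$output_name
  d_feats <- intersect(catalog$disease_specific, colnames(attribution$phi))
  s_feats <- intersect(catalog$symptom_specific[[out]] %||% character(),
                       colnames(attribution$phi))
  x1 <- if (length(d_feats)) rowSums(attribution$phi[, d_feats, drop = FALSE]) else NULL
  x2 <- if (length(s_feats)) rowSums(attribution$phi[, s_feats, drop = FALSE]) else NULL
  r2 <- function(design) {
    if (is.null(design)) return(0)
    fit <- stats::lm.fit(cbind(1, design), predictions)
    1 - sum(fit$residuals^2) / sum((predictions - mean(predictions))^2)
  }
  r2_d <- r2(x1)
  r2_ds <- r2(if (is.null(x1)) x2 else cbind(x1, x2))
  shares <- c(disease = max(r2_d, 0),
              symptom = max(r2_ds - r2_d, 0))
  shares <- pmin(shares, 1)
  c(shares, residual = max(1 - sum(shares), 0))
}
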