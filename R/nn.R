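#' Network architecture specification
#'
#' The model is a fully connected multi-task network: a standardization
#' (normalization) layer, two shared hidden layers Z1 (64 nodes) and Z2
#' (32 nodes) capturing disease-general structure, then one parallel
#' 8-node sub-layer per output capturing symptom-specific structure, each
#' feeding a typed head (sigmoid for binary, softmax for categorical,
#' linear for continuous scores).  ReLU activations throughout; dropout
#' after Z1 and Z2 at train time; L2 weight decay on kernel matrices only.
#'
#' @param n_features input width.
#' @param schema a [score_schema()]; one sub-layer and head per output.
#' @param width_z1,width_z2 shared layer widths (defaults 64 and 32).
#' @param width_z3 nodes per parallel sub-layer (default 8).
#' @param dropout dropout rate after Z1 and Z2 (default 0.5).
#' @param dropout_z3 also apply dropout after each sub-layer (default FALSE;
#'   the architecture diagram places dropout on the shared layers only).
#' @param l2_lambda L2 penalty coefficient on kernels (default 0.008).
#' @param use_z3 set FALSE for the ablated variant whose heads attach
#'   directly to Z2 (the "DNN" baseline).
#' @return an `architecture_spec` list.
#' @export
architecture_spec <- function(n_features, schema, width_z1 = 64L,
                              width_z2 = 32L, width_z3 = 8L,
                              dropout = 0.5, dropout_z3 = FALSE,
                              l2_lambda = 0.008, use_z3 = TRUE) {
  stopifnot(inherits(schema, "score_schema"))
  if (nrow(schema) < 1) stop_sym("schema declares zero outputs")
  if (min(width_z1, width_z2, width_z3) < 1) stop_sym("layer widths must be > 0")
  if (dropout < 0 || dropout >= 1) stop_sym("dropout must be in [0, 1)")
  if (l2_lambda < 0) stop_sym("l2_lambda must be >= 0")
  structure(list(n_features = as.integer(n_features), schema = schema,
                 width_z1 = as.integer(width_z1), width_z2 = as.integer(width_z2),
                 width_z3 = as.integer(width_z3), dropout = dropout,
                 dropout_z3 = dropout_z3, l2_lambda = l2_lambda,
                 use_z3 = isTRUE(use_z3)),
            class = "architecture_spec")
}

#' Training hyperparameters
#'
#' Defaults follow the grid-searched training configuration: Adam with
#' learning rate 5e-4 (beta1 0.9, beta2 0.999, epsilon 1e-7), 500 epochs,
#' batch size 64.  The Huber delta for continuous-score losses defaults
#' to 1.
#'
#' @param learning_rate Adam step size.
#' @param epochs,batch_size training schedule.
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @param huber_delta threshold between the quadratic and linear regimes of
#'   the continuous-score loss.
#' @param seed controls initialization, shuffling and dropout masks.
#' @return a `hyperparams` list.
#' @export
hyperparams <- function(learning_rate = 5e-4, epochs = 500L, batch_size = 64L,
                        beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                        huber_delta = 1, seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1, huber_delta > 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon, huber_delta = huber_delta,
                 seed = as.integer(seed)),
            class = "hyperparams")
}

head_dim <- function(schema, i) {
  if (schema$dtype[i] == "categorical") schema$n_levels[i] else 1L
}

he_normal <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

#' Build an untrained model
#'
#' Allocates all weights with He-normal initialization.  Shared layers draw
#' from a stream seeded by `seed`; each output's sub-layer and head draw
#' from a stream seeded by `seed` plus a hash of the output's *name*, so
#' that reordering outputs in the schema permutes the heads without
#' changing any output's own initialization.
#'
#' @param arch an [architecture_spec()].
#' @param seed integer seed.
#' @return an `omics_nn` model (untrained).
#' @export
build_model <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "architecture_spec"))
  schema <- arch$schema
  w <- with_seed(seed, {
    list(W1 = he_normal(arch$n_features, arch$width_z1),
         b1 = numeric(arch$width_z1),
         W2 = he_normal(arch$width_z1, arch$width_z2),
         b2 = numeric(arch$width_z2))
  })
  for (i in seq_len(nrow(schema))) {
    d <- head_dim(schema, i)
    wi <- with_seed(str_seed(schema$name[i], seed), {
      if (arch$use_z3)
        list(W3 = he_normal(arch$width_z2, arch$width_z3),
             b3 = numeric(arch$width_z3),
             W4 = he_normal(arch$width_z3, d), b4 = numeric(d))
      else
        list(W4 = he_normal(arch$width_z2, d), b4 = numeric(d))
    })
    for (nm in names(wi)) w[[paste0(nm, "_", i)]] <- wi[[nm]]
  }
  structure(list(arch = arch, schema = schema, weights = w, stats = NULL,
                 feature_ids = NULL, trained = FALSE, history = NULL,
                 seed = as.integer(seed)),
            class = "omics_nn")
}

#' @export
print.omics_nn <- function(x, ...) {
  cat(sprintf("<omics_nn> %d features -> Z1(%d) -> Z2(%d) -> %s -> %d outputs; %s, %s params\n",
              x$arch$n_features, x$arch$width_z1, x$arch$width_z2,
              if (x$arch$use_z3) sprintf("%d x Z3(%d)", nrow(x$schema), x$arch$width_z3)
              else "(no Z3)",
              nrow(x$schema), if (x$trained) "trained" else "untrained",
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model an `omics_nn`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) sum(vapply(model$weights, length, 1L))

#' Loss assigned to an output type
#'
#' Losses are assigned dynamically by output type: binary cross-entropy,
#' categorical cross-entropy over the C one-hot levels, and the Huber loss
#' for continuous scores.
#'
#' @param dtype `"binary"`, `"categorical"` or `"continuous"` (a schema row
#'   is also accepted).
#' @return `"bce"`, `"cce"` or `"huber"`.
#' @export
assign_loss <- function(dtype) {
  if (is.data.frame(dtype)) dtype <- dtype$dtype[1]
  switch(dtype,
         binary = "bce", categorical = "cce", continuous = "huber",
         stop_sym("unknown output dtype '", dtype, "'"))
}

#' Huber loss
#'
#' Quadratic for errors within `delta`, linear beyond:
#' `0.5 e^2` if `|e| <= delta`, else `delta (|e| - 0.5 delta)`, `e = y - yhat`.
#'
#' @param y,yhat true and predicted values (vectorized).
#' @param delta positive threshold.
#' @return elementwise loss.
#' @export
huber_loss <- function(y, yhat, delta = 1) {
  stopifnot(delta > 0)
  e <- y - yhat
  ifelse(abs(e) <= delta, 0.5 * e^2, delta * (abs(e) - 0.5 * delta))
}

relu <- function(x) x * (x > 0)

softmax_rows <- function(h) {
  h <- h - apply(h, 1, max)
  e <- exp(h)
  e / rowSums(e)
}

# One forward pass.  `masks` (from make_dropout_masks) enables train-time
# dropout; NULL means inference.  Returns all intermediates for backprop.
nn_forward <- function(weights, arch, X, masks = NULL) {
  pre1 <- sweep(X %*% weights$W1, 2, weights$b1, "+")
  A1 <- relu(pre1)
  A1d <- if (!is.null(masks)) A1 * masks$M1 else A1
  pre2 <- sweep(A1d %*% weights$W2, 2, weights$b2, "+")
  A2 <- relu(pre2)
  A2d <- if (!is.null(masks)) A2 * masks$M2 else A2
  n_out <- nrow(arch$schema)
  pre3 <- A3 <- A3d <- H <- out <- vector("list", n_out)
  for (i in seq_len(n_out)) {
    if (arch$use_z3) {
      pre3[[i]] <- sweep(A2d %*% weights[[paste0("W3_", i)]], 2,
                         weights[[paste0("b3_", i)]], "+")
      A3[[i]] <- relu(pre3[[i]])
      A3d[[i]] <- if (!is.null(masks) && arch$dropout_z3)
        A3[[i]] * masks$M3[[i]] else A3[[i]]
      hin <- A3d[[i]]
    } else hin <- A2d
    H[[i]] <- sweep(hin %*% weights[[paste0("W4_", i)]], 2,
                    weights[[paste0("b4_", i)]], "+")
    out[[i]] <- switch(arch$schema$dtype[i],
                       binary = stats::plogis(H[[i]]),
                       categorical = softmax_rows(H[[i]]),
                       continuous = H[[i]])
  }
  list(pre1 = pre1, A1 = A1, A1d = A1d, pre2 = pre2, A2 = A2, A2d = A2d,
       pre3 = pre3, A3 = A3, A3d = A3d, H = H, out = out)
}

make_dropout_masks <- function(arch, n) {
  if (arch$dropout == 0) return(NULL)
  keep <- 1 - arch$dropout
  draw <- function(k) matrix(stats::rbinom(n * k, 1, keep) / keep, n, k)
  m <- list(M1 = draw(arch$width_z1), M2 = draw(arch$width_z2))
  if (arch$dropout_z3 && arch$use_z3)
    m$M3 <- lapply(seq_len(nrow(arch$schema)), function(i) draw(arch$width_z3))
  m
}

# Encode a score matrix for the loss: per output the observation mask,
# target vector and (categorical) one-hot matrix.
encode_targets <- function(Y, schema) {
  lapply(seq_len(nrow(schema)), function(i) {
    y <- Y[, schema$name[i]]
    obs <- !is.na(y)
    enc <- list(dtype = schema$dtype[i], y = y, obs = obs, n_obs = sum(obs))
    if (schema$dtype[i] == "categorical") {
      C <- schema$n_levels[i]
      oh <- matrix(0, length(y), C)
      oh[cbind(which(obs), y[obs] + 1L)] <- 1
      enc$onehot <- oh
    }
    enc
  })
}

# Loss and full gradient in one backward pass.  Total loss is the
# weighted sum of per-output mean losses (missing scores masked; unit
# weights by default) plus (lambda/2) * sum of squared kernel weights;
# biases are not penalized.
nn_loss_grad <- function(weights, arch, X, enc, masks = NULL, huber_delta = 1,
                         want_grad = TRUE, loss_weights = NULL) {
  if (is.null(loss_weights)) loss_weights <- rep(1, nrow(arch$schema))
  fw <- nn_forward(weights, arch, X, masks)
  n_out <- nrow(arch$schema)
  per_loss <- numeric(n_out)
  g <- if (want_grad) lapply(weights, function(w) w * 0) else NULL
  dA2d <- matrix(0, nrow(X), arch$width_z2)
  epsl <- 1e-12
  for (i in seq_len(n_out)) {
    e <- enc[[i]]
    H <- fw$H[[i]]; out <- fw$out[[i]]
    N <- max(e$n_obs, 1L)
    w_obs <- as.numeric(e$obs)
    dH <- switch(e$dtype,
      binary = {
        p <- pmin(pmax(out[, 1], epsl), 1 - epsl)
        per_loss[i] <- sum(w_obs * -(e$y * log(p) + (1 - e$y) * log(1 - p)),
                           na.rm = TRUE) / N
        matrix(w_obs * (out[, 1] - ifelse(e$obs, e$y, 0)) / N, ncol = 1)
      },
      categorical = {
        p <- pmin(pmax(out, epsl), 1)
        per_loss[i] <- -sum(w_obs * rowSums(e$onehot * log(p))) / N
        (out - e$onehot) * (w_obs / N)
      },
      continuous = {
        err <- ifelse(e$obs, e$y - H[, 1], 0)
        per_loss[i] <- sum(w_obs * huber_loss(ifelse(e$obs, e$y, 0),
                                              ifelse(e$obs, H[, 1], 0),
                                              huber_delta)) / N
        matrix(w_obs * -pmin(pmax(err, -huber_delta), huber_delta) / N, ncol = 1)
      })
    if (!want_grad) next
    dH <- dH * loss_weights[i]
    if (arch$use_z3) {
      hin <- fw$A3d[[i]]
      g[[paste0("W4_", i)]] <- crossprod(hin, dH)
      g[[paste0("b4_", i)]] <- colSums(dH)
      dA3d <- dH %*% t(weights[[paste0("W4_", i)]])
      if (!is.null(masks) && arch$dropout_z3) dA3d <- dA3d * masks$M3[[i]]
      dZ3 <- dA3d * (fw$pre3[[i]] > 0)
      g[[paste0("W3_", i)]] <- crossprod(fw$A2d, dZ3)
      g[[paste0("b3_", i)]] <- colSums(dZ3)
      dA2d <- dA2d + dZ3 %*% t(weights[[paste0("W3_", i)]])
    } else {
      g[[paste0("W4_", i)]] <- crossprod(fw$A2d, dH)
      g[[paste0("b4_", i)]] <- colSums(dH)
      dA2d <- dA2d + dH %*% t(weights[[paste0("W4_", i)]])
    }
  }
  lam <- arch$l2_lambda
  kernels <- grep("^W", names(weights), value = TRUE)
  l2 <- if (lam > 0) 0.5 * lam * sum(vapply(kernels, function(k)
    sum(weights[[k]]^2), 0)) else 0
  loss <- sum(per_loss * loss_weights) + l2
  if (!want_grad)
    return(list(loss = loss, per_output = per_loss, grads = NULL, forward = fw))
  dA2 <- if (!is.null(masks)) dA2d * masks$M2 else dA2d
  dZ2 <- dA2 * (fw$pre2 > 0)
  g$W2 <- crossprod(fw$A1d, dZ2)
  g$b2 <- colSums(dZ2)
  dA1d <- dZ2 %*% t(weights$W2)
  dA1 <- if (!is.null(masks)) dA1d * masks$M1 else dA1d
  dZ1 <- dA1 * (fw$pre1 > 0)
  g$W1 <- crossprod(X, dZ1)
  g$b1 <- colSums(dZ1)
  if (lam > 0) for (k in kernels) g[[k]] <- g[[k]] + lam * weights[[k]]
  list(loss = loss, per_output = per_loss, grads = g, forward = fw)
}

#' Train the multi-output network
#'
#' Mini-batch Adam on the summed multi-output loss.  When
#' `standardize_input` is TRUE (default) the normalization layer is fitted
#' on the training data and stored in the model; prediction then applies
#' the stored statistics, so test and external data are transformed with
#' the train-fitted mean and variance.
#'
#' @param model an `omics_nn` from [build_model()].
#' @param x training [omics_matrix()] (samples x features).
#' @param y a [score_matrix()] aligned to `x` by sample id.
#' @param hp a [hyperparams()].
#' @param sample_idx optional integer subset of samples to train on (e.g.
#'   one under-sampling iteration from [rus_plan()]).
#' @param standardize_input fit and store normalization statistics (TRUE),
#'   or assume `x` is already standardized (FALSE).
#' @param loss_normalization `"none"` (default) sums the per-output losses
#'   with unit weights; `"null"` divides each output's loss by the loss of
#'   its best constant predictor (mean for Huber, base rate for binary
#'   cross-entropy, class frequencies for categorical cross-entropy),
#'   computed from the training scores before fitting.  Null normalization
#'   equalizes the gradient pressure the twelve symptoms exert on the
#'   shared layers, which otherwise is dominated by the cross-entropy
#'   heads (their losses are an order of magnitude larger than a Huber
#'   loss on 0-1 scores).
#' @return the trained model, with `$history` an (epochs x outputs+1) matrix
#'   of per-epoch mean batch losses (last column = total incl. L2).
#' @export
train_model <- function(model, x, y, hp = hyperparams(), sample_idx = NULL,
                        standardize_input = TRUE,
                        loss_normalization = c("none", "null")) {
  loss_normalization <- match.arg(loss_normalization)
  stopifnot(inherits(model, "omics_nn"), inherits(hp, "hyperparams"))
  X <- as_omics_values(x)
  if (ncol(X) != model$arch$n_features)
    stop_sym("input width ", ncol(X), " does not match architecture (",
             model$arch$n_features, ")")
  Y <- if (inherits(y, "score_matrix")) y$values else y
  if (!identical(rownames(X), rownames(Y))) {
    if (!setequal(rownames(X), rownames(Y)))
      stop_sym("samples of x and y do not match")
    Y <- Y[rownames(X), , drop = FALSE]
  }
  if (!is.null(sample_idx)) {
    X <- X[sample_idx, , drop = FALSE]
    Y <- Y[sample_idx, , drop = FALSE]
  }
  if (standardize_input) {
    st <- standardize(omics_matrix_nocheck(X), NULL)
    X <- st$x$values
    model$stats <- st$stats
  }
  model$feature_ids <- colnames(X)
  arch <- model$arch
  enc_all <- encode_targets(Y, model$schema)
  loss_weights <- if (loss_normalization == "null")
    1 / pmax(null_losses(Y, model$schema, hp$huber_delta), 1e-3)
  else rep(1, nrow(model$schema))
  n <- nrow(X)
  w <- model$weights
  mstate <- lapply(w, function(z) z * 0)
  vstate <- lapply(w, function(z) z * 0)
  t_step <- 0
  n_out <- nrow(model$schema)
  history <- matrix(NA_real_, hp$epochs, n_out + 1,
                    dimnames = list(NULL, c(model$schema$name, "total")))
  with_seed(hp$seed, {
    for (epoch in seq_len(hp$epochs)) {
      perm <- sample(n)
      starts <- seq(1, n, by = hp$batch_size)
      ep_loss <- numeric(n_out + 1)
      for (s in starts) {
        idx <- perm[s:min(s + hp$batch_size - 1, n)]
        Xb <- X[idx, , drop = FALSE]
        encb <- lapply(enc_all, function(e) {
          eb <- list(dtype = e$dtype, y = e$y[idx], obs = e$obs[idx],
                     n_obs = sum(e$obs[idx]))
          if (!is.null(e$onehot)) eb$onehot <- e$onehot[idx, , drop = FALSE]
          eb
        })
        masks <- make_dropout_masks(arch, length(idx))
        lg <- nn_loss_grad(w, arch, Xb, encb, masks, hp$huber_delta,
                           loss_weights = loss_weights)
        if (!is.finite(lg$loss))
          stop_sym("non-finite loss at epoch ", epoch,
                   "; try a lower learning rate")
        t_step <- t_step + 1
        corr1 <- 1 - hp$beta1^t_step
        corr2 <- 1 - hp$beta2^t_step
        for (k in names(w)) {
          gk <- lg$grads[[k]]
          mstate[[k]] <- hp$beta1 * mstate[[k]] + (1 - hp$beta1) * gk
          vstate[[k]] <- hp$beta2 * vstate[[k]] + (1 - hp$beta2) * gk^2
          w[[k]] <- w[[k]] - hp$learning_rate * (mstate[[k]] / corr1) /
            (sqrt(vstate[[k]] / corr2) + hp$epsilon)
        }
        ep_loss <- ep_loss + c(lg$per_output, lg$loss)
      }
      history[epoch, ] <- ep_loss / length(starts)
    }
  })
  model$weights <- w
  model$trained <- TRUE
  model$history <- history
  model$hp <- hp
  model$loss_weights <- loss_weights
  model
}

# Loss of the best constant predictor per output, used by the "null"
# loss normalization.
null_losses <- function(Y, schema, huber_delta = 1) {
  vapply(seq_len(nrow(schema)), function(i) {
    y <- Y[, schema$name[i]]
    y <- y[!is.na(y)]
    if (!length(y)) return(1)
    switch(schema$dtype[i],
      continuous = mean(huber_loss(y, mean(y), huber_delta)),
      binary = {
        p <- min(max(mean(y), 1e-6), 1 - 1e-6)
        -mean(y * log(p) + (1 - y) * log(1 - p))
      },
      categorical = {
        f <- table(factor(y, levels = seq(0, schema$n_levels[i] - 1))) / length(y)
        -sum(f[f > 0] * log(f[f > 0]))
      })
  }, 0)
}

# internal: wrap a plain matrix without re-validating (used on hot paths)
omics_matrix_nocheck <- function(v, kind = "combined") {
  structure(list(values = v, kind = kind), class = "omics_matrix")
}

#' Predict scores for new samples
#'
#' Runs the network in inference mode (dropout disabled).  If the model
#' stores normalization statistics they are applied first; the input must
#' already be aligned to the model's feature list (see [align_external()]).
#'
#' @param model a trained `omics_nn`.
#' @param x an [omics_matrix()] or matrix with the model's features.
#' @return a `score_predictions` object: `$scores` is a samples x outputs
#'   matrix of scalar summaries (continuous head value, binary probability,
#'   categorical expected level), `$probs` holds the full probability
#'   vectors for binary and categorical outputs.
#' @export
predict_scores <- function(model, x) {
  X <- as_omics_values(x)
  if (!is.null(model$feature_ids)) {
    if (!identical(colnames(X), model$feature_ids)) {
      if (!all(model$feature_ids %in% colnames(X)))
        stop_sym("input lacks model features: ",
                 fmt_ids(setdiff(model$feature_ids, colnames(X))))
      X <- X[, model$feature_ids, drop = FALSE]
    }
  } else if (ncol(X) != model$arch$n_features) {
    stop_sym("input width ", ncol(X), " does not match architecture (",
             model$arch$n_features, ")")
  }
  if (!is.null(model$stats)) {
    div <- ifelse(model$stats$sigma > 0, model$stats$sigma, 1)
    X <- sweep(sweep(X, 2, model$stats$mu), 2, div, "/")
  }
  fw <- nn_forward(model$weights, model$arch, X, masks = NULL)
  schema <- model$schema
  scores <- matrix(NA_real_, nrow(X), nrow(schema),
                   dimnames = list(rownames(X), schema$name))
  probs <- list()
  for (i in seq_len(nrow(schema))) {
    o <- fw$out[[i]]
    scores[, i] <- switch(schema$dtype[i],
      continuous = o[, 1],
      binary = o[, 1],
      categorical = as.numeric(o %*% seq(0, schema$n_levels[i] - 1)))
    if (schema$dtype[i] != "continuous") {
      rownames(o) <- rownames(X)
      probs[[schema$name[i]]] <- o
    }
  }
  structure(list(scores = scores, probs = probs, schema = schema),
            class = "score_predictions")
}

#' Finite-difference gradient check
#'
#' Compares the analytic gradient of the total multi-output loss against
#' central finite differences on a random subset of coordinates.
#'
#' @param model an `omics_nn`.
#' @param x numeric matrix of (standardized) inputs.
#' @param y a [score_matrix()] or matrix.
#' @param n_coords coordinates probed per parameter block.
#' @param eps finite-difference step.
#' @param huber_delta Huber threshold used in the loss.
#' @param seed seed for coordinate sampling.
#' @return maximum relative error across probed coordinates.
#' @export
gradient_check <- function(model, x, y, n_coords = 5L, eps = 1e-5,
                           huber_delta = 1, seed = 1L) {
  X <- as_omics_values(x)
  Y <- if (inherits(y, "score_matrix")) y$values else y
  enc <- encode_targets(Y, model$schema)
  arch <- model$arch
  w <- model$weights
  base <- nn_loss_grad(w, arch, X, enc, NULL, huber_delta)
  worst <- 0
  with_seed(seed, {
    for (k in names(w)) {
      nk <- length(w[[k]])
      for (j in sample(nk, min(n_coords, nk))) {
        wp <- w; wp[[k]][j] <- wp[[k]][j] + eps
        wm <- w; wm[[k]][j] <- wm[[k]][j] - eps
        num <- (nn_loss_grad(wp, arch, X, enc, NULL, huber_delta,
                             want_grad = FALSE)$loss -
                nn_loss_grad(wm, arch, X, enc, NULL, huber_delta,
                             want_grad = FALSE)$loss) / (2 * eps)
        ana <- base$grads[[k]][j]
        rel <- abs(num - ana) / max(abs(num), abs(ana), 1e-8)
        worst <- max(worst, rel)
      }
    }
  })
  worst
}
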