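test_that("the architecture matches its blueprint", {
  sch12 <- score_schema(sprintf("y%02d", 1:12), "continuous",
                        raw_min = 0, raw_max = 1)
  arch <- architecture_spec(100, sch12)
  m <- build_model(arch, seed = 1)
  w <- m$weights
  expect_equal(dim(w$W1), c(100, 64))
  expect_equal(dim(w$W2), c(64, 32))
  for (i in 1:12) {
    expect_equal(dim(w[[paste0("W3_", i)]]), c(32, 8))
    expect_equal(dim(w[[paste0("W4_", i)]]), c(8, 1))
  }
  # parameter count by enumeration equals the layer-shape arithmetic
  expect_equal(n_parameters(m),
               (100 * 64 + 64) + (64 * 32 + 32) +
                 12 * (32 * 8 + 8) + 12 * (8 * 1 + 1))
  expect_identical(n_parameters(m), 11820L)

  # He-normal initialization: mean ~ 0, sd ~ sqrt(2 / fan_in)
  expect_lt(abs(mean(w$W1)), 0.01)
  expect_equal(sd(w$W1), sqrt(2 / 100), tolerance = 0.05)
  expect_true(all(w$b1 == 0))

  # seeded determinism
  m2 <- build_model(arch, seed = 1)
  expect_identical(m$weights, m2$weights)
  expect_false(identical(build_model(arch, seed = 2)$weights, m$weights))

  expect_error(architecture_spec(10, sch12[0, ]), "zero outputs")
  expect_error(architecture_spec(10, sch12, dropout = 1), "dropout")
})

test_that("losses are assigned by output type and Huber is piecewise", {
  expect_identical(assign_loss("binary"), "bce")
  expect_identical(assign_loss("categorical"), "cce")
  expect_identical(assign_loss("continuous"), "huber")
  expect_error(assign_loss("count"), "unknown")

  expect_equal(huber_loss(1, 1, delta = 1), 0)
  expect_equal(huber_loss(0.5, 0, delta = 1), 0.125)
  expect_equal(huber_loss(3, 0, delta = 1), 2.5)
  # continuity at the elbow
  expect_equal(huber_loss(1 + 1e-9, 0, 1), huber_loss(1 - 1e-9, 0, 1),
               tolerance = 1e-6)
})

test_that("backpropagation matches finite differences on the fixture", {
  tf <- trained_fixture()
  Xs <- standardize(tf$omics)$x$values
  err <- gradient_check(tf$model, Xs, tf$scores, n_coords = 6, seed = 11)
  expect_lt(err, 1e-4)

  # and on a model with all three head types
  mh <- mixed_head_model()
  Xs2 <- standardize(mh$x)$x$values
  err2 <- gradient_check(mh$model, Xs2, mh$cohort$scores, n_coords = 4,
                         seed = 12)
  expect_lt(err2, 1e-4)
})

test_that("training reduces the loss and is reproducible", {
  tf <- trained_fixture()
  h <- tf$model$history
  expect_lt(h[nrow(h), "total"], h[1, "total"])
  expect_true(all(is.finite(h)))
  # retraining with the same seeds reproduces the history exactly
  arch <- architecture_spec(6, tf$scores$schema, width_z1 = 16,
                            width_z2 = 8, width_z3 = 4)
  again <- train_model(build_model(arch, seed = 1), tf$omics, tf$scores,
                       hyperparams(learning_rate = 5e-3, epochs = 60,
                                   batch_size = 4, seed = 2))
  expect_identical(again$history, h)
  expect_identical(again$weights, tf$model$weights)
})

test_that("the L2 penalty touches kernels only", {
  fx <- make_worked_fixture()
  arch <- architecture_spec(6, fx$scores$schema, width_z1 = 4, width_z2 = 3,
                            width_z3 = 2, l2_lambda = 0.5, dropout = 0)
  m <- build_model(arch, 1)
  # zero out all kernels, set biases large: penalty must be zero
  for (k in names(m$weights))
    m$weights[[k]] <- if (grepl("^W", k)) m$weights[[k]] * 0
                      else m$weights[[k]] + 10
  enc <- symptomics:::encode_targets(fx$scores$values, fx$scores$schema)
  X <- standardize(fx$omics)$x$values
  lg <- symptomics:::nn_loss_grad(m$weights, arch, X, enc)
  expect_equal(lg$loss, sum(lg$per_output))  # no L2 contribution
  # bias gradients carry no penalty term: with nonzero kernels the kernel
  # gradient picks up lambda * W while biases do not
  m2 <- build_model(arch, 1)
  lg2 <- symptomics:::nn_loss_grad(m2$weights, arch, X * 0, enc)
  lg0 <- symptomics:::nn_loss_grad(m2$weights,
                                   architecture_spec(6, fx$scores$schema,
                                                     width_z1 = 4, width_z2 = 3,
                                                     width_z3 = 2, l2_lambda = 0,
                                                     dropout = 0),
                                   X * 0, enc)
  expect_equal(lg2$grads$W1 - lg0$grads$W1, 0.5 * m2$weights$W1,
               ignore_attr = TRUE)
  expect_equal(lg2$grads$b1, lg0$grads$b1, ignore_attr = TRUE)
})

test_that("prediction obeys head semantics and is deterministic", {
  mh <- mixed_head_model()
  p <- predict_scores(mh$model, mh$x)
  sch <- mh$cohort$scores$schema
  catn <- sch$name[sch$dtype == "categorical"]
  binn <- sch$name[sch$dtype == "binary"]
  expect_lt(max(abs(rowSums(p$probs[[catn]]) - 1)), 1e-6)
  expect_true(all(p$probs[[binn]] > 0 & p$probs[[binn]] < 1))
  # duplicated input row predicts identically
  X2 <- mh$x$values[c(1, 1), , drop = FALSE]
  rownames(X2) <- c("a", "b")
  p2 <- predict_scores(mh$model, X2)
  expect_identical(p2$scores[1, ], p2$scores[2, ])
  # repeat call identical (no dropout at inference)
  expect_identical(predict_scores(mh$model, mh$x)$scores, p$scores)

  # all-zero weights with a continuous head predict exactly 0
  fx <- make_worked_fixture()
  arch <- architecture_spec(6, fx$scores$schema, width_z1 = 4, width_z2 = 3,
                            width_z3 = 2)
  m0 <- build_model(arch, 1)
  m0$weights <- lapply(m0$weights, function(w) w * 0)
  p0 <- predict_scores(m0, fx$omics$values)
  expect_true(all(p0$scores[, "pain"] == 0))
  expect_true(all(p0$probs$orthostatic_intolerance == 0.5))

  expect_error(predict_scores(m0, fx$omics$values[, 1:3]), "width|features")
})

test_that("dropout masks act at train time only", {
  fx <- make_worked_fixture()
  arch <- architecture_spec(6, fx$scores$schema, width_z1 = 16, width_z2 = 8,
                            width_z3 = 4, dropout = 0.5)
  masks <- symptomics:::with_seed(1,
    symptomics:::make_dropout_masks(arch, 12))
  expect_setequal(unique(as.vector(masks$M1)), c(0, 2))  # inverted dropout
  # forward with masks differs from inference forward
  m <- build_model(arch, 1)
  X <- standardize(fx$omics)$x$values
  f_inf <- symptomics:::nn_forward(m$weights, arch, X)
  f_tr <- symptomics:::nn_forward(m$weights, arch, X, masks)
  expect_false(isTRUE(all.equal(f_inf$out[[1]], f_tr$out[[1]])))
})

test_that("outputs are treated symmetrically: permuting the schema permutes
          heads without changing any output's trajectory", {
  fx <- make_worked_fixture()
  hp <- hyperparams(learning_rate = 5e-3, epochs = 8, batch_size = 4, seed = 2)
  arch1 <- architecture_spec(6, fx$scores$schema, width_z1 = 8, width_z2 = 4,
                             width_z3 = 2)
  m1 <- train_model(build_model(arch1, 1), fx$omics, fx$scores, hp)
  sch_rev <- fx$scores$schema[2:1, ]
  class(sch_rev) <- class(fx$scores$schema)
  y_rev <- score_matrix(fx$scores$values[, 2:1], sch_rev)
  arch2 <- architecture_spec(6, sch_rev, width_z1 = 8, width_z2 = 4,
                             width_z3 = 2)
  m2 <- train_model(build_model(arch2, 1), fx$omics, y_rev, hp)
  expect_equal(m1$history[, "pain"], m2$history[, "pain"], tolerance = 1e-8)
  expect_equal(m1$history[, "orthostatic_intolerance"],
               m2$history[, "orthostatic_intolerance"], tolerance = 1e-8)
  p1 <- predict_scores(m1, fx$omics$values)
  p2 <- predict_scores(m2, fx$omics$values)
  expect_equal(p1$scores[, "pain"], p2$scores[, "pain"], tolerance = 1e-8)
})

test_that("null loss normalization rescales the training objective", {
  fx <- make_worked_fixture()
  nl <- symptomics:::null_losses(fx$scores$values, fx$scores$schema)
  # binary null loss is the base-rate entropy
  p <- mean(fx$scores$values[, "orthostatic_intolerance"])
  expect_equal(nl[2], -(p * log(p) + (1 - p) * log(1 - p)), tolerance = 1e-12)
  arch <- architecture_spec(6, fx$scores$schema, width_z1 = 8, width_z2 = 4,
                            width_z3 = 2)
  m <- train_model(build_model(arch, 1), fx$omics, fx$scores,
                   hyperparams(learning_rate = 5e-3, epochs = 5,
                               batch_size = 4, seed = 2),
                   loss_normalization = "null")
  expect_equal(unname(m$loss_weights), unname(1 / pmax(nl, 1e-3)))
})

test_that("missing scores are masked out of the loss", {
  fx <- make_worked_fixture()
  Y <- fx$scores$values
  Y[1:3, "pain"] <- NA
  arch <- architecture_spec(6, fx$scores$schema, width_z1 = 8, width_z2 = 4,
                            width_z3 = 2, dropout = 0)
  m <- build_model(arch, 1)
  X <- standardize(fx$omics)$x$values
  enc_masked <- symptomics:::encode_targets(Y, fx$scores$schema)
  lg <- symptomics:::nn_loss_grad(m$weights, arch, X, enc_masked)
  # loss over observed samples only equals loss on the reduced data
  enc_sub <- symptomics:::encode_targets(Y[4:12, , drop = FALSE],
                                         fx$scores$schema)
  lg_sub <- symptomics:::nn_loss_grad(m$weights, arch, X[4:12, ], enc_sub)
  expect_equal(lg$per_output[1], lg_sub$per_output[1], tolerance = 1e-12)
})
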