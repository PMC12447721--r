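test_that("exact enumeration reproduces analytic Shapley values", {
  # single feature: phi is forced to f(x) - f(background)
  f1 <- function(X) 3 * X[, 1]
  expect_equal(as.numeric(exact_shapley(f1, c(x1 = 2), matrix(0, 1, 1))),
               6, tolerance = 1e-12)
  # additive model splits by coefficient
  f2 <- function(X) X[, 1] + 2 * X[, 2]
  phi <- exact_shapley(f2, c(a = 1, b = 1), matrix(0, 2, 2))
  expect_equal(as.numeric(phi), c(1, 2), tolerance = 1e-12)
  # pure interaction splits equally (symmetry axiom)
  f3 <- function(X) X[, 1] * X[, 2]
  phi3 <- exact_shapley(f3, c(1, 1), matrix(0, 2, 2))
  expect_equal(as.numeric(phi3), c(0.5, 0.5), tolerance = 1e-12)
  expect_error(exact_shapley(f2, rnorm(16), matrix(0, 1, 16)), "15")
})

test_that("exact Shapley satisfies the four axioms on small predictors", {
  set.seed(31)
  m <- 5
  bg <- matrix(rnorm(20 * m), 20, m)
  x <- rnorm(m)
  f <- function(X) X[, 1]^2 + 2 * X[, 2] * X[, 3] - X[, 4]
  g <- function(X) exp(X[, 1] / 2) + X[, 5]
  phi_f <- exact_shapley(f, x, bg)
  phi_g <- exact_shapley(g, x, bg)
  bgm <- colMeans(bg)
  # efficiency
  expect_equal(sum(phi_f) + attr(phi_f, "base_value"), f(matrix(x, 1)),
               tolerance = 1e-10)
  # dummy: feature 5 never enters f
  expect_equal(unname(phi_f[5]), 0, tolerance = 1e-12)
  # linearity: phi(f + g) = phi(f) + phi(g)
  phi_fg <- exact_shapley(function(X) f(X) + g(X), x, bg)
  expect_equal(as.numeric(phi_fg), as.numeric(phi_f + phi_g),
               tolerance = 1e-10)
  # symmetry: exchangeable features with equal values get equal phi
  fs <- function(X) X[, 1] * X[, 2]
  xs <- c(0.7, 0.7, rnorm(1))
  phis <- exact_shapley(fs, xs, matrix(0.1, 4, 3))
  expect_equal(unname(phis[1]), unname(phis[2]), tolerance = 1e-12)
})

test_that("the kernel estimator agrees with exact enumeration when the
          coalition lattice is fully enumerated", {
  set.seed(32)
  m <- 6
  bg <- matrix(rnorm(30 * m), 30, m)
  x <- rnorm(m)
  f <- function(X) X[, 1]^2 - X[, 2] * X[, 3] + 0.5 * X[, 4] + tanh(X[, 5])
  pe <- exact_shapley(f, x, bg)
  pk <- kernel_shapley(f, x, bg, n_coalitions = 2^m - 2)
  expect_lt(max(abs(pe - pk)), 1e-6)
  expect_equal(attr(pk, "base_value"), attr(pe, "base_value"))
  # local accuracy holds exactly for the estimator too
  expect_equal(sum(pk) + attr(pk, "base_value"), f(matrix(x, 1)),
               tolerance = 1e-9)
  # dummy feature 6 is zero
  expect_lt(abs(pk[6]), 1e-6)
  expect_error(kernel_shapley(f, x, bg, n_coalitions = m), "m \\+ 2")
})

test_that("sampled kernel estimates converge toward exact enumeration", {
  set.seed(33)
  m <- 8
  bg <- matrix(rnorm(25 * m), 25, m)
  x <- rnorm(m)
  f <- function(X) X[, 1] * X[, 2] + X[, 3]^2 - X[, 4] + 0.3 * X[, 5] * X[, 6]
  pe <- exact_shapley(f, x, bg)
  budgets <- c(2 * m + 4, 8 * m, 2^m - 2)
  devs <- sapply(budgets, function(b) {
    max(abs(kernel_shapley(f, x, bg, n_coalitions = b, seed = 7) - pe))
  })
  expect_true(all(diff(devs) <= 1e-9))  # monotone improvement
  expect_lt(devs[length(devs)], 1e-6)
})

test_that("sub-models agree exactly with the full model and leave it intact", {
  mh <- mixed_head_model()
  model <- mh$model
  before <- predict_scores(model, mh$x)$scores
  set.seed(34)
  Xr <- matrix(runif(100 * 10), 100, 10,
               dimnames = list(sprintf("r%03d", 1:100),
                               feature_ids(mh$x)))
  full <- predict_scores(model, Xr)$scores
  for (i in seq_len(nrow(model$schema))) {
    fi <- extract_submodel(model, i)
    expect_equal(unname(fi(Xr)), unname(full[, i]), tolerance = 1e-12)
  }
  expect_error(extract_submodel(model, 99), "out of range")
  # extraction did not mutate the model
  expect_identical(predict_scores(model, mh$x)$scores, before)
})

test_that("explain_all yields one locally-accurate matrix per output", {
  tf <- trained_fixture()
  att <- explain_all(tf$model, tf$omics, background_size = 12)
  expect_length(att, 2)
  for (i in seq_along(att)) {
    fi <- extract_submodel(tf$model, i)
    pred <- fi(tf$omics$values)
    recon <- att[[i]]$base_value + rowSums(att[[i]]$phi)
    expect_lt(max(abs(recon - pred)), 1e-9)  # exact mode
  }
  # deterministic repeat
  att2 <- explain_all(tf$model, tf$omics, background_size = 12)
  expect_identical(att[[1]]$phi, att2[[1]]$phi)
  # constant (all-zero-weight) model attributes nothing
  m0 <- tf$model
  m0$weights <- lapply(m0$weights, function(w) w * 0)
  att0 <- explain_all(m0, tf$omics, background_size = 12)
  expect_true(all(abs(att0[[1]]$phi) < 1e-12))
  expect_error(explain_all(tf$model, tf$omics, background_size = 99),
               "background")
  # kernel mode agrees with exact on the same model
  attk <- explain_all(tf$model, tf$omics, mode = "kernel",
                      background_size = 12, n_coalitions = 2^6 - 2)
  expect_lt(max(abs(attk[[1]]$phi - att[[1]]$phi)), 1e-6)
})

test_that("biomarker categorization applies the top-k / cutoff rule", {
  feats <- paste0("f", 1:6)
  mk_att <- function(name, imp) {
    phi <- matrix(rep(imp, each = 4), 4, length(imp),
                  dimnames = list(paste0("s", 1:4), feats))
    structure(list(output_name = name, phi = phi, base_value = 0),
              class = "attribution_matrix")
  }
  # f1 is top-2 in 9 of 12 outputs (exactly 75%), f2 in all, f3 in 1, f4 never
  atts <- lapply(1:12, function(i) {
    imp <- c(f1 = if (i <= 9) 10 else 0.1, f2 = 9,
             f3 = if (i == 1) 20 else 0, f4 = 0.01,
             f5 = if (i > 9) 8 else 0.5, f6 = if (i > 1 & i <= 9) 7 else 0.2)
    mk_att(paste0("y", i), imp)
  })
  ct <- categorize_biomarkers(atts, top_k = 2, cutoff = 0.75)
  expect_true("f1" %in% ct$disease_specific)     # 9/12 boundary qualifies
  expect_true("f2" %in% ct$disease_specific)
  expect_false("f3" %in% ct$disease_specific)
  expect_true("f3" %in% ct$symptom_specific$y1)  # single-output contributor
  expect_false("f4" %in% unlist(ct$symptom_specific))  # never ranks
  expect_false("f4" %in% ct$disease_specific)
  # disease and symptom sets are disjoint per output
  for (nm in names(ct$symptom_specific))
    expect_length(intersect(ct$symptom_specific[[nm]], ct$disease_specific), 0)
  expect_error(categorize_biomarkers(atts, top_k = 10), "features")
  expect_error(categorize_biomarkers(atts[1], top_k = 2), "two outputs")
})

test_that("tie-broken ranking is lexicographic in the feature id", {
  feats <- c("b_feat", "a_feat", "c_feat")
  phi <- matrix(1, 3, 3, dimnames = list(NULL, feats))  # all-equal importance
  atts <- lapply(1:2, function(i)
    structure(list(output_name = paste0("y", i), phi = phi, base_value = 0),
              class = "attribution_matrix"))
  ct <- categorize_biomarkers(atts, top_k = 2, cutoff = 0.75)
  expect_identical(ct$top_sets$y1, c("a_feat", "b_feat"))
})

test_that("variance decomposition sums to one and honours degenerate cases", {
  set.seed(35)
  n <- 60
  feats <- c("d1", "d2", "s1", "n1")
  phi <- cbind(d1 = rnorm(n), d2 = rnorm(n), s1 = rnorm(n), n1 = rnorm(n) * 0.01)
  rownames(phi) <- paste0("s", 1:n)
  att <- structure(list(output_name = "y1", phi = phi, base_value = 0.2),
                   class = "attribution_matrix")
  catg <- structure(list(disease_specific = c("d1", "d2"),
                         symptom_specific = list(y1 = "s1"),
                         top_k = 3, cutoff = 0.75),
                    class = "biomarker_catalog")
  pred <- 0.2 + rowSums(phi)  # local accuracy => full reconstruction
  sh <- variance_decomposition(att, catg, pred)
  expect_equal(sum(sh), 1, tolerance = 1e-9)
  expect_true(all(sh >= 0 & sh <= 1))
  expect_gt(sh["disease"], 0.4)
  expect_gt(sh["symptom"], 0.1)
  # constant predictor
  expect_identical(variance_decomposition(att, catg, rep(1, n)),
                   c(disease = 0, symptom = 0, residual = 1))
})

test_that("attributions recover the planted shared block on a strong cohort", {
  # small, fast end-to-end check: one assay, strong shared signal
  co <- simulate_cohort(sim_config(n_samples = 150, n_species = 0, n_kegg = 0,
                                   n_immune = 12, n_metabolome = 0, n_blood = 0,
                                   n_shared_biomarkers = 3,
                                   n_specific_per_output = 0,
                                   effect_size = 2, noise_sd = 0.3, seed = 6))
  x <- co$omics$immune
  arch <- architecture_spec(12, co$scores$schema, width_z1 = 24, width_z2 = 12,
                            width_z3 = 4)
  m <- train_model(build_model(arch, 1), x, co$scores,
                   hyperparams(learning_rate = 5e-3, epochs = 150, seed = 1))
  att <- explain_all(m, x, background_size = 100, seed = 1)
  ct <- categorize_biomarkers(att, top_k = 3, cutoff = 0.75)
  shared <- co$truth$features$feature_id
  expect_gte(mean(shared %in% ct$disease_specific), 2 / 3)
  # the shared block dominates the variance of most outputs
  sub <- extract_submodel(m, 3)
  sh <- variance_decomposition(att[[3]], ct, sub(x$values))
  expect_gt(sh["disease"], 0.5)
})
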