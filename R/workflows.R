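#' Desk-scale evaluation workflows
#'
#' These functions bundle the package's standard simulation benchmarks so
#' that tests, scripts and users run exactly the same recipes.  Problem
#' sizes and schedules are the package's desk-scale defaults (documented in
#' the methods vignette); the underlying study conditions — cohort size
#' 300, 2:1 imbalance, planted effect sizes and noise — are fixed by the
#' synthetic-cohort generator.
#'
#' `run_signal_benchmark` runs the two-stage headline recipe on a strong
#' signal cohort: per-assay models are decoded into attributions, the top
#' features of each assay form a combined panel, and the panel model is
#' evaluated by stratified 5-fold cross-validation with random
#' under-sampling; the score layer collapses predicted scores into a
#' disease probability.
#'
#' @param seed integer seed for the cohort and all model fits.
#' @param effect_size,noise_sd planted contribution SD and severity noise.
#' @param two_stage run attribution-based panel selection before the
#'   cross-validated fit (TRUE, the headline recipe); FALSE evaluates the
#'   full concatenated matrix directly (used for null cohorts, where
#'   selection has nothing to find).
#' @param top_counts features kept per assay by the panel selection.
#' @param epochs_select,epochs_cv,learning_rate,rus_iter,k schedule knobs.
#' @return list with `pooled_auc`, `mse` (mean per-output CV MSE),
#'   `score_var` (per-output score variance), `cv` (the full `cv_report`)
#'   and, for the two-stage recipe, `panel` feature ids.
#' @export
run_signal_benchmark <- function(seed, effect_size = 2, noise_sd = 0.5,
                                 two_stage = TRUE,
                                 top_counts = c(species = 12, kegg = 12,
                                                immune = 10, metabolome = 10,
                                                blood = 4),
                                 epochs_select = 250L, epochs_cv = 200L,
                                 learning_rate = 2e-3, rus_iter = 2L,
                                 k = 5L) {
  cohort <- simulate_cohort(sim_config(effect_size = effect_size,
                                       noise_sd = noise_sd, seed = seed))
  if (two_stage) {
    sel <- select_combined_panel(
      cohort$omics, cohort$scores, top_counts,
      hp = hyperparams(learning_rate = learning_rate,
                       epochs = epochs_select, seed = seed),
      seed = seed)
    x <- sel$combined
  } else {
    x <- cohort_combined(cohort)
  }
  cv <- evaluate_cv(x, cohort$scores, cohort$labels,
                    hyperparams(learning_rate = learning_rate,
                                epochs = epochs_cv, seed = seed),
                    k = k, rus_iter = rus_iter, seed = seed)
  list(pooled_auc = cv$pooled_auc,
       mse = colMeans(cv$mse),
       score_var = apply(cohort$scores$values, 2, stats::var),
       cv = cv,
       panel = if (two_stage) feature_ids(x) else NULL)
}

#' @rdname run_signal_benchmark
#' @details `run_biomarker_recovery` plants 10 shared and 3-per-output
#'   specific effects, trains one model per assay, decodes each into
#'   attributions, categorizes biomarkers within each assay
#'   ([categorize_biomarkers()], the per-assay reading of the reference
#'   analysis) and unions the results, then scores them against the
#'   generator's ground truth.  Assays with at most `top_k` features are
#'   skipped (every feature would be a top contributor).
#' @param top_k,cutoff categorization parameters.
#' @param epochs,n_coalitions model schedule and attribution budget.
#' @export
run_biomarker_recovery <- function(seed, effect_size = 2, noise_sd = 0.5,
                                   top_k = 10L, cutoff = 0.75,
                                   epochs = 400L, learning_rate = 2e-3,
                                   n_coalitions = 512L) {
  cohort <- simulate_cohort(sim_config(
    n_shared_biomarkers = 10, n_specific_per_output = 3,
    effect_size = effect_size, noise_sd = noise_sd, seed = seed))
  truth <- cohort$truth$features
  disease_all <- character()
  symptom_all <- list()
  for (kind in names(cohort$omics)) {
    xk <- cohort$omics[[kind]]
    if (ncol(xk$values) <= top_k) next
    arch <- architecture_spec(ncol(xk$values), cohort$scores$schema)
    mk <- train_model(build_model(arch, seed),
                      xk, cohort$scores,
                      hyperparams(learning_rate = learning_rate,
                                  epochs = epochs, seed = seed))
    att <- explain_all(mk, xk,
                       mode = if (ncol(xk$values) <= 15) "exact" else "kernel",
                       background_size = min(100L, nrow(xk$values)),
                       n_coalitions = n_coalitions, seed = seed)
    ct <- categorize_biomarkers(att, top_k = top_k, cutoff = cutoff)
    disease_all <- union(disease_all, ct$disease_specific)
    for (nm in names(ct$symptom_specific))
      symptom_all[[nm]] <- union(symptom_all[[nm]], ct$symptom_specific[[nm]])
  }
  shared <- truth$feature_id[truth$scope == "shared"]
  spec <- truth[truth$scope == "specific", ]
  spec_hit <- mapply(function(f, tgt) f %in% symptom_all[[tgt]],
                     spec$feature_id, spec$target)
  list(shared_recovery = mean(shared %in% disease_all),
       specific_recovery = mean(spec_hit),
       specific_by_shape = tapply(spec_hit, spec$shape, mean),
       n_false_disease = length(setdiff(disease_all, shared)),
       disease_specific = disease_all,
       symptom_specific = symptom_all)
}

#' @rdname run_signal_benchmark
#' @details `run_external_benchmark` trains a single-assay model plus score
#'   layer on a training cohort (metabolome, 100 features so that the
#'   printed overlap fractions are exact), then simulates external cohorts
#'   at decreasing feature overlap, aligns them ([align_external()], zero
#'   imputation) and reports coverage and AUC per overlap, averaged over
#'   external draws.
#' @param overlaps overlap fractions to probe.
#' @param n_external external cohort draws averaged per overlap.
#' @param rus_iter under-sampling iterations; predictions are averaged
#'   across the resulting models.
#' @export
run_external_benchmark <- function(seed, overlaps = c(1, 0.75, 0.5),
                                   effect_size = 2, noise_sd = 0.5,
                                   epochs = 400L, learning_rate = 2e-3,
                                   n_external = 5L, rus_iter = 3L) {
  cohort <- simulate_cohort(sim_config(n_metabolome = 100,
                                       effect_size = effect_size,
                                       noise_sd = noise_sd, seed = seed))
  xk <- cohort$omics$metabolome
  arch <- architecture_spec(ncol(xk$values), cohort$scores$schema)
  plan <- rus_plan(cohort$labels, n_iter = rus_iter, seed = seed)
  models <- lapply(seq_len(rus_iter), function(i)
    train_model(build_model(arch, seed + i), xk, cohort$scores,
                hyperparams(learning_rate = learning_rate,
                            epochs = epochs, seed = seed + i),
                sample_idx = plan$iterations[[i]]))
  layer <- score_layer_fit(predict_rus_average(models, xk$values),
                           cohort$labels, true_scores = cohort$scores)
  res <- lapply(overlaps, function(ov) {
    runs <- lapply(seq_len(n_external), function(r) {
      ext <- simulate_external_cohort(cohort, kind = "metabolome",
                                      overlap_fraction = ov,
                                      seed = seed + 100L * r)
      al <- align_external(ext$x, models[[1]]$feature_ids)
      pred <- predict_rus_average(models, al$x$values)
      prob <- score_layer_predict(layer, pred)
      c(coverage = al$report$coverage,
        auc = unname(binary_metrics(ext$labels, prob)["auc"]))
    })
    colMeans(do.call(rbind, runs))
  })
  out <- do.call(rbind, res)
  data.frame(overlap = overlaps, coverage = out[, "coverage"],
             auc = out[, "auc"])
}
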