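#' Default pipeline configuration
#'
#' A single structured configuration covering every stage; any element can
#' be overridden through `...`.  Passing it through [run_pipeline()] twice
#' with the same seed reproduces all deterministic outputs.
#'
#' @param seed master seed threaded through simulation, folds, resampling,
#'   training and attribution.
#' @param ... overrides for individual elements (e.g. `epochs = 50`).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    sim = list(n_samples = 300, case_control_ratio = 2),
    epochs = 100L, batch_size = 64L, learning_rate = 5e-4,
    k_folds = 5L, rus_iter = 3L,
    background_size = 100L, n_coalitions = NULL,
    top_k = 10L, cutoff = 0.75,
    network_threshold = 0.3)
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulate (or accept) a cohort, assemble the combined feature matrix,
#' evaluate by cross-validation, train a final model on the full cohort,
#' decode it with Shapley attributions, categorize biomarkers, and write
#' every artifact (metrics, attributions, catalog, manifest) under
#' `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param cohort optional pre-built `sim_cohort`; by default one is
#'   simulated from `config$sim` and `config$seed`.
#' @return invisibly, a list with `cv`, `model`, `layer`, `attributions`,
#'   `catalog` and `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (missing(out_dir)) stop_sym("`out_dir` is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_sym("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  cohort <- cohort %||% stage("simulate", {
    sc <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    simulate_cohort(sc)
  })
  x <- stage("preprocess", cohort_combined(cohort))
  hp <- hyperparams(learning_rate = config$learning_rate,
                    epochs = config$epochs, batch_size = config$batch_size,
                    seed = config$seed)
  cv <- stage("cross-validation",
              evaluate_cv(x, cohort$scores, cohort$labels, hp,
                          k = config$k_folds, rus_iter = config$rus_iter,
                          seed = config$seed))
  final <- stage("train", {
    arch <- architecture_spec(ncol(x$values), cohort$scores$schema)
    plan <- rus_plan(cohort$labels, n_iter = 1L, seed = config$seed)
    train_model(build_model(arch, seed = config$seed), x, cohort$scores, hp,
                sample_idx = plan$iterations[[1]])
  })
  layer <- stage("score-layer", {
    pred <- predict_scores(final, x)
    score_layer_fit(pred, cohort$labels, true_scores = cohort$scores)
  })
  attributions <- stage("explain",
    explain_all(final, x, mode = "kernel",
                background_size = min(config$background_size, nrow(x$values)),
                n_coalitions = config$n_coalitions, seed = config$seed))
  catalog <- stage("catalog",
    categorize_biomarkers(attributions, top_k = config$top_k,
                          cutoff = config$cutoff))
  stage("write", {
    jsonlite::write_json(list(
      config = unclass(config),
      pooled_auc = cv$pooled_auc,
      fold_auc = as.numeric(cv$binary[, "auc"]),
      mse = as.list(colMeans(cv$mse)),
      n_parameters = n_parameters(final)),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(
      disease_specific = catalog$disease_specific,
      symptom_specific = catalog$symptom_specific,
      counts = as.list(catalog$counts),
      top_k = catalog$top_k, cutoff = catalog$cutoff),
      file.path(out_dir, "catalog.json"), auto_unbox = TRUE)
    for (a in attributions) {
      utils::write.table(
        data.frame(sample_id = rownames(a$phi), a$phi, check.names = FALSE),
        file.path(out_dir, paste0("attributions_", a$output_name, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    saveRDS(final, file.path(out_dir, "model.rds"))
    jsonlite::write_json(list(package = "symptomics",
                              version = as.character(utils::packageVersion("symptomics")),
                              seed = config$seed,
                              timestamp = format(Sys.time(), tz = "UTC")),
                         file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  })
  invisible(list(cv = cv, model = final, layer = layer,
                 attributions = attributions, catalog = catalog,
                 out_dir = out_dir))
}
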