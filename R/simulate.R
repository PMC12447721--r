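#' Configuration for the synthetic multi-omics cohort generator
#'
#' The generator plants known feature-to-symptom effects inside realistic
#' multi-omics marginals so that training, attribution and external
#' validation can all be tested against a ground truth.  Shared
#' (disease-level) biomarkers influence every score; specific biomarkers
#' influence exactly one.  Planted effects come in three shapes, echoing the
#' contribution patterns seen in real biomarker-symptom scatter plots:
#' `monotonic` (linear in the latent), `biphasic` (quadratic around a
#' centre) and `sparse` (active only in a carrier subset of samples).
#'
#' @param n_samples cohort size (>= 20).
#' @param case_control_ratio cases per control; the default 2 reproduces the
#'   2:1 patient:control imbalance typical of case-heavy clinical cohorts.
#' @param n_species,n_kegg,n_immune,n_metabolome,n_blood features per assay.
#' @param n_shared_biomarkers number of planted disease-level features.
#' @param n_specific_per_output planted features unique to each score.
#' @param effect_size standard deviation of each planted contribution
#'   (each shape is variance-standardized before scaling).
#' @param noise_sd standard deviation of the Gaussian noise added to every
#'   latent severity and to the disease latent.
#' @param sparse_fraction carrier fraction for sparse effects outside the
#'   KEGG assay (KEGG sparse effects use the gene's presence mask).
#' @param schema a [score_schema()]; defaults to the 12-score panel.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 300, case_control_ratio = 2,
                       n_species = 60, n_kegg = 60, n_immune = 40,
                       n_metabolome = 40, n_blood = 8,
                       n_shared_biomarkers = 6, n_specific_per_output = 2,
                       effect_size = 1, noise_sd = 0.5,
                       sparse_fraction = 0.3,
                       schema = default_score_schema(), seed = 1L) {
  if (n_samples < 20) stop_sym("n_samples must be >= 20")
  if (noise_sd < 0) stop_sym("noise_sd must be >= 0")
  counts <- c(n_species, n_kegg, n_immune, n_metabolome, n_blood)
  if (any(counts < 0)) stop_sym("feature counts must be >= 0")
  structure(list(n_samples = n_samples,
                 case_control_ratio = case_control_ratio,
                 n_species = n_species, n_kegg = n_kegg, n_immune = n_immune,
                 n_metabolome = n_metabolome, n_blood = n_blood,
                 n_shared_biomarkers = n_shared_biomarkers,
                 n_specific_per_output = n_specific_per_output,
                 effect_size = effect_size, noise_sd = noise_sd,
                 sparse_fraction = sparse_fraction,
                 schema = schema, seed = as.integer(seed)),
            class = "sim_config")
}

sim_feature_ids <- function(config) {
  mk <- function(prefix, n) if (n > 0) sprintf("%s_%03d", prefix, seq_len(n)) else character()
  list(species = mk("sp", config$n_species),
       kegg = mk("ko", config$n_kegg),
       immune = mk("imm", config$n_immune),
       metabolome = mk("met", config$n_metabolome),
       blood = mk("bld", config$n_blood))
}

# variance-standardize a planted contribution (population convention)
std_contrib <- function(v) {
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) v * 0 else (v - mean(v)) / s
}

#' Simulate a multi-omics cohort with planted effects
#'
#' Draws a latent standard-normal matrix, maps each column through its
#' assay's marginal transform (softmax composition for species,
#' zero-inflated log-normal for KEGG genes, logistic proportions for immune
#' cells, log-normal intensities for metabolites, Gaussian blood labs), and
#' builds each score's latent severity as the sum of its planted
#' contributions plus Gaussian noise.  Continuous scores are the logistic
#' squash of the severity; categorical scores are quantile-binned into C
#' levels; the disease label thresholds a shared-feature disease latent so
#' that the case:control ratio is met exactly.
#'
#' @param config a [sim_config()].
#' @return a `sim_cohort`: list with `omics` (named list of
#'   [omics_matrix()]), `scores` ([score_matrix()]), `labels` (named 0/1
#'   integer vector, 1 = case), `truth` (the planted-effect ledger, class
#'   `ground_truth`) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pop <- sim_population(config)
  sim_draw(pop, config, draw_seed = (as.numeric(config$seed) + 500009) %%
             2147480009)
}

# Population stage: everything that defines the generative model itself —
# per-feature marginal parameters and the planted-effect table — drawn
# deterministically from config$seed.  External cohorts share this
# population and differ only in the sample draw.
sim_population <- function(config) {
  schema <- config$schema
  n_out <- nrow(schema)
  feats <- sim_feature_ids(config)
  kinds_of <- rep(names(feats), lengths(feats))
  all_feats <- unlist(feats, use.names = FALSE)
  p <- length(all_feats)
  with_seed(config$seed, {
    marg <- list(
      species_base = if (config$n_species > 0)
        stats::rnorm(config$n_species, 0, 1.5),
      kegg_prev = if (config$n_kegg > 0)
        stats::runif(config$n_kegg, 0.25, 0.9),
      immune_mu = if (config$n_immune > 0)
        stats::rnorm(config$n_immune, -1, 0.8),
      met_mu = if (config$n_metabolome > 0)
        stats::rnorm(config$n_metabolome, 8, 1),
      blood_mu = if (config$n_blood > 0) stats::rnorm(config$n_blood, 50, 20),
      blood_sd = if (config$n_blood > 0) stats::runif(config$n_blood, 1, 10))

    monotone_pool <- all_feats[kinds_of != "kegg"]
    n_shared <- config$n_shared_biomarkers
    n_spec <- config$n_specific_per_output
    need <- n_shared + n_spec * n_out
    if (need > p) stop_sym("not enough features (", p, ") to plant ", need,
                           " effects")
    shared <- if (n_shared > 0) sample(monotone_pool, n_shared) else character()
    # specific shapes cycle monotonic/biphasic/sparse across the flat list
    shapes_cycle <- c("monotonic", "biphasic", "sparse")
    remaining_mono <- setdiff(monotone_pool, shared)
    remaining_kegg <- all_feats[kinds_of == "kegg"]
    spec_rows <- list()
    k <- 0L
    for (o in seq_len(n_out)) for (j in seq_len(n_spec)) {
      k <- k + 1L
      shape <- shapes_cycle[(k - 1L) %% 3L + 1L]
      if (shape == "sparse" && length(remaining_kegg) > 0) {
        f <- sample(remaining_kegg, 1)
        remaining_kegg <- setdiff(remaining_kegg, f)
      } else {
        f <- sample(remaining_mono, 1)
        remaining_mono <- setdiff(remaining_mono, f)
      }
      spec_rows[[k]] <- data.frame(feature_id = f, target = schema$name[o],
                                   shape = shape, stringsAsFactors = FALSE)
    }
    spec <- if (length(spec_rows)) do.call(rbind, spec_rows) else NULL

    truth_df <- rbind(
      if (n_shared > 0)
        data.frame(feature_id = shared, scope = "shared",
                   target = NA_character_, shape = "monotonic",
                   stringsAsFactors = FALSE),
      if (!is.null(spec))
        data.frame(feature_id = spec$feature_id, scope = "specific",
                   target = spec$target, shape = spec$shape,
                   stringsAsFactors = FALSE))
    if (is.null(truth_df))
      truth_df <- data.frame(feature_id = character(), scope = character(),
                             target = character(), shape = character(),
                             stringsAsFactors = FALSE)
    truth_df$kind <- kinds_of[match(truth_df$feature_id, all_feats)]
    truth_df$sign <- sample(c(-1, 1), nrow(truth_df), replace = TRUE)
    # block-balanced coefficients: the shared (disease-level) block carries
    # total contribution variance 2*effect_size^2 per score and the
    # specific block effect_size^2, so both biomarker categories matter for
    # every score regardless of how many features make up each block
    truth_df$coefficient <- ifelse(
      truth_df$scope == "shared",
      config$effect_size * sqrt(2 / max(n_shared, 1)),
      config$effect_size * sqrt(1 / max(n_spec, 1)))
    truth_df$x0 <- ifelse(truth_df$shape == "biphasic", 0, NA_real_)

    list(marginals = marg, truth_df = truth_df, feats = feats,
         kinds_of = kinds_of, all_feats = all_feats)
  })
}

# Sample stage: draw a cohort from a fixed population.
sim_draw <- function(pop, config, draw_seed) {
  n <- config$n_samples
  r <- config$case_control_ratio
  n_cases <- round(n * r / (1 + r))
  if (n_cases < 1 || n - n_cases < 1)
    stop_sym("infeasible case:control ratio ", r, " for n_samples = ", n)
  schema <- config$schema
  n_out <- nrow(schema)
  feats <- pop$feats
  all_feats <- pop$all_feats
  p <- length(all_feats)
  truth_df <- pop$truth_df
  marg <- pop$marginals
  sample_id <- sprintf("S%03d", seq_len(n))

  with_seed(draw_seed, {
    L <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(sample_id, all_feats))

    # assay marginals -----------------------------------------------------
    omics <- list()
    kegg_mask <- NULL
    if (config$n_species > 0) {
      ex <- exp(sweep(L[, feats$species, drop = FALSE], 2,
                      marg$species_base, "+"))
      omics$species <- omics_matrix(ex / rowSums(ex), "species")
    }
    if (config$n_kegg > 0) {
      kegg_mask <- matrix(
        stats::rbinom(n * config$n_kegg, 1, rep(marg$kegg_prev, each = n)),
        n, config$n_kegg, dimnames = list(sample_id, feats$kegg))
      v <- exp(0.8 * L[, feats$kegg, drop = FALSE]) * kegg_mask
      omics$kegg <- omics_matrix(v, "kegg")
    }
    if (config$n_immune > 0) {
      v <- stats::plogis(sweep(L[, feats$immune, drop = FALSE], 2,
                               marg$immune_mu, "+") / 1.2)
      omics$immune <- omics_matrix(v, "immune")
    }
    if (config$n_metabolome > 0) {
      v <- exp(sweep(0.8 * L[, feats$metabolome, drop = FALSE], 2,
                     marg$met_mu, "+"))
      omics$metabolome <- omics_matrix(v, "metabolome")
    }
    if (config$n_blood > 0) {
      v <- sweep(sweep(L[, feats$blood, drop = FALSE], 2, marg$blood_sd, "*"),
                 2, marg$blood_mu, "+")
      omics$blood <- omics_matrix(v, "blood")
    }

    # contributions (variance-standardized per shape) ---------------------
    sparse_subsets <- list()
    contrib <- matrix(0, n, nrow(truth_df))
    for (i in seq_len(nrow(truth_df))) {
      f <- truth_df$feature_id[i]
      z <- L[, f]
      c_i <- switch(truth_df$shape[i],
        monotonic = std_contrib(z),
        biphasic  = std_contrib((z - truth_df$x0[i])^2),
        sparse = {
          if (truth_df$kind[i] == "kegg" && !is.null(kegg_mask)) {
            mask <- kegg_mask[, f]
          } else {
            idx <- sample(n, max(1L, round(config$sparse_fraction * n)))
            mask <- as.numeric(seq_len(n) %in% idx)
          }
          sparse_subsets[[f]] <- which(mask == 1)
          std_contrib(z * mask)
        })
      contrib[, i] <- truth_df$sign[i] * truth_df$coefficient[i] * c_i
    }

    # latents, labels, scores ---------------------------------------------
    is_shared <- truth_df$scope == "shared"
    shared_sum <- if (any(is_shared))
      rowSums(contrib[, is_shared, drop = FALSE]) else numeric(n)
    disease_latent <- shared_sum + stats::rnorm(n, 0, config$noise_sd)
    thr <- sort(disease_latent, decreasing = TRUE)[n_cases]
    labels <- as.integer(disease_latent >= thr)
    names(labels) <- sample_id

    severity <- matrix(0, n, n_out, dimnames = list(sample_id, schema$name))
    values <- severity
    case_frac <- n_cases / n
    for (o in seq_len(n_out)) {
      own <- !is_shared & truth_df$target == schema$name[o]
      own[is.na(own)] <- FALSE
      s <- shared_sum +
        (if (any(own)) rowSums(contrib[, own, drop = FALSE]) else 0) +
        stats::rnorm(n, 0, config$noise_sd)
      severity[, o] <- s
      values[, o] <- switch(schema$dtype[o],
        # squash the standardized severity so scores spread over (0, 1)
        # like real 0-1 instruments instead of saturating at the ends
        continuous  = stats::plogis(1.7 * std_contrib(s)),
        binary      = as.numeric(s > stats::quantile(s, 1 - case_frac)),
        categorical = {
          C <- schema$n_levels[o]
          br <- stats::quantile(s, probs = seq(0, 1, length.out = C + 1))
          br[1] <- -Inf; br[C + 1] <- Inf
          as.numeric(cut(s, breaks = br, labels = FALSE,
                         include.lowest = TRUE)) - 1
        })
    }

    truth <- structure(list(features = truth_df,
                            sparse_subsets = sparse_subsets,
                            severity = severity,
                            disease_latent = disease_latent,
                            labels = labels),
                       class = "ground_truth")
    structure(list(omics = omics,
                   scores = score_matrix(values, schema),
                   labels = labels, truth = truth, config = config),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> n=%d (%d cases / %d controls), assays: %s\n",
              x$config$n_samples, sum(x$labels), sum(x$labels == 0),
              paste(names(x$omics), collapse = ", ")))
  invisible(x)
}

#' Outputs targeted by a planted feature
#'
#' Shared features target every output; specific features target exactly one.
#'
#' @param truth a `ground_truth`.
#' @param feature_id planted feature id.
#' @param schema the cohort's [score_schema()].
#' @return character vector of output names.
#' @export
truth_targets <- function(truth, feature_id, schema) {
  row <- truth$features[truth$features$feature_id == feature_id, ]
  if (nrow(row) == 0) return(character())
  if (row$scope[1] == "shared") schema$name else row$target
}

#' Combine a cohort's assays into one feature matrix
#'
#' Concatenates the assay matrices column-wise (features prefixed with their
#' kind when names collide) as a simple integrated input for model training.
#'
#' @param cohort a `sim_cohort` or named list of [omics_matrix()].
#' @param kinds which assays to include (default all present).
#' @return an `omics_matrix` of kind `"combined"`.
#' @export
cohort_combined <- function(cohort, kinds = NULL) {
  omics <- if (inherits(cohort, "sim_cohort")) cohort$omics else cohort
  kinds <- kinds %||% names(omics)
  mats <- lapply(omics[kinds], as_omics_values)
  all_names <- unlist(lapply(mats, colnames), use.names = FALSE)
  if (anyDuplicated(all_names)) {
    for (k in names(mats)) colnames(mats[[k]]) <- paste0(k, ".", colnames(mats[[k]]))
  }
  omics_matrix(do.call(cbind, mats), "combined")
}

#' Simulate an external validation cohort
#'
#' Draws new samples from the *same population* as the training cohort —
#' identical marginal parameters and identical planted effects — then
#' keeps only a fraction of the model's features, optionally renames some
#' of them (simulating identifiers that cannot be matched across studies),
#' and applies a per-feature location shift as a simple batch effect.
#'
#' @param cohort the training `sim_cohort`.
#' @param kind which assay to export.
#' @param overlap_fraction fraction (0, 1] of the training features measured
#'   in the external cohort.
#' @param rename_fraction fraction of the kept features whose ids are
#'   changed so they no longer match the model's feature list.
#' @param batch_shift_sd standard deviation (in units of each feature's own
#'   SD) of the per-feature location shift; 0 disables the batch effect.
#' @param seed seed for the external draw; defaults to the training seed + 1.
#' @return list with `x` (the external [omics_matrix()]), `labels`,
#'   `kept_features` and `config`.
#' @export
simulate_external_cohort <- function(cohort, kind = "metabolome",
                                     overlap_fraction = 0.79,
                                     rename_fraction = 0,
                                     batch_shift_sd = 0.5,
                                     seed = NULL) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (overlap_fraction <= 0 || overlap_fraction > 1)
    stop_sym("overlap_fraction must be in (0, 1]")
  if (!kind %in% names(cohort$omics))
    stop_sym("kind '", kind, "' not present in the training cohort")
  config <- cohort$config
  draw_seed <- as.integer((as.numeric(seed %||% (config$seed + 1L))) %%
                            2147480009)
  ext <- sim_draw(sim_population(config), config, draw_seed)
  v <- as_omics_values(ext$omics[[kind]])
  m <- ncol(v)
  n_keep <- floor(m * overlap_fraction + 0.5)
  with_seed((draw_seed + 7L) %% 2147480009, {
    keep <- sort(sample(m, n_keep))
    v <- v[, keep, drop = FALSE]
    if (batch_shift_sd > 0) {
      shift <- stats::rnorm(ncol(v), 0, batch_shift_sd) * apply(v, 2, stats::sd)
      v <- sweep(v, 2, shift, "+")
      if (kind %in% c("species", "immune")) v <- pmax(v, 0)
      if (kind == "species") v <- v / pmax(rowSums(v), 1e-12)
      if (kind == "immune") v <- pmin(v, 1)
    }
    kept <- colnames(v)
    if (rename_fraction > 0) {
      n_ren <- floor(ncol(v) * rename_fraction + 0.5)
      if (n_ren > 0) {
        idx <- sample(ncol(v), n_ren)
        colnames(v)[idx] <- paste0(colnames(v)[idx], "_alt")
      }
    }
    list(x = structure(list(values = v, kind = kind), class = "omics_matrix"),
         labels = ext$labels, kept_features = kept, config = config)
  })
}

#' Tiny deterministic worked example
#'
#' A 12-sample, 6-feature, 2-output bundle built by fixed arithmetic (no
#' RNG), used in documentation and fast unit tests.  Feature `f1` is a
#' shared biomarker driving both outputs; `f2` is specific to `pain`; `f3`
#' is specific to `orthostatic_intolerance`; `f4`-`f6` carry no effect.
#' Labels are exactly 8 cases and 4 controls, and the binary score equals
#' the disease label, so the bundle is linearly separable.
#'
#' @return list with `omics` ([omics_matrix()], kind `"immune"`), `scores`
#'   ([score_matrix()]), `labels` and `truth`.
#' @export
make_worked_fixture <- function() {
  n <- 12L
  i <- seq_len(n)
  labels <- as.integer(i <= 8)  # 8 cases, 4 controls
  sample_id <- sprintf("S%02d", i)
  wig <- function(k) sin(k * i) / 4
  f1 <- 0.3 + 0.4 * labels + wig(1)            # shared driver
  f2 <- 0.5 + 0.3 * cos(i) * labels + wig(2)   # pain-specific
  f3 <- 0.2 + 0.35 * labels + wig(3)           # intolerance-specific
  f4 <- 0.5 + wig(4)
  f5 <- 0.4 + wig(5)
  f6 <- 0.6 + wig(6)
  X <- cbind(f1 = f1, f2 = f2, f3 = f3, f4 = f4, f5 = f5, f6 = f6)
  X <- pmin(pmax(X, 0), 1)
  rownames(X) <- sample_id
  schema <- score_schema(c("pain", "orthostatic_intolerance"),
                         c("continuous", "binary"),
                         raw_min = c(0, NA), raw_max = c(1, NA))
  pain <- pmin(pmax(0.15 + 0.5 * (f1 - 0.3) + 0.4 * (f2 - 0.5), 0), 1)
  scores <- cbind(pain = pain, orthostatic_intolerance = as.numeric(labels))
  rownames(scores) <- sample_id
  truth <- structure(list(
    features = data.frame(
      feature_id = c("f1", "f2", "f3"),
      scope = c("shared", "specific", "specific"),
      target = c(NA, "pain", "orthostatic_intolerance"),
      shape = "monotonic", kind = "immune", sign = 1, coefficient = 1,
      x0 = NA_real_, stringsAsFactors = FALSE),
    sparse_subsets = list(), severity = NULL,
    disease_latent = f1, labels = stats::setNames(labels, sample_id)),
    class = "ground_truth")
  list(omics = omics_matrix(X, "immune"),
       scores = score_matrix(scores, schema),
       labels = stats::setNames(labels, sample_id),
       truth = truth)
}
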