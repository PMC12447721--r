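#' Standardize features to zero mean and unit variance
#'
#' Columnwise z-scoring, the model's normalization layer.  Standard
#' deviations use the population convention (divide by n).  Constant
#' features (sigma = 0) are centered and left unscaled.  When `stats` is
#' supplied (train-fitted), it is applied unchanged, which is how test and
#' external data must be transformed.
#'
#' @param x an [omics_matrix()] or numeric matrix.
#' @param stats optional `standardization_stats` fitted on training data.
#' @return a list with `x` (the standardized `omics_matrix`) and `stats`
#'   (class `standardization_stats`: `mu`, `sigma`, `feature_ids`).
#' @export
standardize <- function(x, stats = NULL) {
  v <- as_omics_values(x)
  kind <- if (inherits(x, "omics_matrix")) x$kind else "combined"
  if (is.null(stats)) {
    mu <- colMeans(v)
    sigma <- sqrt(colMeans(sweep(v, 2, mu)^2))  # population sd
    stats <- structure(list(mu = mu, sigma = sigma, feature_ids = colnames(v)),
                       class = "standardization_stats")
  } else {
    if (!inherits(stats, "standardization_stats"))
      stop_sym("`stats` must be standardization_stats")
    if (!identical(stats$feature_ids, colnames(v)))
      stop_sym("feature mismatch between matrix and standardization stats")
  }
  div <- ifelse(stats$sigma > 0, stats$sigma, 1)
  z <- sweep(sweep(v, 2, stats$mu), 2, div, "/")
  out <- structure(list(values = z, kind = kind), class = "omics_matrix")
  list(x = out, stats = stats)
}

#' Filter features by mean abundance and prevalence
#'
#' Keeps features whose mean value strictly exceeds `min_mean_abundance`
#' and whose fraction of non-zero samples strictly exceeds
#' `min_prevalence`, the standard cleanup for species relative abundances
#' (mean > 1e-4) and KEGG gene profiles (prevalence > 20%).  Feature order
#' is preserved.
#'
#' @param x an [omics_matrix()].
#' @param min_mean_abundance strict lower threshold on the feature mean.
#' @param min_prevalence strict lower threshold on the non-zero fraction.
#' @return the filtered `omics_matrix`.
#' @export
filter_features <- function(x, min_mean_abundance = 0, min_prevalence = 0) {
  v <- as_omics_values(x)
  keep <- colMeans(v) > min_mean_abundance &
    colMeans(v != 0) > min_prevalence
  if (!any(keep))
    stop_sym("all ", ncol(v), " features removed; lower min_mean_abundance (",
             min_mean_abundance, ") or min_prevalence (", min_prevalence, ")")
  omics_matrix(v[, keep, drop = FALSE],
               if (inherits(x, "omics_matrix")) x$kind else "combined")
}

#' Remove confounder effects by OLS residualization
#'
#' Each feature is replaced by its residual from an ordinary least-squares
#' fit on the confounder covariates (plus intercept), retaining the part of
#' the signal not explained by the confounders.  With an empty covariate
#' set this reduces to mean-centering.
#'
#' @param x an [omics_matrix()]; rownames must match `confounders`.
#' @param confounders data frame of numeric covariates with sample ids as
#'   rownames (e.g. 0/1 medication indicators); no missing values.
#' @return an `omics_matrix` of residuals (same dimensions and ids).
#' @export
residualize <- function(x, confounders) {
  v <- as_omics_values(x)
  if (nrow(confounders) != nrow(v) ||
      !setequal(rownames(confounders), rownames(v)))
    stop_sym("confounder table samples do not match the omics matrix")
  confounders <- confounders[rownames(v), , drop = FALSE]
  if (anyNA(confounders)) stop_sym("confounder table contains missing values")
  design <- cbind(`(Intercept)` = 1, as.matrix(confounders))
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    drop_cols <- colnames(design)[qd$pivot[seq(qd$rank + 1, ncol(design))]]
    stop_sym("confounder design is rank deficient; collinear columns: ",
             fmt_ids(drop_cols))
  }
  res <- qr.resid(qd, v)
  dimnames(res) <- dimnames(v)
  structure(list(values = res,
                 kind = if (inherits(x, "omics_matrix")) x$kind else "combined"),
            class = "omics_matrix")
}
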