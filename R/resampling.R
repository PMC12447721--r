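#' Random under-sampling plan for class imbalance
#'
#' Builds `n_iter` balanced training sets: each iteration keeps the entire
#' minority class and pairs it with an equal-sized majority subset drawn
#' without replacement (a fresh, independent draw per iteration).  With the
#' cohort's 2:1 imbalance and 100 iterations, virtually every majority
#' sample is used at least once.
#'
#' @param labels 0/1 vector (any two-level vector works; the rarer level is
#'   the minority class).
#' @param n_iter number of resampling iterations (default 100).
#' @param seed integer seed.
#' @return a `resample_plan`: list with `iterations` (list of integer index
#'   vectors), `n_iter`, `minority`/`majority` index sets and `seed`.
#' @export
rus_plan <- function(labels, n_iter = 100L, seed = 1L) {
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop_sym("labels must contain exactly two classes")
  idx_by <- split(seq_along(labels), labels)
  ord <- order(lengths(idx_by))
  minority <- idx_by[[ord[1]]]
  majority <- idx_by[[ord[2]]]
  if (length(minority) == 0) stop_sym("minority class is empty")
  iters <- with_seed(seed, {
    lapply(seq_len(n_iter), function(i) {
      sub <- if (length(majority) == length(minority)) majority
             else sample(majority, length(minority))
      sort(c(minority, sub))
    })
  })
  structure(list(iterations = iters, n_iter = as.integer(n_iter),
                 minority = sort(minority), majority = sort(majority),
                 seed = as.integer(seed)),
            class = "resample_plan")
}

#' Stratified k-fold split
#'
#' Partitions samples into k disjoint test folds whose union covers every
#' sample, with each class spread as evenly as possible across folds
#' (per-fold class counts within one sample of balance).
#'
#' @param labels class labels.
#' @param k number of folds (default 5); cannot exceed the number of
#'   samples (k = n gives the leave-one-out partition).
#' @param seed integer seed.
#' @param stratified set FALSE for a plain (unstratified) k-fold split.
#' @return a `fold_split`: list with `test_idx` (list of k integer vectors),
#'   `k` and `seed`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L, stratified = TRUE) {
  n <- length(labels)
  if (k < 2 || k > n)
    stop_sym("k = ", k, " exceeds the sample count (", n, ")")
  folds <- integer(n)
  with_seed(seed, {
    if (stratified) {
      # round-robin continues across classes so fold sizes stay balanced
      offset <- 0L
      for (cl in sort(unique(labels))) {
        idx <- sample(which(labels == cl))
        folds[idx] <- (seq_along(idx) - 1L + offset) %% k + 1L
        offset <- offset + length(idx)
      }
    } else {
      folds[sample(n)] <- rep_len(seq_len(k), n)
    }
  })
  structure(list(test_idx = lapply(seq_len(k), function(f) which(folds == f)),
                 k = as.integer(k), seed = as.integer(seed),
                 stratified = stratified),
            class = "fold_split")
}

#' Serialize or restore a plan as JSON
#'
#' Index plans are stored as plain JSON integer lists so a training run can
#' be reproduced exactly elsewhere.
#'
#' @param x a `resample_plan` or `fold_split`.
#' @param path output file.
#' @return `path` invisibly (write) or the restored object (read).
#' @export
write_plan_json <- function(x, path) {
  obj <- unclass(x)
  obj$class <- class(x)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan_json
#' @export
read_plan_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$class
  obj$class <- NULL
  if (cls == "resample_plan" && is.matrix(obj$iterations))
    obj$iterations <- lapply(seq_len(nrow(obj$iterations)),
                             function(i) obj$iterations[i, ])
  if (cls == "fold_split" && is.matrix(obj$test_idx))
    obj$test_idx <- lapply(seq_len(nrow(obj$test_idx)),
                           function(i) obj$test_idx[i, ])
  structure(obj, class = cls)
}
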