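#' Declare the model's output scores
#'
#' A score schema lists the clinical outputs the network predicts, one row
#' per score, with its data type and (for continuous instruments) the raw
#' range used by [scale_scores()].  `severity_direction` is +1 when a larger
#' raw value means a worse symptom and -1 for well-being-oriented
#' instruments, which are inverted during scaling so that 1 always encodes
#' maximum severity.
#'
#' @param name character vector of unique output names.
#' @param dtype one of `"binary"`, `"categorical"`, `"continuous"` per output.
#' @param n_levels number of categorical levels C (>= 2); NA otherwise.
#' @param severity_direction +1 or -1 per output.
#' @param raw_min,raw_max declared raw instrument range (continuous only).
#' @return a `score_schema`: a data frame with one row per output.
#' @export
score_schema <- function(name, dtype, n_levels = NA_integer_,
                         severity_direction = 1L,
                         raw_min = NA_real_, raw_max = NA_real_) {
  n <- length(name)
  if (n < 1) stop_sym("schema needs at least one output")
  if (anyDuplicated(name)) stop_sym("output names must be unique")
  dtype <- match.arg(dtype, c("binary", "categorical", "continuous"),
                     several.ok = TRUE)
  sch <- data.frame(name = as.character(name),
                    dtype = rep_len(dtype, n),
                    n_levels = as.integer(rep_len(n_levels, n)),
                    severity_direction = as.integer(rep_len(severity_direction, n)),
                    raw_min = rep_len(as.numeric(raw_min), n),
                    raw_max = rep_len(as.numeric(raw_max), n),
                    stringsAsFactors = FALSE)
  bad <- sch$dtype == "categorical" & (is.na(sch$n_levels) | sch$n_levels < 2)
  if (any(bad))
    stop_sym("categorical outputs need n_levels >= 2: ", fmt_ids(sch$name[bad]))
  sch$n_levels[sch$dtype != "categorical"] <- NA_integer_
  class(sch) <- c("score_schema", "data.frame")
  sch
}

#' Default 12-score symptom panel
#'
#' Ten continuous severity scores on a 0-1 scale, one 5-level categorical
#' score (overall physical health, worst level 4) and one binary score
#' (orthostatic intolerance), mirroring a typical chronic-illness symptom
#' battery built from instruments such as RAND-36, PSQI and GSRS.
#'
#' @return a `score_schema` with 12 outputs.
#' @export
default_score_schema <- function() {
  cont <- c("pain", "fatigue", "sleep_problems", "gastrointestinal",
            "cognitive_efficiency", "emotional_wellbeing", "social_activity",
            "daily_activity", "health_perception", "emotional_problems")
  score_schema(
    name = c("physical_health", "orthostatic_intolerance", cont),
    dtype = c("categorical", "binary", rep("continuous", length(cont))),
    n_levels = c(5L, rep(NA_integer_, length(cont) + 1L)),
    severity_direction = 1L,
    raw_min = c(NA, NA, rep(0, length(cont))),
    raw_max = c(NA, NA, rep(1, length(cont))))
}

validate_score_values <- function(values, schema, where = "score matrix") {
  for (i in seq_len(nrow(schema))) {
    v <- values[, schema$name[i]]
    ok <- is.na(v) | switch(schema$dtype[i],
      binary      = v %in% c(0, 1),
      categorical = v %in% seq(0L, schema$n_levels[i] - 1L),
      continuous  = v >= -1e-9 & v <= 1 + 1e-9)
    if (!all(ok)) {
      j <- which(!ok)[1]
      stop_sym(where, ": invalid value ", v[j], " for ", schema$dtype[i],
               " score '", schema$name[i], "' (sample '", rownames(values)[j], "')")
    }
  }
  invisible(TRUE)
}

#' Scored clinical outcomes for a cohort
#'
#' @param values numeric matrix (samples x outputs) with rownames = sample
#'   ids and colnames matching `schema$name`; continuous scores must lie in
#'   0-1, binary in 0/1, categorical in 0..C-1.  NA marks a missing score.
#' @param schema a [score_schema()].
#' @return a `score_matrix`: list with `values` and `schema`.
#' @export
score_matrix <- function(values, schema) {
  stopifnot(inherits(schema, "score_schema"))
  if (!is.matrix(values) || !is.numeric(values))
    stop_sym("`values` must be a numeric matrix")
  if (is.null(rownames(values))) stop_sym("`values` needs sample ids as rownames")
  missing_cols <- setdiff(schema$name, colnames(values))
  if (length(missing_cols))
    stop_sym("score columns missing: ", fmt_ids(missing_cols))
  values <- values[, schema$name, drop = FALSE]
  validate_score_values(values, schema)
  structure(list(values = values, schema = schema), class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d samples x %d scores (%s)\n",
              nrow(x$values), nrow(x$schema),
              paste(table(x$schema$dtype), names(table(x$schema$dtype)),
                    collapse = ", ")))
  invisible(x)
}

#' Scale raw instrument scores to the model's 0-1 convention
#'
#' Continuous scores are mapped affinely from their declared raw range to
#' 0-1 with 1 = maximum severity; instruments whose raw scale is
#' well-being-oriented (`severity_direction = -1`) are inverted.  Binary and
#' categorical scores are validated and passed through.
#'
#' @param raw numeric matrix (samples x outputs, rownames = sample ids)
#'   of raw instrument values, columns named as in `schema`.
#' @param schema a [score_schema()] with `raw_min`/`raw_max` filled in for
#'   every continuous output.
#' @return a [score_matrix()].
#' @export
scale_scores <- function(raw, schema) {
  stopifnot(inherits(schema, "score_schema"))
  if (!is.matrix(raw)) raw <- as.matrix(raw)
  out <- matrix(NA_real_, nrow(raw), nrow(schema),
                dimnames = list(rownames(raw), schema$name))
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (!nm %in% colnames(raw)) stop_sym("raw table lacks score '", nm, "'")
    v <- raw[, nm]
    if (schema$dtype[i] == "continuous") {
      lo <- schema$raw_min[i]; hi <- schema$raw_max[i]
      if (is.na(lo) || is.na(hi) || hi <= lo)
        stop_sym("continuous score '", nm, "' needs a declared raw_min < raw_max")
      bad <- which(!is.na(v) & (v < lo | v > hi))
      if (length(bad))
        stop_sym("raw value ", v[bad[1]], " outside declared range [", lo, ", ",
                 hi, "] for score '", nm, "', sample '", rownames(raw)[bad[1]], "'")
      s <- (v - lo) / (hi - lo)
      if (schema$severity_direction[i] < 0) s <- 1 - s
      out[, i] <- s
    } else {
      out[, i] <- v  # validated by score_matrix()
    }
  }
  score_matrix(out, schema)
}
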