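# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the global random stream seeded to `seed`, then restores
#' whatever stream was active before.  All stochastic operations in the
#' package route through this so that no call mutates the caller's RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic small hash of a string, used to give each model output an
# initialization substream that depends on its name, not its position.
str_seed <- function(x, base = 0L) {
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 131 + ch) %% 2147480009
  as.integer((h + as.numeric(base)) %% 2147480009)
}

stop_sym <- function(...) stop(..., call. = FALSE)

# format a few ids for error messages
fmt_ids <- function(ids, max = 5L) {
  ids <- as.character(ids)
  if (length(ids) > max) {
    paste0(paste(ids[seq_len(max)], collapse = ", "), ", ... (",
           length(ids), " total)")
  } else paste(ids, collapse = ", ")
}
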