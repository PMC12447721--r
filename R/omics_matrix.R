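#' Sample-by-feature 'omics matrix
#'
#' The basic input container: a numeric matrix with samples in rows and
#' features in columns, tagged with the assay kind.  Species matrices are
#' validated as relative abundances (non-negative, row sums at most 1).
#'
#' @param values numeric matrix with unique rownames (sample ids) and unique
#'   colnames (feature ids).
#' @param kind one of `"species"`, `"kegg"`, `"immune"`, `"metabolome"`,
#'   `"blood"`, `"combined"`.
#' @return an object of class `omics_matrix`: a list with elements `values`
#'   and `kind`.
#' @examples
#' m <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("s", 1:3), paste0("f", 1:2)))
#' omics_matrix(m, "immune")
#' @export
omics_matrix <- function(values,
                         kind = c("species", "kegg", "immune", "metabolome",
                                  "blood", "combined")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop_sym("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_sym("`values` must have sample ids as rownames and feature ids as colnames")
  dup_s <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_s))
    stop_sym("duplicated sample ids: ", fmt_ids(dup_s))
  dup_f <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_f))
    stop_sym("duplicated feature ids: ", fmt_ids(dup_f))
  if (anyNA(values))
    stop_sym("omics matrix contains missing values; resolve at read time ",
             "(see `read_omics_matrix(missing = )`)")
  if (kind == "species") {
    if (any(values < 0))
      stop_sym("species matrix must be non-negative relative abundances")
    rs <- rowSums(values)
    if (any(rs > 1 + 1e-6))
      stop_sym("species row sums exceed 1 for samples: ",
               fmt_ids(rownames(values)[rs > 1 + 1e-6]))
  }
  structure(list(values = values, kind = kind), class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> kind=%s: %d samples x %d features\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Sample and feature identifiers
#' @param x an `omics_matrix`.
#' @return character vector of ids.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
feature_ids <- function(x) colnames(x$values)

as_omics_values <- function(x) {
  if (inherits(x, "omics_matrix")) x$values
  else if (is.matrix(x)) x
  else stop_sym("expected an omics_matrix or a matrix")
}

#' Read a delimited feature table
#'
#' Reads a TSV/CSV with one header row and one leading id column into an
#' [omics_matrix()].  Tables stored features-in-rows are transposed on load.
#'
#' @param path file path; `.csv` is parsed comma-separated, anything else
#'   tab-separated.
#' @param orientation `"samples"` if samples are in rows (default) or
#'   `"features"` if features are in rows.
#' @param kind assay kind, see [omics_matrix()].
#' @param missing `"error"` (default) fails on any missing cell; `"zero"`
#'   imputes zeros, intended for abundance-like kinds.
#' @return an `omics_matrix`.
#' @export
read_omics_matrix <- function(path,
                              orientation = c("samples", "features"),
                              kind = "combined",
                              missing = c("error", "zero")) {
  orientation <- match.arg(orientation)
  missing <- match.arg(missing)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  if (ncol(raw) < 2) stop_sym("table must have an id column plus data columns")
  ids <- raw[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop_sym("duplicated row ids in ", path, ": ", fmt_ids(dup))
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !is.na(body) & body != "" & toupper(body) != "NA",
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop_sym("non-numeric cell at row '", ids[bad[1, 1]], "', column '",
             colnames(body)[bad[1, 2]], "': \"", body[bad[1, 1], bad[1, 2]], "\"")
  }
  if (anyNA(num)) {
    if (missing == "zero") num[is.na(num)] <- 0
    else {
      miss <- which(is.na(num), arr.ind = TRUE)
      stop_sym("missing value at row '", ids[miss[1, 1]], "', column '",
               colnames(body)[miss[1, 2]],
               "'; use missing = \"zero\" to impute abundance tables")
    }
  }
  dimnames(num) <- list(ids, colnames(body))
  if (orientation == "features") num <- t(num)
  omics_matrix(num, kind)
}

#' Write an omics matrix as delimited text
#'
#' Inverse of [read_omics_matrix()]: samples in rows, header row, leading
#' `sample_id` column, full double precision.
#'
#' @param x an `omics_matrix`.
#' @param path output path; `.csv` writes comma-separated.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(x, path) {
  v <- as_omics_values(x)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  # 17 significant digits round-trips doubles exactly
  for (j in seq(2, ncol(df))) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
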