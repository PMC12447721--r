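#' Module eigengenes
#'
#' Summarizes each co-expression module by the first principal component of
#' its standardized member features, scaled to unit variance and sign-fixed
#' so that its mean correlation with the members is non-negative.
#' Singleton modules pass through standardized.  The fraction of member
#' variance explained by the eigengene is recorded per module.
#'
#' @param x an [omics_matrix()] (samples x features).
#' @param assignment named character vector mapping every feature id to a
#'   module label; the label `"unassigned"` (grey) is skipped.
#' @return an `eigengene_matrix`: list with `values` (samples x modules),
#'   `variance_explained`, `module_sizes`, `kind`.
#' @export
module_eigengene <- function(x, assignment) {
  V <- as_omics_values(x)
  feats <- colnames(V)
  if (!all(feats %in% names(assignment)))
    stop_sym("assignment missing for features: ",
             fmt_ids(setdiff(feats, names(assignment))))
  assignment <- assignment[feats]
  modules <- setdiff(unique(assignment), "unassigned")
  if (!length(modules)) stop_sym("no assigned modules")
  E <- matrix(NA_real_, nrow(V), length(modules),
              dimnames = list(rownames(V), modules))
  varexp <- stats::setNames(numeric(length(modules)), modules)
  sizes <- stats::setNames(integer(length(modules)), modules)
  for (mod in modules) {
    member <- feats[assignment == mod]
    sizes[mod] <- length(member)
    Z <- standardize(omics_matrix_nocheck(V[, member, drop = FALSE]))$x$values
    if (length(member) == 1) {
      e <- Z[, 1]
      varexp[mod] <- 1
    } else {
      pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
      e <- pc$x[, 1]
      varexp[mod] <- pc$sdev[1]^2 / sum(pc$sdev^2)
    }
    s <- stats::sd(e)
    if (s > 0) e <- e / s
    cors <- suppressWarnings(stats::cor(e, Z))
    if (mean(cors, na.rm = TRUE) < 0) e <- -e
    E[, mod] <- e
  }
  structure(list(values = E, variance_explained = varexp,
                 module_sizes = sizes,
                 kind = if (inherits(x, "omics_matrix")) x$kind else "combined"),
            class = "eigengene_matrix")
}

#' Inter-assay module correlation network
#'
#' Spearman correlations between all pairs of module eigengenes (within and
#' across assays) on the shared samples.  Edges are kept when |rho| meets
#' the threshold (inclusive, default 0.3); Holm-adjusted p-values are
#' reported per edge family but the filter itself is the |rho| rule.
#' Degree and (unweighted) betweenness centrality are computed on the
#' thresholded graph.
#'
#' @param eigengenes a single `eigengene_matrix` or a list of them (one per
#'   assay).
#' @param threshold absolute-correlation threshold for an edge.
#' @return a `correlation_network`: `nodes` (data frame: node, kind, module,
#'   size, degree, betweenness), `edges` (node pairs with rho, p, p_adj),
#'   `rho_full` (pre-threshold correlation matrix), `threshold`.
#' @export
correlation_network <- function(eigengenes, threshold = 0.3) {
  if (inherits(eigengenes, "eigengene_matrix")) eigengenes <- list(eigengenes)
  mats <- lapply(eigengenes, function(e) e$values)
  kinds <- vapply(eigengenes, function(e) e$kind, "")
  shared <- Reduce(intersect, lapply(mats, rownames))
  if (length(shared) < 3)
    stop_sym("fewer than 3 shared samples across eigengene matrices")
  blocks <- mapply(function(m, k) {
    m <- m[shared, , drop = FALSE]
    colnames(m) <- paste0(k, ".", colnames(m))
    m
  }, mats, kinds, SIMPLIFY = FALSE)
  M <- do.call(cbind, blocks)
  rho <- stats::cor(M, method = "spearman")
  nodes <- data.frame(node = colnames(M),
                      kind = rep(kinds, vapply(blocks, ncol, 1L)),
                      module = unlist(lapply(eigengenes,
                                             function(e) colnames(e$values))),
                      size = unlist(lapply(eigengenes,
                                           function(e) e$module_sizes)),
                      stringsAsFactors = FALSE)
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  edges <- data.frame(node1 = rownames(rho)[pairs[, 1]],
                      node2 = colnames(rho)[pairs[, 2]],
                      rho = rho[pairs], stringsAsFactors = FALSE)
  edges$p <- vapply(seq_len(nrow(edges)), function(i) {
    suppressWarnings(stats::cor.test(M[, edges$node1[i]], M[, edges$node2[i]],
                                     method = "spearman", exact = FALSE)$p.value)
  }, 0)
  edges$p_adj <- stats::p.adjust(edges$p, method = "holm")
  edges <- edges[abs(edges$rho) >= threshold, , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges[, c("node1", "node2")],
                                     directed = FALSE, vertices = nodes$node)
  nodes$degree <- as.numeric(igraph::degree(g)[nodes$node])
  nodes$betweenness <- as.numeric(igraph::betweenness(g)[nodes$node])
  structure(list(nodes = nodes, edges = edges, rho_full = rho,
                 threshold = threshold, p_adjust = "holm",
                 n_samples = length(shared)),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("<correlation_network> %d nodes, %d edges at |rho| >= %.2f (n=%d samples)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold, x$n_samples))
  invisible(x)
}

#' Differential network between a subgroup and its reference
#'
#' Per node pair, the change in Spearman correlation
#' `delta_rho = rho_subgroup - rho_reference`, computed on the
#' *pre-threshold* correlations so that edges absent from one network still
#' difference correctly.  Pairs with `|delta_rho| >= delta` are reported
#' and flagged as increased, decreased, or reversed (sign flip).
#'
#' @param net_subgroup,net_reference two [correlation_network()] objects on
#'   the same node set (e.g. female patients vs female healthy).
#' @param delta report threshold on |delta_rho| (default 0.3).
#' @return data frame: node1, node2, rho_subgroup, rho_reference,
#'   delta_rho, direction.
#' @export
differential_network <- function(net_subgroup, net_reference, delta = 0.3) {
  a <- net_subgroup$rho_full
  b <- net_reference$rho_full
  if (!identical(sort(rownames(a)), sort(rownames(b)))) {
    diff_nodes <- c(setdiff(rownames(a), rownames(b)),
                    setdiff(rownames(b), rownames(a)))
    stop_sym("node sets differ: ", fmt_ids(diff_nodes))
  }
  b <- b[rownames(a), colnames(a)]
  pairs <- which(upper.tri(a), arr.ind = TRUE)
  out <- data.frame(node1 = rownames(a)[pairs[, 1]],
                    node2 = colnames(a)[pairs[, 2]],
                    rho_subgroup = a[pairs], rho_reference = b[pairs],
                    stringsAsFactors = FALSE)
  out$delta_rho <- out$rho_subgroup - out$rho_reference
  out <- out[abs(out$delta_rho) >= delta, , drop = FALSE]
  out$direction <- ifelse(sign(out$rho_subgroup) * sign(out$rho_reference) < 0 &
                            abs(out$rho_subgroup) > 1e-12 &
                            abs(out$rho_reference) > 1e-12,
                          "reversed",
                          ifelse(out$delta_rho > 0, "increased", "decreased"))
  rownames(out) <- NULL
  out
}

#' Export an edge list as TSV (and optionally GraphML)
#'
#' @param network a [correlation_network()].
#' @param path output TSV path.
#' @param graphml optional GraphML path for network viewers.
#' @return `path` invisibly.
#' @export
write_network <- function(network, path, graphml = NULL) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                       vertices = network$nodes)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}
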