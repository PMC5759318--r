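#' Spearman correlation matrix of sampled fluxes
#'
#' Rank correlation over the sampled flux values of each reaction pair.
#' Reactions whose flux is constant across the sample (fixed by the
#' constraints) have no ranks to correlate and are excluded with a warning
#' rather than producing NaN edges.
#'
#' @param sample a `flux_sample_set`.
#' @param reaction_subset reaction ids to include; defaults to all.
#' @return symmetric matrix of Spearman rho with unit diagonal.
#' @export
spearman_matrix <- function(sample, reaction_subset = NULL) {
  stopifnot(inherits(sample, "flux_sample_set"))
  X <- sample$samples
  if (!is.null(reaction_subset)) {
    missing_ids <- setdiff(reaction_subset, colnames(X))
    if (length(missing_ids)) {
      stop("unknown reaction id(s): ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    X <- X[, reaction_subset, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("empty reaction subset", call. = FALSE)
  variances <- apply(X, 2, stats::var)
  constant <- variances < .Machine$double.eps
  if (all(constant)) {
    stop("all selected flux columns are constant; nothing to correlate",
         call. = FALSE)
  }
  if (any(constant)) {
    warning("excluding constant flux column(s): ",
            paste(colnames(X)[constant], collapse = ", "))
    X <- X[, !constant, drop = FALSE]
  }
  stats::cor(X, method = "spearman")
}

#' Threshold a correlation matrix into a module network
#'
#' Keeps edges with |rho| at or above the threshold (ties at the threshold
#' included), annotates nodes with their pathway subsystem, and extracts
#' modules as the connected components of the thresholded graph. Raising
#' the threshold can only remove edges, so modules only ever split.
#'
#' @param rho symmetric Spearman matrix, as from [spearman_matrix()].
#' @param threshold minimum |rho| for an edge (default 0.7).
#' @param subsystems named character vector mapping reaction id to
#'   subsystem; unknown ids get `""`.
#' @param condition label stored with the network.
#' @return a `correlation_network`: list with `nodes` (id, subsystem,
#'   module), `edges` (from, to, rho), `graph` (igraph object),
#'   `threshold`, `condition`.
#' @export
threshold_network <- function(rho, threshold = 0.7, subsystems = NULL,
                              condition = "default") {
  stopifnot(is.matrix(rho), nrow(rho) == ncol(rho))
  ids <- colnames(rho)
  adj <- abs(rho) >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  idx <- which(upper.tri(rho) & adj, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      rho = rho[idx], stringsAsFactors = FALSE)
  sub <- if (is.null(subsystems)) rep("", length(ids)) else {
    out <- subsystems[ids]
    out[is.na(out)] <- ""
    unname(out)
  }
  nodes <- data.frame(id = ids, subsystem = sub,
                      module = unname(comp$membership[ids]),
                      stringsAsFactors = FALSE)
  igraph::V(g)$subsystem <- nodes$subsystem
  structure(list(nodes = nodes, edges = edges, graph = g,
                 threshold = threshold, condition = condition,
                 n_modules = comp$no),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("Correlation network (", x$condition, "): ", nrow(x$nodes),
      " nodes, ", nrow(x$edges), " edges at |rho| >= ", x$threshold,
      ", ", x$n_modules, " modules\n", sep = "")
  invisible(x)
}

#' Modules (connected components) of a correlation network
#'
#' @param network a `correlation_network`.
#' @return list of character vectors, one per module, each the reaction
#'   ids of one maximal connected component.
#' @export
network_modules <- function(network) {
  split(network$nodes$id, network$nodes$module)
}

#' Count correlation edges within a reaction subset
#'
#' @param network a `correlation_network`.
#' @param reaction_subset reaction ids; defaults to all nodes.
#' @return number of edges with both endpoints in the subset.
#' @export
count_correlations <- function(network, reaction_subset = NULL) {
  if (is.null(reaction_subset)) return(nrow(network$edges))
  unknown <- setdiff(reaction_subset, network$nodes$id)
  if (length(unknown)) {
    stop("subset contains unknown node(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sum(network$edges$from %in% reaction_subset &
        network$edges$to %in% reaction_subset)
}

#' Export a correlation network
#'
#' Writes the thresholded network in a standard format loadable by network
#' viewers: GraphML, SIF (`node1 corr node2` lines), an edge-list TSV
#' (`from`, `to`, `rho`) or a module-membership TSV.
#'
#' @param network a `correlation_network`.
#' @param path output file.
#' @param format one of `"graphml"`, `"sif"`, `"edges"`, `"modules"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path,
                           format = c("graphml", "sif", "edges",
                                      "modules")) {
  format <- match.arg(format)
  switch(format,
         graphml = igraph::write_graph(network$graph, path,
                                       format = "graphml"),
         sif = writeLines(
           sprintf("%s corr %s", network$edges$from, network$edges$to),
           path),
         edges = utils::write.table(network$edges, path, sep = "\t",
                                    quote = FALSE, row.names = FALSE),
         modules = utils::write.table(network$nodes, path, sep = "\t",
                                      quote = FALSE, row.names = FALSE))
  invisible(path)
}
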