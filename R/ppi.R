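#' Read a PPI edge list
#'
#' Two-column tab- or whitespace-separated file of gene-symbol pairs.
#' Duplicate and reversed pairs are collapsed; self-loops are dropped with
#' a warning giving their count.
#'
#' @param path Path to the edge-list file.
#' @param focal Optional focal gene symbol stored on the result (added as
#'   an isolated node if absent from the edges).
#' @return A list of class `ppi_graph`: `graph` (undirected simple igraph),
#'   `focal`.
#' @export
read_edge_list <- function(path, focal = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  edges <- matrix(character(0), ncol = 2)
  if (length(lines) > 0) {
    parsed <- strsplit(trimws(lines), "[\t ]+")
    bad <- which(vapply(parsed, length, integer(1)) != 2)
    if (length(bad) > 0)
      stop("malformed edge-list line ", bad[1], " in ", path)
    edges <- do.call(rbind, parsed)
  }
  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  nodes <- unique(c(as.vector(t(edges)), focal))
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(nodes)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, t(matrix(match(edges, nodes), ncol = 2)))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  structure(list(graph = g, focal = focal), class = "ppi_graph")
}

#' Construct a PPI graph from an edge data frame
#'
#' @param edges Two-column data frame or matrix of symbol pairs.
#' @param focal Focal gene symbol.
#' @param nodes Optional additional (possibly isolated) nodes.
#' @return A `ppi_graph`.
#' @export
ppi_graph <- function(edges, focal, nodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edges must have two columns")
  keep <- edges[, 1] != edges[, 2]
  edges <- edges[keep, , drop = FALSE]
  all_nodes <- unique(c(as.vector(t(edges)), focal, nodes))
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(all_nodes)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, t(matrix(match(edges, all_nodes), ncol = 2)))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  structure(list(graph = g, focal = focal), class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat("PPI graph:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges; focal =", x$focal, "\n")
  invisible(x)
}

#' Primary and secondary interactors of the focal gene
#'
#' Primary interactors are the focal gene's neighbors; secondary
#' interactors sit at shortest-path distance exactly 2.  Node degrees are
#' computed within the subgraph induced by the focal gene and its
#' primary/secondary interactors (mirroring hub analysis of the displayed
#' ego network); set `full_graph_degree = TRUE` for degrees in the whole
#' input graph.
#'
#' @param graph A `ppi_graph`.
#' @param full_graph_degree Use full-graph degrees instead of
#'   induced-subgraph degrees (default FALSE).
#' @return A list of class `interactor_set`: `focal`, `primary`,
#'   `secondary` (sorted character vectors) and `degrees` (named integer
#'   vector over focal + primary + secondary).
#' @export
ego_interactors <- function(graph, full_graph_degree = FALSE) {
  stopifnot(inherits(graph, "ppi_graph"))
  focal <- graph$focal
  g <- graph$graph
  if (is.null(focal) || !focal %in% igraph::V(g)$name)
    stop("focal gene absent from graph")
  d <- as.vector(igraph::distances(g, v = focal))
  names(d) <- igraph::V(g)$name
  primary <- sort(names(d)[d == 1])
  secondary <- sort(names(d)[d == 2])
  members <- c(focal, primary, secondary)
  if (full_graph_degree) {
    deg <- igraph::degree(g, v = members)
  } else {
    sub <- igraph::induced_subgraph(g, members)
    deg <- igraph::degree(sub)[members]
  }
  structure(list(focal = focal, primary = primary, secondary = secondary,
                 degrees = deg), class = "interactor_set")
}

#' @export
print.interactor_set <- function(x, ...) {
  cat("Interactors of ", x$focal, ": ", length(x$primary), " primary, ",
      length(x$secondary), " secondary\n", sep = "")
  invisible(x)
}

#' High-connectivity interactors
#'
#' Members of an interactor set (excluding the focal gene itself) with
#' degree at least `min_degree`, sorted by degree descending then symbol.
#'
#' @param interactors An `interactor_set` from [ego_interactors()].
#' @param min_degree Minimum degree (default 5).
#' @return Named integer vector of degrees.
#' @export
high_connectivity <- function(interactors, min_degree = 5) {
  deg <- interactors$degrees
  deg <- deg[setdiff(names(deg), interactors$focal)]
  deg <- deg[deg >= min_degree]
  deg[order(-deg, names(deg))]
}
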