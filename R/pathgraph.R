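# Graph machinery over the connectome.  Pathways are, by default, simple
# paths on the undirected support of C (an edge exists if C[m,j] > 0 or
# C[j,m] > 0): the preprocessed matrix is approximately symmetric in
# support and routes are treated as undirected.  The directed view is
# available via `directed = TRUE`.

con_graph <- function(connectome, directed = FALSE) {
  A <- connectome$C > 0
  if (!directed) A <- A | t(A)
  igraph::graph_from_adjacency_matrix(A, mode = if (directed) "directed" else "undirected")
}

# undirected edge cost 1/C, using max(C[m,j], C[j,m]) where asymmetric
inv_strength_costs <- function(connectome, graph) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- pmax(connectome$C[el], connectome$C[el[, 2:1, drop = FALSE]])
  1 / w
}

#' Enumerate simple pathways between two nodes
#'
#' All simple paths from `src` to `dst` with at most `max_edges` edges, in
#' deterministic lexicographic order of their node sequences.
#'
#' @param connectome A [connectome()].
#' @param src,dst Distinct node indices.
#' @param max_edges Maximum number of edges per path.
#' @param directed Use the directed support of `C` instead of the
#'   undirected default.
#' @return List of integer node-index vectors (each a path `src .. dst`);
#'   empty list for a disconnected pair.
#' @export
enumerate_paths <- function(connectome, src, dst, max_edges = 6,
                            directed = FALSE) {
  stopifnot(src != dst, max_edges >= 1)
  g <- con_graph(connectome, directed)
  ps <- igraph::all_simple_paths(g, from = src, to = dst, cutoff = max_edges,
                                 mode = "out")
  ps <- lapply(ps, as.integer)
  if (length(ps) == 0) return(list())
  ps[order(vapply(ps, function(p) paste(sprintf("%06d", p), collapse = ","),
                  character(1)))]
}

#' Dijkstra distance on inverted connection strengths
#'
#' Shortest-path distance between `src` and `dst` with edge costs `1/C`
#' (undirected; `1/max(C[m,j], C[j,m])` where the matrix is asymmetric).  A
#' proxy for the inverse connectedness of the pair.
#'
#' @inheritParams enumerate_paths
#' @return List with `distance` (Inf if disconnected) and `path` (integer
#'   node sequence realizing it, or NULL).
#' @export
dijkstra_inverse_strength <- function(connectome, src, dst) {
  g <- con_graph(connectome, directed = FALSE)
  w <- inv_strength_costs(connectome, g)
  d <- igraph::distances(g, v = src, to = dst, weights = w)[1, 1]
  if (!is.finite(d)) return(list(distance = Inf, path = NULL))
  p <- igraph::shortest_paths(g, from = src, to = dst, weights = w)$vpath[[1]]
  list(distance = d, path = as.integer(p))
}

#' Hop count and metric length of the shortest pathway
#'
#' Minimum number of edges separating the pair and, among all paths
#' attaining that hop count, the minimum summed fiber length (mm).  The
#' mm-minimal path is the recorded tie-break.
#'
#' @inheritParams enumerate_paths
#' @return List with `edges` (integer hop count), `length_mm`, and `path`.
#' @export
shortest_path_stats <- function(connectome, src, dst) {
  g <- con_graph(connectome, directed = FALSE)
  hops <- igraph::distances(g, v = src, to = dst, weights = NA)[1, 1]
  if (!is.finite(hops)) stop("node pair is disconnected")
  cands <- igraph::all_shortest_paths(g, from = src, to = dst,
                                      weights = NA)$vpaths
  lens <- vapply(cands, function(p) {
    p <- as.integer(p)
    sum(connectome$L[cbind(p[-length(p)], p[-1])])
  }, numeric(1))
  k <- which.min(lens)
  list(edges = as.integer(hops), length_mm = lens[k],
       path = as.integer(cands[[k]]))
}

path_edge_set <- function(path) {
  if (length(path) < 2) return(character(0))
  a <- path[-length(path)]; b <- path[-1]
  paste(pmin(a, b), pmax(a, b), sep = "-")
}

#' Are two pathways edge-disjoint?
#'
#' TRUE iff the undirected edge sets of the two paths are disjoint; shared
#' nodes are allowed.
#'
#' @param p1,p2 Integer node sequences.
#' @return Logical scalar.
#' @export
edge_disjoint <- function(p1, p2) {
  length(intersect(path_edge_set(p1), path_edge_set(p2))) == 0
}

#' Count pathways between a pair, with pooling
#'
#' Number of simple paths with at most `max_edges` edges; counts above
#' `pool_above` are pooled to `pool_above + 1` (one "many paths" level), as
#' used when relating the facilitation effect to connectedness.
#'
#' @inheritParams enumerate_paths
#' @param pool_above Pool threshold; `Inf` disables pooling.
#' @return Integer count (possibly pooled).
#' @export
count_paths <- function(connectome, src, dst, max_edges = 5,
                        pool_above = 5) {
  k <- length(enumerate_paths(connectome, src, dst, max_edges = max_edges))
  if (k > pool_above) pool_above + 1 else k
}
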