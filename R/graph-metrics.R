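# All four summaries are computed on the undirected binarized skeleton of
# the thresholded graph; strength uses |R| edge weights. igraph does the
# graph work behind this surface.

as_igraph_undirected <- function(graph) {
  stopifnot(inherits(graph, "connectivity_graph"))
  el <- cbind(graph$edges$a, graph$edges$b)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, graph$n_sources - igraph::vcount(g)))
  if (nrow(graph$edges)) {
    igraph::E(g)$weight <- abs(graph$edges$R)
  }
  g
}

#' Node degree (D)
#'
#' Number of retained connections incident to each node, each unordered
#' pair counted once.
#'
#' @param graph a `connectivity_graph`.
#' @return List with `per_node` and `mean`.
#' @export
node_degree <- function(graph) {
  g <- as_igraph_undirected(graph)
  d <- as.numeric(igraph::degree(g))
  list(per_node = d, mean = mean(d))
}

#' Node strength (S)
#'
#' Sum of absolute correlation weights over each node's retained edges.
#'
#' @param graph a `connectivity_graph`.
#' @return List with `per_node` and `mean`.
#' @export
node_strength <- function(graph) {
  g <- as_igraph_undirected(graph)
  s <- if (igraph::ecount(g)) as.numeric(igraph::strength(g))
  else rep(0, igraph::vcount(g))
  list(per_node = s, mean = mean(s))
}

#' Characteristic path length (L)
#'
#' Mean shortest-path hop count over connected node pairs of the binarized
#' undirected graph; disconnected pairs are excluded from the mean. A graph
#' with no connected pair returns `NA` (undefined), never 0.
#'
#' @param graph a `connectivity_graph`.
#' @return Scalar (or `NA` when no path exists).
#' @export
path_length <- function(graph) {
  g <- as_igraph_undirected(graph)
  D <- igraph::distances(g, weights = NA)
  vals <- D[upper.tri(D)]
  vals <- vals[is.finite(vals) & vals > 0]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Clustering coefficient (C)
#'
#' Per node, the fraction of its neighbor pairs that are themselves
#' connected (2 x triangles / k(k-1)); nodes with fewer than two neighbors
#' contribute 0. Mean taken over all nodes so group comparisons use a fixed
#' node set.
#'
#' @param graph a `connectivity_graph`.
#' @return List with `per_node` and `mean`.
#' @export
clustering_coefficient <- function(graph) {
  g <- as_igraph_undirected(graph)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[is.na(cc)] <- 0
  list(per_node = as.numeric(cc), mean = mean(cc))
}

#' All four network parameters for one subject graph
#'
#' @param graph a `connectivity_graph`.
#' @return One-row data frame: subject, band, degree_D, strength_S,
#'   path_length_L, clustering_C, n_edges.
#' @export
graph_metrics <- function(graph) {
  data.frame(
    subject = if (is.null(graph$subject_id)) NA_character_ else graph$subject_id,
    band = if (is.null(graph$band)) NA_character_ else graph$band$name,
    degree_D = node_degree(graph)$mean,
    strength_S = node_strength(graph)$mean,
    path_length_L = path_length(graph),
    clustering_C = clustering_coefficient(graph)$mean,
    n_edges = nrow(graph$edges),
    stringsAsFactors = FALSE
  )
}
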