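#' Node-centrality suite
#'
#' Computes the six centrality features used to characterize reconstructed
#' networks: connectivity (degree), normalized closeness
#' \eqn{(n-1)/\sum d}, shortest-path betweenness, eccentricity (longest
#' shortest-path distance), principal-eigenvector centrality, and PageRank
#' with damping 0.85. All metrics except PageRank are computed on the
#' undirected skeleton of the network; PageRank respects edge direction. On
#' disconnected graphs, closeness and eccentricity are computed within each
#' node's connected component and the report is flagged.
#'
#' @param network a `signed_network` or an [igraph::graph].
#' @param nodes optional subset of node names; defaults to all nodes.
#' @return a `centrality_report`: data frame (one row per node) with the six
#'   metric columns, plus attributes `"averages"` (named means over the
#'   subset) and `"disconnected"` (logical flag).
#' @export
centrality_suite <- function(network, nodes = NULL) {
  g <- if (inherits(network, "signed_network")) as_igraph(network) else network
  stopifnot(igraph::vcount(g) >= 1L)
  und <- igraph::as_undirected(g, mode = "collapse")
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(g)))
  n <- length(ids)
  disconnected <- !igraph::is_connected(und)
  if (disconnected) {
    warning("centrality_suite: graph disconnected; closeness/eccentricity ",
            "computed within components")
  }
  # centralities are topological: signed edge weights are not distances,
  # so every metric runs on the unweighted structure
  dist <- igraph::distances(und, weights = NA)
  closeness <- vapply(seq_len(n), function(i) {
    d <- dist[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) return(0)
    length(d) / sum(d)
  }, numeric(1))
  eccentricity <- vapply(seq_len(n), function(i) {
    d <- dist[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) return(0)
    max(d)
  }, numeric(1))
  eig <- if (igraph::ecount(und)) {
    igraph::eigen_centrality(und, weights = NA)$vector
  } else rep(0, n)
  rep <- data.frame(
    node = ids,
    connectivity = as.integer(igraph::degree(und)),
    closeness = closeness,
    betweenness = igraph::betweenness(und, directed = FALSE, weights = NA),
    eccentricity = eccentricity,
    eigenvector = unname(eig),
    pagerank = unname(igraph::page_rank(g, damping = 0.85,
                                        weights = NA)$vector))
  if (!is.null(nodes)) {
    stopifnot(all(nodes %in% ids))
    rep <- rep[match(nodes, rep$node), , drop = FALSE]
  }
  attr(rep, "averages") <- colMeans(rep[, -1L, drop = FALSE])
  attr(rep, "disconnected") <- disconnected
  class(rep) <- c("centrality_report", "data.frame")
  rep
}
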