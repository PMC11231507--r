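#' Six per-node topological metrics
#'
#' Computed on the undirected view of the network (metrics carry no
#' directionality mode): degree (edges in and out of a node), closeness
#' (inverse of the sum of hop distances to reachable vertices), harmonic
#' centrality (sum of inverse distances, with 1/Inf = 0 on disconnected
#' graphs), eigenvector centrality (leading eigenvector of the adjacency
#' matrix, scaled to a maximum of 1), betweenness (shortest-path bridge
#' count, endpoints excluded, fractional credit for ties) and eccentricity
#' (distance to the farthest reachable node).
#'
#' @param net a [mlnet] object.
#' @return data.frame with one row per node and columns `degree`,
#'   `closeness`, `harmonic`, `eigenvector`, `betweenness`, `eccentricity`.
#' @export
node_centralities <- function(net) {
  if (nrow(net$nodes) == 0) stop_np("network is empty")
  g <- undirected_view(net)
  ec <- if (igraph::ecount(g) > 0) {
    with_fixed_rng(1L, igraph::eigen_centrality(g)$vector)
  } else {
    setNames(rep(0, igraph::vcount(g)), igraph::V(g)$name)
  }
  suppressWarnings(res <- data.frame(
    node = igraph::V(g)$name,
    degree = igraph::degree(g),
    closeness = igraph::closeness(g, normalized = FALSE),
    harmonic = igraph::harmonic_centrality(g, normalized = FALSE),
    eigenvector = ec,
    betweenness = igraph::betweenness(g, directed = FALSE),
    eccentricity = igraph::eccentricity(g),
    row.names = NULL
  ))
  res$closeness[is.nan(res$closeness) | is.na(res$closeness)] <- 0
  res
}

#' Inverse-log-weighted common-neighbor similarity
#'
#' Similarity of two nodes is the sum over their common neighbors z of
#' 1/ln(deg(z)): shared partners count more when they are themselves
#' selective. Computed on the undirected view.
#'
#' @param net a [mlnet] object.
#' @param targets character vector of node ids (the rows).
#' @param restrict_to `"all"` (columns = every node, the default) or
#'   `"protein"` (columns restricted to the protein layer).
#' @return a [feature_matrix] of similarities, category `"topological"`.
#' @export
invlog_similarity <- function(net, targets, restrict_to = c("all", "protein")) {
  restrict_to <- match.arg(restrict_to)
  if (length(targets) == 0) stop_np("empty target list")
  missing <- setdiff(targets, node_ids(net))
  if (length(missing) > 0) {
    stop_np("target(s) not in network: ",
            paste(head(missing, 5), collapse = ", "))
  }
  g <- undirected_view(net)
  nodes <- igraph::V(g)$name
  S <- igraph::similarity(g, method = "invlogweighted")
  dimnames(S) <- list(nodes, nodes)
  cols <- if (restrict_to == "protein") {
    net$nodes$node[net$nodes$layer == "protein"]
  } else nodes
  vals <- S[targets, cols, drop = FALSE]
  ids <- paste0("invlog_sim:", cols)
  colnames(vals) <- ids
  feature_matrix(vals, data.frame(
    feature_id = ids, category = "topological", mode = NA_character_,
    referenced_entity = cols, stringsAsFactors = FALSE
  ))
}

#' Topological feature matrix (category "topological")
#'
#' Horizontal concatenation of the six scalar metrics of
#' [node_centralities()] with the [invlog_similarity()] columns.
#'
#' @inheritParams invlog_similarity
#' @export
topology_feature_matrix <- function(net, targets,
                                    restrict_to = c("all", "protein")) {
  restrict_to <- match.arg(restrict_to)
  cent <- node_centralities(net)
  rownames(cent) <- cent$node
  metrics <- c("degree", "closeness", "harmonic", "eigenvector",
               "betweenness", "eccentricity")
  scalar <- as.matrix(cent[targets, metrics, drop = FALSE])
  rownames(scalar) <- targets
  fm_scalar <- feature_matrix(scalar, data.frame(
    feature_id = metrics, category = "topological", mode = NA_character_,
    referenced_entity = NA_character_, stringsAsFactors = FALSE
  ))
  fm_cbind(fm_scalar, invlog_similarity(net, targets, restrict_to))
}
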