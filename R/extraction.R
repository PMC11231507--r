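FEATURE_CATEGORIES <- c(
  "rwr_downstream", "rwr_upstream", "rwr_non_directed",
  "sp_downstream", "sp_upstream", "sp_non_directed",
  "topological", "cluster", "clique",
  "signature_gene", "signature_protein"
)

#' Extract one feature category
#'
#' Dispatcher over the 11 extraction categories; used by the pipeline and
#' by the rewired-network null of [null_ig_threshold()], which must re-run
#' the same recipe on a randomized network.
#'
#' @param net a [mlnet].
#' @param targets character vector of protein-layer target ids.
#' @param category one of the 11 category names (see
#'   `netprio:::FEATURE_CATEGORIES`).
#' @param params list of category parameters: `restart` and `tol` for RWR
#'   categories; `cluster_algorithms` and `seed` for `cluster`;
#'   `min_size`/`max_size` for `clique`; `signatures` (list of
#'   [signature_set]) for the signature categories; `similarity_columns`
#'   for `topological`.
#' @return a [feature_matrix].
#' @export
extract_category <- function(net, targets, category, params = list()) {
  if (!category %in% FEATURE_CATEGORIES) {
    stop_np("unknown feature category: ", category)
  }
  if (grepl("^rwr_", category)) {
    mode <- sub("^rwr_", "", category)
    return(propagation_feature_matrix(
      net, targets, method = "rwr", mode = mode,
      restart = params$restart %||% 0.7, tol = params$tol %||% 1e-10))
  }
  if (grepl("^sp_", category)) {
    mode <- sub("^sp_", "", category)
    return(propagation_feature_matrix(net, targets,
                                      method = "shortest_path",
                                      mode = mode))
  }
  if (category == "topological") {
    return(topology_feature_matrix(
      net, targets, restrict_to = params$similarity_columns %||% "all"))
  }
  if (category == "cluster") {
    ppi <- layer_subgraph(net, "protein")
    mods <- detect_clusters(
      ppi, algorithms = params$cluster_algorithms %||%
        default_cluster_algorithms(),
      seed = params$seed %||% 1L)
    return(module_feature_matrix(net, targets, mods))
  }
  if (category == "clique") {
    mods <- filtered_cliques(net, min_size = params$min_size %||% 15,
                             max_size = params$max_size %||% 50)
    return(module_feature_matrix(net, targets, mods))
  }
  # signature categories: map the provided gene signatures to the layer
  sigs <- params$signatures
  if (is.null(sigs)) stop_np("signature categories need params$signatures")
  layer <- sub("^signature_", "", category)
  mapped <- lapply(sigs, function(s) {
    if (s$layer == layer) s else
      map_signature_to_layer(s, net, layer = layer,
                             gene_to_protein = params$gene_to_protein)
  })
  mapped <- Filter(function(s) s$usable, mapped)
  signature_feature_matrix(net, targets, mapped)
}

#' Extract all 11 feature categories
#'
#' Runs propagation (RWR and shortest path under the three directionality
#' modes), topological, module (cluster and clique) and signature (gene
#' and protein layer) extraction, returning one [feature_matrix] per
#' category. Refined signatures (signature-by-module intersections) are
#' built here so both signature categories share them.
#'
#' @param net a [mlnet].
#' @param targets character vector of protein-layer target ids.
#' @param signatures list of gene-layer [signature_set] objects.
#' @param gene_to_protein data.frame mapping `gene` to `protein`.
#' @param restart RWR restart probability.
#' @param cluster_algorithms see [detect_clusters()].
#' @param clique_bounds length-2 numeric, clique size bounds.
#' @param refine_min_size minimum size for refined signature sets.
#' @param seed integer seed (clustering).
#' @return named list of [feature_matrix], one per category.
#' @export
extract_all_features <- function(net, targets, signatures = list(),
                                 gene_to_protein = NULL, restart = 0.7,
                                 cluster_algorithms =
                                   default_cluster_algorithms(),
                                 clique_bounds = c(15, 50),
                                 refine_min_size = 2, seed = 1L) {
  out <- list()
  for (mode in DIRECTIONALITY_MODES) {
    out[[paste0("rwr_", mode)]] <- propagation_feature_matrix(
      net, targets, method = "rwr", mode = mode, restart = restart)
    out[[paste0("sp_", mode)]] <- propagation_feature_matrix(
      net, targets, method = "shortest_path", mode = mode)
  }
  out[["topological"]] <- topology_feature_matrix(net, targets)
  ppi <- layer_subgraph(net, "protein")
  clusters <- detect_clusters(ppi, algorithms = cluster_algorithms,
                              seed = seed)
  cliques <- filtered_cliques(net, min_size = clique_bounds[1],
                              max_size = clique_bounds[2])
  out[["cluster"]] <- module_feature_matrix(net, targets, clusters)
  out[["clique"]] <- module_feature_matrix(net, targets, cliques)
  # refinement happens in protein space (modules live on the PPI layer):
  # signature proteins intersected with each module, then mapped back to
  # genes so both signature categories share the refined sets
  all_modules <- module_set(c(clusters$modules, cliques$modules))
  refined_p <- list()
  refined_g <- list()
  if (!is.null(gene_to_protein)) {
    prot_sigs <- Filter(function(s) s$usable,
                        lapply(signatures, map_signature_to_layer,
                               net = net, layer = "protein",
                               gene_to_protein = gene_to_protein))
    refined_p <- unlist(lapply(prot_sigs, refine_by_modules,
                               modules = all_modules,
                               min_size = refine_min_size),
                        recursive = FALSE) %||% list()
    p2g <- split(gene_to_protein$gene, gene_to_protein$protein)
    refined_g <- Filter(function(s) s$usable,
                        lapply(refined_p, function(s) signature_set(
      paste0(s$name, "_genes"), "refined",
      unique(unlist(p2g[s$members])), layer = "gene",
      parent_signature = s$parent_signature,
      parent_module = s$parent_module)))
  }
  out[["signature_gene"]] <- extract_category(
    net, targets, "signature_gene",
    params = list(signatures = c(signatures, refined_g)))
  out[["signature_protein"]] <- extract_category(
    net, targets, "signature_protein",
    params = list(signatures = c(signatures, refined_p),
                  gene_to_protein = gene_to_protein))
  out
}
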