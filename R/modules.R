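#' Module set (communities and cliques on the protein layer)
#'
#' @param modules list of modules, each a list with `id`, `kind`
#'   (`"cluster"` or `"clique"`), `members` (character vector) and
#'   `provenance` (algorithm + parameters string).
#' @export
module_set <- function(modules) {
  ids <- vapply(modules, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop_np("duplicate module ids")
  for (m in modules) {
    if (length(m$members) == 0) stop_np("module '", m$id, "' is empty")
    if (!m$kind %in% c("cluster", "clique")) {
      stop_np("module kind must be 'cluster' or 'clique'")
    }
  }
  structure(list(modules = modules), class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  kinds <- vapply(x$modules, `[[`, character(1), "kind")
  cat(sprintf("module_set: %d modules (%d clusters, %d cliques)\n",
              length(x$modules), sum(kinds == "cluster"),
              sum(kinds == "clique")))
  invisible(x)
}

#' @export
length.module_set <- function(x) length(x$modules)

# Registry of community-detection algorithms usable on the PPI layer.
# Each entry is a function(g, params) returning an igraph communities
# object (or any list of member vectors). Pluggable so external tools such
# as kernel/multiresolution clustering suites can be slotted in.
cluster_registry <- new.env(parent = emptyenv())

#' Register a clustering algorithm
#' @param name registry key.
#' @param fn function of `(g, params)` returning igraph communities or a
#'   list of character member vectors.
#' @export
register_cluster_algorithm <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = cluster_registry)
  invisible(name)
}

register_defaults <- function() {
  register_cluster_algorithm("leading_eigenvector", function(g, params) {
    igraph::cluster_leading_eigen(g)
  })
  register_cluster_algorithm("modularity_optimization", function(g, params) {
    igraph::cluster_louvain(g, resolution = params$resolution %||% 1)
  })
  register_cluster_algorithm("short_random_walks", function(g, params) {
    igraph::cluster_walktrap(g, steps = params$steps %||% 4)
  })
}

#' Default clustering parameterizations
#'
#' Leading eigenvector; modularity optimization at resolutions 1, 1.5 and
#' 2; short-random-walk agglomeration with 4 and 5 steps.
#' @export
default_cluster_algorithms <- function() {
  list(
    list(name = "leading_eigenvector"),
    list(name = "modularity_optimization", resolution = 1),
    list(name = "modularity_optimization", resolution = 1.5),
    list(name = "modularity_optimization", resolution = 2),
    list(name = "short_random_walks", steps = 4),
    list(name = "short_random_walks", steps = 5)
  )
}

algo_label <- function(alg) {
  extras <- alg[setdiff(names(alg), "name")]
  if (length(extras) == 0) return(alg$name)
  paste0(alg$name, "(",
         paste(sprintf("%s=%s", names(extras), unlist(extras)),
               collapse = ","), ")")
}

#' Detect clusters on the protein-protein interaction layer
#'
#' Runs every requested algorithm once, pools the resulting communities
#' into one module set, drops singleton communities and deduplicates
#' identical member sets (first provenance wins). Stochastic partitioners
#' are made reproducible by the seed.
#'
#' @param ppi the protein-layer subnetwork (see [layer_subgraph()]).
#' @param algorithms list of parameterizations, each a list with `name`
#'   (a registry key) plus algorithm parameters; see
#'   [default_cluster_algorithms()].
#' @param seed integer seed.
#' @return a [module_set] of kind `"cluster"`.
#' @export
detect_clusters <- function(ppi, algorithms = default_cluster_algorithms(),
                            seed = 1L) {
  g <- undirected_view(ppi)
  mods <- list()
  seen <- character()
  for (ai in seq_along(algorithms)) {
    alg <- algorithms[[ai]]
    fn <- get0(alg$name, envir = cluster_registry)
    if (is.null(fn)) stop_np("unknown clustering algorithm: ", alg$name)
    set.seed(derive_seed(seed, ai))
    if (igraph::ecount(g) == 0) next
    comm <- fn(g, alg)
    groups <- if (inherits(comm, "communities")) {
      igraph::communities(comm)
    } else comm
    k <- 0L
    for (grp in groups) {
      members <- sort(as.character(grp))
      if (length(members) < 2) next
      key <- paste(members, collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      k <- k + 1L
      mods[[length(mods) + 1L]] <- list(
        id = sprintf("cluster_%s_%d", algo_label(alg), k),
        kind = "cluster", members = members,
        provenance = algo_label(alg)
      )
    }
  }
  module_set(mods)
}

#' Filtered maximal cliques of the protein layer
#'
#' Retains maximal cliques of the protein layer with size within
#' `[min_size, max_size]` whose every member has at least one edge to a
#' pathway-layer node (the biological-interpretability criterion).
#'
#' @param net the full multi-layer network (pathway membership is read
#'   from edges to pathway nodes).
#' @param min_size,max_size clique size bounds; defaults 15 and 50.
#' @return a [module_set] of kind `"clique"`.
#' @export
filtered_cliques <- function(net, min_size = 15, max_size = 50) {
  gp <- undirected_view(layer_subgraph(net, "protein"))
  lay <- node_layers(net)
  pathway_nodes <- net$nodes$node[net$nodes$layer == "pathway"]
  e <- net$edges
  linked <- unique(c(e$from[e$to %in% pathway_nodes],
                     e$to[e$from %in% pathway_nodes]))
  cl <- igraph::max_cliques(gp, min = min_size, max = max_size)
  mods <- list()
  k <- 0L
  for (cq in cl) {
    members <- sort(igraph::V(gp)$name[as.integer(cq)])
    if (!all(members %in% linked)) next
    k <- k + 1L
    mods[[length(mods) + 1L]] <- list(
      id = sprintf("clique_%d", k), kind = "clique", members = members,
      provenance = sprintf("maximal_clique(size=%d,pathway_linked)",
                           length(members))
    )
  }
  module_set(mods)
}

#' Average shortest-path distance from a node to a module
#'
#' The mean over module members of undirected hop distances from the node
#' (self-distance 0 included when the node belongs to the module);
#' unreachable members take the profile's finite sentinel (largest finite
#' distance + 1).
#'
#' @param net a [mlnet].
#' @param node node id.
#' @param module a module (list with `members`) or a character vector of
#'   member ids.
#' @return mean hop distance (numeric scalar).
#' @export
module_distance <- function(net, node, module) {
  members <- if (is.list(module)) module$members else module
  if (length(members) == 0) stop_np("empty module")
  if (!node %in% node_ids(net)) stop_np("node '", node, "' not in network")
  missing <- setdiff(members, node_ids(net))
  if (length(missing) > 0) {
    stop_np("module member(s) not in network: ",
            paste(head(missing, 5), collapse = ", "))
  }
  g <- undirected_view(net)
  d <- as.numeric(igraph::distances(g, v = node, to = members))
  finite <- is.finite(d)
  if (!any(finite)) {
    # node reaches no member: fall back to global eccentricity bound
    d[] <- max(igraph::distances(g, v = node)[
      is.finite(igraph::distances(g, v = node))]) + 1
  } else {
    d[!finite] <- max(d[finite]) + 1
  }
  mean(d)
}

#' Module-proximity feature matrix (categories "cluster" and "clique")
#'
#' @param net a [mlnet].
#' @param targets character vector of node ids.
#' @param modules a [module_set].
#' @return a [feature_matrix] with one column per module.
#' @export
module_feature_matrix <- function(net, targets, modules) {
  stopifnot(inherits(modules, "module_set"))
  if (length(targets) == 0) stop_np("empty target list")
  if (length(modules$modules) == 0) {
    vals <- matrix(numeric(0), nrow = length(targets), ncol = 0,
                   dimnames = list(targets, character()))
    return(feature_matrix(vals, data.frame(
      feature_id = character(), category = character(),
      mode = character(), referenced_entity = character())))
  }
  g <- undirected_view(net)
  nodes <- igraph::V(g)$name
  D <- igraph::distances(g, v = targets)
  colnames(D) <- nodes
  vals <- matrix(NA_real_, length(targets), length(modules$modules),
                 dimnames = list(targets, NULL))
  for (j in seq_along(modules$modules)) {
    mem <- modules$modules[[j]]$members
    for (i in seq_along(targets)) {
      d <- D[i, mem]
      finite <- is.finite(d)
      if (!any(finite)) {
        row <- D[i, ]
        d[] <- max(row[is.finite(row)]) + 1
      } else {
        d[!finite] <- max(d[finite]) + 1
      }
      vals[i, j] <- mean(d)
    }
  }
  ids <- unname(vapply(modules$modules, `[[`, character(1), "id"))
  kinds <- unname(vapply(modules$modules, `[[`, character(1), "kind"))
  prov <- unname(vapply(modules$modules, `[[`, character(1), "provenance"))
  colnames(vals) <- ids
  feature_matrix(vals, data.frame(
    feature_id = ids, category = kinds, mode = NA_character_,
    referenced_entity = ids, provenance = prov, stringsAsFactors = FALSE
  ))
}

#' Serialize / read a module set as membership + provenance TSVs
#' @param modules a [module_set].
#' @param path two-column membership TSV (module_id, member).
#' @param provenance_path provenance TSV (module_id, kind, provenance).
#' @export
write_module_set <- function(modules, path, provenance_path) {
  mem <- do.call(rbind, lapply(modules$modules, function(m) {
    data.frame(module_id = m$id, member = m$members)
  })) %||% data.frame(module_id = character(), member = character())
  write.table(mem, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- do.call(rbind, lapply(modules$modules, function(m) {
    data.frame(module_id = m$id, kind = m$kind, provenance = m$provenance)
  })) %||% data.frame(module_id = character(), kind = character(),
                      provenance = character())
  write.table(prov, provenance_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

register_defaults()
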