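#' Heterogeneous multi-layer biological network
#'
#' A `mlnet` object stores typed nodes and typed edges over five closed
#' layers: `gene`, `protein`, `metabolite`, `go` (Gene Ontology term) and
#' `pathway`. Edges carry an interaction type and may be directed (e.g.
#' transcription-factor regulation, gene-to-protein translation) or
#' undirected (e.g. protein-protein or protein-metabolite interactions).
#' Undirected edges are stored once, with endpoints in lexicographic order;
#' self-loops are dropped on construction and duplicate
#' `(source, target, interaction_type)` edges are collapsed.
#'
#' @param nodes data.frame with columns `node` and `layer`, optionally an
#'   `attrs` list column of named character vectors.
#' @param edges data.frame with columns `from`, `to`, `type` and logical
#'   `directed`.
#' @return An object of class `mlnet` with elements `nodes` (data.frame:
#'   `node`, `layer`), `edges` (data.frame: `from`, `to`, `type`,
#'   `directed`) and `attrs` (named list of named character vectors).
#' @examples
#' net <- mlnet(
#'   nodes = data.frame(node = c("A", "B"), layer = "protein"),
#'   edges = data.frame(from = "A", to = "B", type = "ppi", directed = FALSE)
#' )
#' @export
mlnet <- function(nodes, edges = NULL, attrs = NULL) {
  stopifnot(is.data.frame(nodes), all(c("node", "layer") %in% names(nodes)))
  nodes$node <- as.character(nodes$node)
  nodes$layer <- as.character(nodes$layer)
  bad <- setdiff(unique(nodes$layer), MLNET_LAYERS)
  if (length(bad) > 0) {
    stop_np("unknown layer label(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(nodes$node)) {
    dup <- nodes$node[duplicated(nodes$node)]
    stop_np("duplicated node id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        type = character(), directed = logical())
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$type <- as.character(edges$type)
  edges$directed <- as.logical(edges$directed)
  missing_ep <- setdiff(c(edges$from, edges$to), nodes$node)
  if (length(missing_ep) > 0) {
    stop_np("edge endpoint(s) not in node set: ",
            paste(head(missing_ep, 5), collapse = ", "))
  }
  loops <- edges$from == edges$to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  # canonical storage: undirected endpoints sorted so A--B == B--A
  und <- !edges$directed
  swap <- und & edges$from > edges$to
  if (any(swap)) {
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }
  key <- paste(edges$from, edges$to, edges$type, edges$directed)
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL

  if (is.null(attrs)) attrs <- list()
  extra <- setdiff(names(attrs), nodes$node)
  if (length(extra) > 0) {
    stop_np("attribute(s) for unknown node(s): ",
            paste(head(extra, 5), collapse = ", "))
  }
  structure(
    list(nodes = nodes[, c("node", "layer")], edges = edges, attrs = attrs),
    class = "mlnet"
  )
}

#' @export
print.mlnet <- function(x, ...) {
  cat(sprintf("mlnet: %d nodes, %d edges (%d directed)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$directed)))
  tab <- table(factor(x$nodes$layer, levels = MLNET_LAYERS))
  cat("  layers:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

node_ids <- function(net) net$nodes$node

node_layers <- function(net) setNames(net$nodes$layer, net$nodes$node)

#' Read a multi-layer network from an edge-list file
#'
#' The edge list is a UTF-8 tab-separated file with header
#' `source target source_layer target_layer interaction_type directed`,
#' where `directed` is `true` or `false`. An optional node-attribute table
#' (`node layer key value`) can add isolated nodes and per-node attributes.
#'
#' @param path path to the edge-list TSV.
#' @param attrs_path optional path to a node-attribute TSV.
#' @return A [mlnet] object whose node set is the union of edge endpoints
#'   and attribute-table nodes.
#' @export
read_edge_list <- function(path, attrs_path = NULL) {
  if (!file.exists(path)) stop_np("edge list not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  expected <- c("source", "target", "source_layer", "target_layer",
                "interaction_type", "directed")
  if (length(lines) == 0) stop_np("empty edge-list file: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, expected)) {
    stop_np("edge-list header must be: ", paste(expected, collapse = " "))
  }
  n <- length(lines) - 1L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 6L) {
      stop_np("malformed edge-list row at line ", i + 1L,
              ": expected 6 tab-separated fields, got ", length(f))
    }
    rows[[i]] <- f
  }
  m <- do.call(rbind, rows)
  dirflag <- tolower(m[, 6])
  bad <- !dirflag %in% c("true", "false")
  if (any(bad)) {
    stop_np("malformed directed flag at line ", which(bad)[1] + 1L,
            " (expected true/false): ", m[bad, 6][1])
  }
  layers <- unique(c(m[, 3], m[, 4]))
  unknown <- setdiff(layers, MLNET_LAYERS)
  if (length(unknown) > 0) {
    stop_np("unknown layer label(s): ", paste(unknown, collapse = ", "))
  }
  node_df <- unique(data.frame(
    node = c(m[, 1], m[, 2]),
    layer = c(m[, 3], m[, 4]),
    stringsAsFactors = FALSE
  ))
  if (anyDuplicated(node_df$node)) {
    dup <- node_df$node[duplicated(node_df$node)][1]
    stop_np("node '", dup, "' listed with conflicting layers")
  }
  attrs <- list()
  if (!is.null(attrs_path)) {
    at <- read.delim(attrs_path, stringsAsFactors = FALSE,
                     colClasses = "character")
    if (!all(c("node", "layer", "key", "value") %in% names(at))) {
      stop_np("node-attribute table must have columns node layer key value")
    }
    bad_layer <- setdiff(unique(at$layer), MLNET_LAYERS)
    if (length(bad_layer) > 0) {
      stop_np("unknown layer label(s) in attribute table: ",
              paste(bad_layer, collapse = ", "))
    }
    known <- match(at$node, node_df$node)
    conflict <- !is.na(known) & node_df$layer[known] != at$layer
    if (any(conflict)) {
      stop_np("attribute table assigns node '", at$node[conflict][1],
              "' to layer '", at$layer[conflict][1],
              "' but the edge list has it in layer '",
              node_df$layer[known[conflict][1]], "'")
    }
    new_nodes <- unique(at[is.na(known), c("node", "layer")])
    if (nrow(new_nodes) > 0) node_df <- rbind(node_df, new_nodes)
    attrs <- split(setNames(at$value, at$key), at$node)
    attrs <- lapply(attrs, function(v) v)
  }
  edges <- data.frame(
    from = m[, 1], to = m[, 2], type = m[, 5],
    directed = dirflag == "true", stringsAsFactors = FALSE
  )
  mlnet(node_df, edges, attrs)
}

#' Write a multi-layer network as an edge list
#'
#' Rows are sorted lexicographically for deterministic diffs. Attributes,
#' when present, are written to `attrs_path` in the four-column format that
#' [read_edge_list()] consumes.
#'
#' @param net a [mlnet] object.
#' @param path output edge-list path.
#' @param attrs_path optional output path for the node-attribute table;
#'   isolated nodes are always recorded there (with a `layer` pseudo-key) so
#'   a round trip preserves them.
#' @export
write_edge_list <- function(net, path, attrs_path = NULL) {
  lay <- node_layers(net)
  e <- net$edges
  out <- data.frame(
    source = e$from, target = e$to,
    source_layer = unname(lay[e$from]), target_layer = unname(lay[e$to]),
    interaction_type = e$type,
    directed = ifelse(e$directed, "true", "false")
  )
  out <- out[order(out$source, out$target, out$interaction_type,
                   out$directed), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(attrs_path)) {
    rows <- list()
    for (nd in names(net$attrs)) {
      a <- net$attrs[[nd]]
      if (length(a) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          node = nd, layer = unname(lay[nd]), key = names(a),
          value = unname(a))
      }
    }
    isolated <- setdiff(node_ids(net), c(e$from, e$to))
    for (nd in isolated) {
      rows[[length(rows) + 1L]] <- data.frame(
        node = nd, layer = unname(lay[nd]), key = ".layer",
        value = unname(lay[nd]))
    }
    at <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(node = character(), layer = character(),
                 key = character(), value = character())
    at <- at[order(at$node, at$key), , drop = FALSE]
    write.table(at, attrs_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Directed graph view under a directionality mode
#'
#' Returns a directed igraph over all nodes of the network. Undirected
#' edges are traversable both ways in every mode. Directed edges follow
#' their stored direction under `downstream`, are reversed under `upstream`
#' (the influence of the rest of the network on a node), and become
#' bidirectional under `non_directed`.
#'
#' @param net a [mlnet] object.
#' @param mode one of `"downstream"`, `"upstream"`, `"non_directed"`.
#' @return a directed [igraph::igraph] graph.
#' @export
directionality_view <- function(net, mode = "non_directed") {
  mode <- check_mode(mode)
  e <- net$edges
  und <- e[!e$directed, , drop = FALSE]
  dir <- e[e$directed, , drop = FALSE]
  from <- c(und$from, und$to)
  to <- c(und$to, und$from)
  if (nrow(dir) > 0) {
    if (mode == "downstream") {
      from <- c(from, dir$from); to <- c(to, dir$to)
    } else if (mode == "upstream") {
      from <- c(from, dir$to); to <- c(to, dir$from)
    } else {
      from <- c(from, dir$from, dir$to); to <- c(to, dir$to, dir$from)
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, nrow(net$nodes), name = net$nodes$node,
                            layer = net$nodes$layer)
  if (length(from) > 0) {
    g <- igraph::add_edges(g, rbind(from, to))
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

# Simple undirected view: every edge (directed or not) becomes one
# undirected edge; used for centralities, similarity, modules, cliques and
# set distances, none of which are assigned a directionality mode.
undirected_view <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(net$nodes), name = net$nodes$node,
                            layer = net$nodes$layer)
  e <- net$edges
  if (nrow(e) > 0) g <- igraph::add_edges(g, rbind(e$from, e$to))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Filter nodes by an attribute predicate
#'
#' Nodes for which `predicate(attrs, node, layer)` is not `TRUE` are removed
#' together with all incident edges; the generalization of keeping only
#' genes expressed above a tissue-specific threshold.
#'
#' @param net a [mlnet] object.
#' @param predicate function of `(attrs, node, layer)` returning a single
#'   logical; `attrs` is the node's named character vector of attributes
#'   (possibly empty).
#' @return the induced [mlnet] on the kept nodes.
#' @export
filter_nodes <- function(net, predicate) {
  stopifnot(is.function(predicate))
  keep <- vapply(seq_len(nrow(net$nodes)), function(i) {
    nd <- net$nodes$node[i]
    isTRUE(predicate(net$attrs[[nd]] %||% character(), nd,
                     net$nodes$layer[i]))
  }, logical(1))
  kept <- net$nodes$node[keep]
  e <- net$edges
  e <- e[e$from %in% kept & e$to %in% kept, , drop = FALSE]
  mlnet(net$nodes[keep, , drop = FALSE], e,
        net$attrs[intersect(names(net$attrs), kept)])
}

#' Induced single-layer subnetwork
#'
#' Keeps the nodes of one layer and only intra-layer edges (inter-layer
#' edges such as gene-to-protein translation are excluded).
#'
#' @param net a [mlnet] object.
#' @param layer one of the five layer labels.
#' @return a [mlnet]; empty when the layer has no nodes.
#' @export
layer_subgraph <- function(net, layer) {
  layer <- match.arg(layer, MLNET_LAYERS)
  keep <- net$nodes$layer == layer
  kept <- net$nodes$node[keep]
  e <- net$edges
  e <- e[e$from %in% kept & e$to %in% kept, , drop = FALSE]
  mlnet(net$nodes[keep, , drop = FALSE], e,
        net$attrs[intersect(names(net$attrs), kept)])
}

#' Read a target-label table
#'
#' @param path TSV with columns `protein`, `label` (`positive`/`unlabeled`)
#'   and `druggable` (`true`/`false`); druggability plays the role of a
#'   Tclin/Tchem-style filter on which proteins enter the learning set.
#' @param net optional [mlnet]; when given, every protein must exist in the
#'   protein layer.
#' @return data.frame with columns `protein`, `label`, `druggable`.
#' @export
read_target_labels <- function(path, net = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein", "label", "druggable") %in% names(tab))) {
    stop_np("label table must have columns protein label druggable")
  }
  tab$protein <- as.character(tab$protein)
  if (anyDuplicated(tab$protein)) stop_np("duplicated protein ids")
  if (!all(tab$label %in% c("positive", "unlabeled"))) {
    stop_np("label must be 'positive' or 'unlabeled'")
  }
  if (is.character(tab$druggable)) {
    tab$druggable <- tolower(tab$druggable) == "true"
  }
  if (!is.null(net)) {
    prot <- net$nodes$node[net$nodes$layer == "protein"]
    missing <- setdiff(tab$protein, prot)
    if (length(missing) > 0) {
      stop_np("label-table protein(s) absent from the protein layer: ",
              paste(head(missing, 5), collapse = ", "))
    }
  }
  tab[, c("protein", "label", "druggable")]
}
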