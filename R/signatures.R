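SIGNATURE_KINDS <- c("mutation", "sv", "cna", "deg_up", "deg_down",
                     "combined_deg", "combined_alteration", "combined_all",
                     "refined")

#' Disease gene/protein signature set
#'
#' @param name signature name.
#' @param kind one of `mutation`, `sv`, `cna`, `deg_up`, `deg_down`,
#'   `combined_deg`, `combined_alteration`, `combined_all`, `refined`.
#' @param members character vector of node ids.
#' @param layer `"gene"` or `"protein"`.
#' @param parent_signature,parent_module for `refined` signatures, the
#'   names of the parent signature and module.
#' @export
signature_set <- function(name, kind, members, layer = "gene",
                          parent_signature = NULL, parent_module = NULL) {
  kind <- match.arg(kind, SIGNATURE_KINDS)
  layer <- match.arg(layer, c("gene", "protein"))
  members <- sort(unique(as.character(members)))
  structure(
    list(name = name, kind = kind, members = members, layer = layer,
         parent_signature = parent_signature, parent_module = parent_module,
         usable = length(members) > 0),
    class = "signature_set"
  )
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set '%s' (%s, %s layer): %d members%s\n",
              x$name, x$kind, x$layer, length(x$members),
              if (x$usable) "" else " [unusable: empty]"))
  invisible(x)
}

#' Selection criteria for building a signature from a statistics table
#'
#' Default thresholds follow the usual case-study cutoffs: mutated genes at
#' frequency >= 5%, structural variants >= 1%, copy-number alterations
#' >= 12%; differential expression at |log2 fold change| > 2 with adjusted
#' p < 0.05.
#'
#' @param kind signature kind (`mutation`, `sv`, `cna`, `deg_up`,
#'   `deg_down`).
#' @param frequency_threshold,logfc_threshold,padj_threshold overrides.
#' @export
signature_criteria <- function(kind, frequency_threshold = NULL,
                               logfc_threshold = 2, padj_threshold = 0.05) {
  kind <- match.arg(kind, c("mutation", "sv", "cna", "deg_up", "deg_down"))
  if (is.null(frequency_threshold)) {
    frequency_threshold <- switch(kind, mutation = 0.05, sv = 0.01,
                                  cna = 0.12, NA_real_)
  }
  stopifnot(logfc_threshold > 0, padj_threshold > 0)
  list(kind = kind, frequency_threshold = frequency_threshold,
       logfc_threshold = logfc_threshold, padj_threshold = padj_threshold)
}

#' Build a signature from a per-gene statistics table
#'
#' Alteration kinds (`mutation`, `sv`, `cna`) keep genes with
#' `frequency >= frequency_threshold`. DEG kinds require
#' `padj < padj_threshold` and a signed log2 fold change beyond the
#' threshold: `deg_up` keeps `logFC > +t`, `deg_down` keeps `logFC < -t`.
#'
#' @param table data.frame with column `gene` plus `frequency` (alteration
#'   kinds) or `logFC` and `padj` (DEG kinds).
#' @param criteria a [signature_criteria()] list.
#' @param name signature name (defaults to the kind).
#' @export
build_signature <- function(table, criteria, name = criteria$kind) {
  if (!"gene" %in% names(table)) stop_np("table lacks a 'gene' column")
  kind <- criteria$kind
  if (kind %in% c("mutation", "sv", "cna")) {
    if (!"frequency" %in% names(table)) {
      stop_np("'", kind, "' signature needs a 'frequency' column")
    }
    keep <- table$frequency >= criteria$frequency_threshold
  } else {
    if (!all(c("logFC", "padj") %in% names(table))) {
      stop_np("'", kind, "' signature needs 'logFC' and 'padj' columns")
    }
    keep <- table$padj < criteria$padj_threshold &
      (if (kind == "deg_up") table$logFC > criteria$logfc_threshold
       else table$logFC < -criteria$logfc_threshold)
  }
  signature_set(name, kind, table$gene[keep & !is.na(keep)], layer = "gene")
}

#' Combine signatures by member union
#'
#' @param parts list of [signature_set] objects on the same layer.
#' @param name combined name.
#' @param kind combined kind; inferred when `NULL` (`combined_deg` when all
#'   parts are DEG sets, `combined_alteration` when all are alteration
#'   sets, otherwise `combined_all`).
#' @export
combine_signatures <- function(parts, name, kind = NULL) {
  stopifnot(length(parts) >= 1)
  layers <- unique(vapply(parts, `[[`, character(1), "layer"))
  if (length(layers) > 1) {
    stop_np("cannot combine signatures across layers: ",
            paste(layers, collapse = ", "))
  }
  kinds <- vapply(parts, `[[`, character(1), "kind")
  if (is.null(kind)) {
    kind <- if (all(kinds %in% c("deg_up", "deg_down", "combined_deg"))) {
      "combined_deg"
    } else if (all(kinds %in% c("mutation", "sv", "cna",
                                "combined_alteration"))) {
      "combined_alteration"
    } else "combined_all"
  }
  members <- sort(unique(unlist(lapply(parts, `[[`, "members"))))
  signature_set(name, kind, members, layer = layers)
}

#' Map a signature onto a network layer
#'
#' `layer = "gene"`: members are intersected with the gene layer.
#' `layer = "protein"`: members are translated through the gene-to-protein
#' mapping (one-to-many mappings fan out to every mapped protein) and
#' intersected with the protein layer; unmapped genes are dropped with a
#' logged count.
#'
#' @param sig a gene-layer [signature_set].
#' @param net a [mlnet].
#' @param layer `"gene"` or `"protein"`.
#' @param gene_to_protein data.frame with columns `gene`, `protein`
#'   (required for `layer = "protein"`).
#' @export
map_signature_to_layer <- function(sig, net, layer = c("gene", "protein"),
                                   gene_to_protein = NULL) {
  layer <- match.arg(layer)
  if (layer == "gene") {
    genes <- net$nodes$node[net$nodes$layer == "gene"]
    members <- intersect(sig$members, genes)
  } else {
    if (is.null(gene_to_protein)) {
      stop_np("protein mapping requires a gene_to_protein table")
    }
    stopifnot(all(c("gene", "protein") %in% names(gene_to_protein)))
    hit <- gene_to_protein[gene_to_protein$gene %in% sig$members, ,
                           drop = FALSE]
    unmapped <- setdiff(sig$members, hit$gene)
    if (length(unmapped) > 0) {
      message(length(unmapped), " signature gene(s) without a protein ",
              "mapping dropped")
    }
    prots <- net$nodes$node[net$nodes$layer == "protein"]
    members <- intersect(unique(hit$protein), prots)
  }
  out <- signature_set(paste0(sig$name, "_", layer), sig$kind, members,
                       layer = layer,
                       parent_signature = sig$parent_signature,
                       parent_module = sig$parent_module)
  out
}

#' Refine a signature by intersection with modules
#'
#' One refined signature per `(signature, module)` pair whose intersection
#' has at least `min_size` members; parents are recorded so selected
#' features can later be tallied per source signature.
#'
#' @param sig a [signature_set].
#' @param modules a [module_set].
#' @param min_size minimum intersection size (default 2: a singleton
#'   refined set would duplicate a single-node proximity feature).
#' @return list of refined [signature_set] objects.
#' @export
refine_by_modules <- function(sig, modules, min_size = 2) {
  stopifnot(inherits(modules, "module_set"))
  out <- list()
  for (m in modules$modules) {
    inter <- intersect(sig$members, m$members)
    if (length(inter) < min_size) next
    out[[length(out) + 1L]] <- signature_set(
      name = paste0(sig$name, "&", m$id), kind = "refined",
      members = inter, layer = sig$layer,
      parent_signature = sig$name, parent_module = m$id
    )
  }
  out
}

#' Read precomputed signature sets from a GMT file
#'
#' One set per line: `name <TAB> description <TAB> member1 <TAB> member2
#' ...`. The description field is ignored; sets are loaded with kind
#' `combined_all` unless the name matches a known kind.
#'
#' @param path GMT file path.
#' @param layer layer the members live on (`"gene"` or `"protein"`).
#' @return list of [signature_set] objects.
#' @export
read_signature_gmt <- function(path, layer = "gene") {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop_np("malformed GMT line: ", substr(ln, 1, 40))
    kind <- if (f[1] %in% SIGNATURE_KINDS) f[1] else "combined_all"
    out[[f[1]]] <- signature_set(f[1], kind, f[-(1:2)], layer = layer)
  }
  out
}

#' Average shortest-path distance from a node to a signature
#'
#' Identical distance semantics to [module_distance()], applied to the
#' signature's layer-mapped members.
#'
#' @param net a [mlnet].
#' @param node node id.
#' @param sig a non-empty [signature_set].
#' @export
signature_distance <- function(net, node, sig) {
  if (!sig$usable || length(sig$members) == 0) {
    stop_np("signature '", sig$name, "' is empty/unusable for distances")
  }
  module_distance(net, node, sig$members)
}

#' Signature-proximity feature matrix
#'
#' One column per signature; the category is `signature_gene` or
#' `signature_protein` according to the signature's layer, and refined
#' signatures carry their parent annotations in the metadata.
#'
#' @param net a [mlnet].
#' @param targets character vector of node ids.
#' @param signatures list of [signature_set] objects.
#' @export
signature_feature_matrix <- function(net, targets, signatures) {
  if (length(targets) == 0) stop_np("empty target list")
  signatures <- Filter(function(s) s$usable, signatures)
  if (length(signatures) == 0) {
    vals <- matrix(numeric(0), length(targets), 0,
                   dimnames = list(targets, character()))
    return(feature_matrix(vals, data.frame(
      feature_id = character(), category = character(),
      mode = character(), referenced_entity = character())))
  }
  mods <- lapply(signatures, function(s) {
    members <- intersect(s$members, node_ids(net))
    if (length(members) == 0) {
      stop_np("signature '", s$name, "' has no member in the network")
    }
    list(id = s$name, kind = "cluster", members = members,
         provenance = "signature")
  })
  fm <- module_feature_matrix(net, targets, module_set(mods))
  layers <- vapply(signatures, `[[`, character(1), "layer")
  meta <- data.frame(
    feature_id = vapply(signatures, `[[`, character(1), "name"),
    category = paste0("signature_", layers),
    mode = NA_character_,
    referenced_entity = vapply(signatures, `[[`, character(1), "name"),
    signature_kind = vapply(signatures, `[[`, character(1), "kind"),
    parent_signature = vapply(signatures, function(s)
      s$parent_signature %||% NA_character_, character(1)),
    parent_module = vapply(signatures, function(s)
      s$parent_module %||% NA_character_, character(1)),
    stringsAsFactors = FALSE
  )
  feature_matrix(fm$values, meta)
}
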