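#' Specification for a synthetic multi-layer fixture
#'
#' Describes a five-layer network with planted positive-unlabeled
#' structure. All druggable targets receive the same number of extra
#' protein-protein edges (uniformly placed, so degree alone carries no
#' label signal); positives and hidden positives are then wired into a
#' "disease neighborhood" (the proteins of the signature genes) until
#' their mean hop distance to it sits `effect_size` background standard
#' deviations below the background mean — a planted separation calibrated
#' directly in SD units. `effect_size = 0` plants nothing, leaving the
#' groups exchangeable.
#'
#' @param n_gene,n_protein,n_metabolite,n_go,n_pathway nodes per layer.
#' @param ppi_edges_per_node preferential-attachment edges per new protein
#'   node (degree-heterogeneous PPI backbone).
#' @param frac_translated fraction of proteins with a coding-gene
#'   translation edge.
#' @param n_tf,tf_out_degree transcription-factor proteins and their
#'   regulated-gene count (directed protein -> gene edges).
#' @param n_mirna,mirna_out_degree miRNA-style regulator genes and their
#'   directed gene -> gene edges.
#' @param n_druggable,n_positives,n_hidden_positives druggable protein
#'   targets, labelled positives, and planted hidden positives (labelled
#'   unlabeled, recorded in the truth).
#' @param extra_edges_per_target extra PPI edges planted per druggable
#'   target.
#' @param effect_size planted separation (>= 0); see Description.
#' @param signature_sizes named integer vector for kinds `mutation`, `sv`,
#'   `cna`, `deg_up`, `deg_down`.
#' @param seed integer master seed.
#' @export
fixture_spec <- function(n_gene = 200, n_protein = 200, n_metabolite = 60,
                         n_go = 80, n_pathway = 60,
                         ppi_edges_per_node = 2, frac_translated = 0.9,
                         n_tf = 15, tf_out_degree = 4,
                         n_mirna = 10, mirna_out_degree = 3,
                         n_druggable = 120, n_positives = 12,
                         n_hidden_positives = 6,
                         extra_edges_per_target = 6, effect_size = 2,
                         signature_sizes = c(mutation = 6, sv = 4,
                                             cna = 8, deg_up = 10,
                                             deg_down = 15),
                         seed = 1L) {
  spec <- as.list(environment())
  stopifnot(effect_size >= 0, n_hidden_positives <= n_druggable - n_positives,
            n_positives + n_hidden_positives <= n_druggable,
            n_druggable <= n_protein,
            all(signature_sizes <= n_gene), all(signature_sizes > 0))
  class(spec) <- "fixture_spec"
  spec
}

#' Generate a synthetic multi-layer fixture with planted PU structure
#'
#' Builds the five-layer network (scale-free PPI backbone, directed
#' gene -> protein translation edges, directed TF protein -> gene and
#' miRNA-style gene -> gene regulation, undirected protein-metabolite
#' edges, undirected GO/pathway membership edges), draws the five base
#' signature statistic tables, labels druggable targets, and plants the
#' positive/hidden-positive disease-neighborhood attachment.
#'
#' @param spec a [fixture_spec()].
#' @return list with `network` ([mlnet]), `labels` (data.frame `protein`,
#'   `label`, `druggable`), `signature_tables` (named list of data.frames),
#'   `gene_to_protein` (data.frame), and `truth` (list recording hidden
#'   positives, the disease neighborhood and the planted parameters).
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  genes <- sprintf("g%03d", seq_len(spec$n_gene))
  prots <- sprintf("p%03d", seq_len(spec$n_protein))
  mets <- sprintf("m%03d", seq_len(spec$n_metabolite))
  gos <- sprintf("go%03d", seq_len(spec$n_go))
  paths <- sprintf("pw%03d", seq_len(spec$n_pathway))
  nodes <- data.frame(
    node = c(genes, prots, mets, gos, paths),
    layer = rep(c("gene", "protein", "metabolite", "go", "pathway"),
                c(spec$n_gene, spec$n_protein, spec$n_metabolite,
                  spec$n_go, spec$n_pathway))
  )
  edges <- list()
  add <- function(from, to, type, directed) {
    edges[[length(edges) + 1L]] <<- data.frame(
      from = from, to = to, type = type, directed = directed)
  }
  # PPI backbone: degree-heterogeneous preferential attachment
  gp <- igraph::sample_pa(spec$n_protein, m = spec$ppi_edges_per_node,
                          directed = FALSE)
  el <- igraph::as_edgelist(gp, names = FALSE)
  add(prots[el[, 1]], prots[el[, 2]], "ppi", FALSE)
  # gene -> protein translation (gene i codes protein i)
  translated <- seq_len(round(spec$frac_translated * spec$n_protein))
  add(genes[translated], prots[translated], "translation", TRUE)
  g2p <- data.frame(gene = genes[translated], protein = prots[translated])
  # TF regulation: protein -> gene
  tfs <- sample(prots, spec$n_tf)
  for (tf in tfs) {
    add(rep(tf, spec$tf_out_degree), sample(genes, spec$tf_out_degree),
        "tf_regulation", TRUE)
  }
  # miRNA-style regulation: gene -> gene
  mirnas <- sample(genes, spec$n_mirna)
  for (mi in mirnas) {
    tg <- sample(setdiff(genes, mi), spec$mirna_out_degree)
    add(rep(mi, spec$mirna_out_degree), tg, "mirna_regulation", TRUE)
  }
  # protein - metabolite interactions
  for (mt in mets) {
    add(rep(mt, 2), sample(prots, 2), "metabolite_interaction", FALSE)
  }
  # GO annotation: genes and proteins
  ann_g <- sample(genes, round(0.5 * spec$n_gene))
  add(ann_g, sample(gos, length(ann_g), replace = TRUE),
      "go_annotation", FALSE)
  ann_p <- sample(prots, round(0.5 * spec$n_protein))
  add(ann_p, sample(gos, length(ann_p), replace = TRUE),
      "go_annotation", FALSE)
  # pathway membership: most proteins, some genes and metabolites
  pw_p <- sample(prots, round(0.8 * spec$n_protein))
  add(pw_p, sample(paths, length(pw_p), replace = TRUE),
      "pathway_membership", FALSE)
  pw_g <- sample(genes, round(0.3 * spec$n_gene))
  add(pw_g, sample(paths, length(pw_g), replace = TRUE),
      "pathway_membership", FALSE)
  pw_m <- sample(mets, round(0.3 * spec$n_metabolite))
  add(pw_m, sample(paths, length(pw_m), replace = TRUE),
      "pathway_membership", FALSE)

  # base signatures over genes (overlaps allowed)
  sig_members <- lapply(spec$signature_sizes, function(k) sample(genes, k))
  names(sig_members) <- names(spec$signature_sizes)
  sig_genes <- unique(unlist(sig_members))
  neighborhood <- intersect(
    g2p$protein[g2p$gene %in% sig_genes], prots)

  # druggable targets and PU labels
  druggable <- sample(prots, spec$n_druggable)
  positives <- sample(druggable, spec$n_positives)
  hidden <- sample(setdiff(druggable, positives),
                   spec$n_hidden_positives)
  planted <- c(positives, hidden)
  # every druggable target attaches extra PPI edges uniformly, so degree
  # alone does not mark the labels
  for (tg in druggable) {
    others <- sample(setdiff(prots, tg), spec$extra_edges_per_target)
    add(tg, others, "ppi", FALSE)
  }
  # planting, calibrated in SD units: positives and hidden positives get
  # direct edges into the disease neighborhood until their mean hop
  # distance to it sits effect_size background-SDs below the background
  # mean; effect_size 0 plants nothing, leaving the groups exchangeable
  if (spec$effect_size > 0 && length(neighborhood) > 0) {
    interim <- mlnet(nodes, do.call(rbind, edges))
    g <- undirected_view(interim)
    D <- igraph::distances(g, v = druggable, to = neighborhood)
    D[!is.finite(D)] <- max(D[is.finite(D)]) + 1
    prox <- rowMeans(D)
    background <- setdiff(druggable, planted)
    mu <- mean(prox[background])
    sigma <- sd(prox[background])
    target_prox <- mu - spec$effect_size * sigma
    for (tg in planted) {
      d <- D[tg, ]
      ord <- order(d, decreasing = TRUE)
      k <- 0L
      while (mean(d) > target_prox && k < length(d)) {
        k <- k + 1L
        if (d[ord[k]] <= 1) break
        d[ord[k]] <- 1
      }
      if (k > 0) {
        new_nb <- setdiff(colnames(D)[ord[seq_len(k)]], tg)
        if (length(new_nb) > 0) add(tg, new_nb, "ppi", FALSE)
      }
    }
  }

  edge_df <- do.call(rbind, edges)
  attrs <- setNames(
    lapply(genes, function(g)
      c(expressed = ifelse(runif(1) < 0.9, "true", "false"))),
    genes)
  net <- mlnet(nodes, edge_df, attrs)

  labels <- data.frame(
    protein = druggable,
    label = ifelse(druggable %in% positives, "positive", "unlabeled"),
    druggable = TRUE
  )
  labels <- labels[order(labels$protein), ]
  rownames(labels) <- NULL

  sig_tables <- list()
  thresholds <- c(mutation = 0.05, sv = 0.01, cna = 0.12)
  for (kind in c("mutation", "sv", "cna")) {
    thr <- thresholds[[kind]]
    memb <- genes %in% sig_members[[kind]]
    freq <- ifelse(memb, thr * (1 + runif(spec$n_gene, 0.2, 3)),
                   thr * runif(spec$n_gene, 0, 0.9))
    sig_tables[[kind]] <- data.frame(gene = genes,
                                     frequency = round(freq, 4))
  }
  up <- genes %in% sig_members$deg_up
  down <- genes %in% sig_members$deg_down & !up
  logfc <- ifelse(up, runif(spec$n_gene, 2.2, 5),
                  ifelse(down, -runif(spec$n_gene, 2.2, 5),
                         runif(spec$n_gene, -1.8, 1.8)))
  padj <- ifelse(up | down, runif(spec$n_gene, 1e-5, 0.04),
                 runif(spec$n_gene, 0, 1))
  sig_tables$deg <- data.frame(gene = genes, logFC = round(logfc, 3),
                               padj = signif(padj, 4))

  truth <- list(
    hidden_positives = sort(hidden), positives = sort(positives),
    disease_neighborhood = sort(neighborhood),
    signature_genes = sort(sig_genes),
    effect_size = spec$effect_size, seed = spec$seed
  )
  list(network = net, labels = labels, signature_tables = sig_tables,
       gene_to_protein = g2p, truth = truth, spec = spec)
}

#' Write a fixture bundle to disk
#'
#' Emits exactly the plain-text formats the pipeline consumes: the
#' edge-list and node-attribute TSVs, the target-label TSV, one statistics
#' TSV per signature table, the gene-to-protein mapping TSV, and the
#' planted truth as JSON.
#'
#' @param bundle result of [generate_fixture()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    edges = file.path(dir, "edges.tsv"),
    node_attrs = file.path(dir, "node_attrs.tsv"),
    labels = file.path(dir, "labels.tsv"),
    gene_to_protein = file.path(dir, "gene_to_protein.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_edge_list(bundle$network, paths["edges"], paths["node_attrs"])
  write.table(bundle$labels, paths["labels"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(bundle$gene_to_protein, paths["gene_to_protein"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (kind in names(bundle$signature_tables)) {
    p <- file.path(dir, sprintf("signature_%s.tsv", kind))
    write.table(bundle$signature_tables[[kind]], p, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths[paste0("signature_", kind)] <- p
  }
  jsonlite::write_json(bundle$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}

#' Planted feature-matrix fixture for selection benchmarks
#'
#' A label vector plus a numeric matrix of `n_informative` features whose
#' class means differ by `effect` standard deviations, among `n_noise`
#' standard-normal noise features.
#'
#' @param n rows (targets).
#' @param n_informative,n_noise feature counts.
#' @param effect class-mean separation in SD units.
#' @param pos_fraction fraction of positive rows.
#' @param seed integer seed.
#' @return list with `features` ([feature_matrix]), `labels` and
#'   `informative` (the planted feature ids).
#' @export
generate_feature_fixture <- function(n = 300, n_informative = 5,
                                     n_noise = 200, effect = 2,
                                     pos_fraction = 0.3, seed = 1L) {
  set.seed(seed)
  n_pos <- round(n * pos_fraction)
  y <- factor(rep(c("positive", "unlabeled"), c(n_pos, n - n_pos)),
              levels = c("positive", "unlabeled"))
  shift <- as.numeric(y == "positive") * effect
  X <- matrix(rnorm(n * (n_informative + n_noise)), nrow = n)
  for (j in seq_len(n_informative)) X[, j] <- X[, j] + shift
  ids <- c(sprintf("info%02d", seq_len(n_informative)),
           sprintf("noise%03d", seq_len(n_noise)))
  colnames(X) <- ids
  rownames(X) <- sprintf("t%03d", seq_len(n))
  fm <- feature_matrix(X, data.frame(
    feature_id = ids, category = "planted", mode = NA_character_,
    referenced_entity = NA_character_, stringsAsFactors = FALSE))
  list(features = fm, labels = setNames(as.character(y), rownames(X)),
       informative = ids[seq_len(n_informative)])
}
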