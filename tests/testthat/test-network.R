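test_that("edge-list reader handles minimal input and undirected collapse", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "source\ttarget\tsource_layer\ttarget_layer\tinteraction_type\tdirected",
    "A\tB\tprotein\tprotein\tppi\tfalse"), f)
  net <- read_edge_list(f)
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 1)
  expect_false(net$edges$directed)

  # same undirected edge listed both ways collapses to one
  writeLines(c(
    "source\ttarget\tsource_layer\ttarget_layer\tinteraction_type\tdirected",
    "A\tB\tprotein\tprotein\tppi\tfalse",
    "B\tA\tprotein\tprotein\tppi\tfalse"), f)
  expect_equal(nrow(read_edge_list(f)$edges), 1)
})

test_that("malformed rows and unknown layers are rejected with position", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "source\ttarget\tsource_layer\ttarget_layer\tinteraction_type\tdirected",
    "A\tB\tprotein\tprotein\tppi\tfalse",
    "C\tD\tprotein"), f)
  expect_error(read_edge_list(f), "line 3")
  writeLines(c(
    "source\ttarget\tsource_layer\ttarget_layer\tinteraction_type\tdirected",
    "A\tB\tprotein\tmystery\tppi\tfalse"), f)
  expect_error(read_edge_list(f), "unknown layer")
  writeLines("source\ttarget", f)
  expect_error(read_edge_list(f), "header")
})

test_that("construction enforces invariants (loops, duplicates, endpoints)", {
  nodes <- data.frame(node = c("A", "B"), layer = "protein")
  expect_warning(
    net <- mlnet(nodes, data.frame(from = c("A", "A"), to = c("A", "B"),
                                   type = "ppi", directed = FALSE)),
    "self-loop")
  expect_equal(nrow(net$edges), 1)
  expect_error(
    mlnet(nodes, data.frame(from = "A", to = "Z", type = "ppi",
                            directed = FALSE)),
    "endpoint")
  # duplicate (source, target, type) collapses; reciprocal directed arcs kept
  net2 <- mlnet(nodes, data.frame(from = c("A", "A", "A", "B"),
                                  to = c("B", "B", "B", "A"),
                                  type = c("ppi", "ppi", "reg", "reg"),
                                  directed = c(FALSE, FALSE, TRUE, TRUE)))
  expect_equal(nrow(net2$edges), 3)
  expect_equal(sum(net2$edges$directed), 2)
})

test_that("read/write round trip is the identity on a random fixture", {
  net <- random_mlnet(25, 50, seed = 11)
  f <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, f, fa)
  back <- read_edge_list(f, fa)
  expect_setequal(back$nodes$node, net$nodes$node)
  expect_equal(node_layers(back)[net$nodes$node], node_layers(net))
  key <- function(n) {
    e <- n$edges
    sort(paste(e$from, e$to, e$type, e$directed))
  }
  expect_equal(key(back), key(net))
})

test_that("directionality views follow, reverse, or ignore stored arcs", {
  net <- protein_net("C-D", directed_edges = "A>B")
  arcs <- function(mode) {
    el <- igraph::as_edgelist(directionality_view(net, mode))
    sort(paste(el[, 1], el[, 2]))
  }
  expect_equal(arcs("downstream"), sort(c("A B", "C D", "D C")))
  expect_equal(arcs("upstream"), sort(c("B A", "C D", "D C")))
  expect_equal(arcs("non_directed"), sort(c("A B", "B A", "C D", "D C")))
})

test_that("non_directed arc count is twice the edge count; views reverse", {
  for (s in 1:3) {
    net <- random_mlnet(15, 30, seed = s)
    g_nd <- directionality_view(net, "non_directed")
    expect_equal(igraph::ecount(g_nd), 2 * nrow(net$edges))
    el_d <- igraph::as_edgelist(directionality_view(net, "downstream"))
    el_u <- igraph::as_edgelist(directionality_view(net, "upstream"))
    expect_setequal(paste(el_d[, 1], el_d[, 2]),
                    paste(el_u[, 2], el_u[, 1]))
  }
})

test_that("filter_nodes removes failing nodes with incident edges, idempotently", {
  nodes <- data.frame(node = c("A", "B", "C"), layer = "protein")
  net <- mlnet(nodes,
               data.frame(from = c("A", "B"), to = c("B", "C"),
                          type = "ppi", directed = FALSE),
               attrs = list(A = c(expressed = "true"),
                            B = c(expressed = "false"),
                            C = c(expressed = "true")))
  keep_expressed <- function(attrs, node, layer) {
    identical(unname(attrs["expressed"]), "true")
  }
  sub <- filter_nodes(net, keep_expressed)
  expect_setequal(sub$nodes$node, c("A", "C"))
  expect_equal(nrow(sub$edges), 0)  # cut node B removed both edges
  # idempotence and identity predicate
  expect_equal(filter_nodes(sub, keep_expressed)$nodes, sub$nodes)
  all_true <- filter_nodes(net, function(a, n, l) TRUE)
  expect_equal(all_true$edges, net$edges)
})

test_that("layer_subgraph keeps only intra-layer edges", {
  nodes <- data.frame(node = c("P1", "P2", "G1"),
                      layer = c("protein", "protein", "gene"))
  net <- mlnet(nodes, data.frame(
    from = c("P1", "G1"), to = c("P2", "P1"),
    type = c("ppi", "translation"), directed = c(FALSE, TRUE)))
  sub <- layer_subgraph(net, "protein")
  expect_equal(nrow(sub$nodes), 2)
  expect_equal(nrow(sub$edges), 1)
  expect_equal(nrow(layer_subgraph(net, "metabolite")$nodes), 0)
  fx <- default_fixture()
  ps <- layer_subgraph(fx$network, "protein")
  expect_equal(nrow(ps$nodes),
               sum(fx$network$nodes$layer == "protein"))
})

test_that("target-label tables are validated", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein\tlabel\tdruggable",
               "P1\tpositive\ttrue", "P2\tunlabeled\tfalse"), f)
  tab <- read_target_labels(f)
  expect_equal(tab$druggable, c(TRUE, FALSE))
  net <- protein_net("P1-P2")
  expect_silent(read_target_labels(f, net))
  writeLines(c("protein\tlabel\tdruggable", "PX\tpositive\ttrue"), f)
  expect_error(read_target_labels(f, net), "absent from the protein layer")
  writeLines(c("protein\tlabel\tdruggable", "P1\tmaybe\ttrue"), f)
  expect_error(read_target_labels(f), "positive")
})
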