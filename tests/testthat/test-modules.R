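# Two 5-cliques joined by a single bridge edge: every registered
# algorithm should recover the two planted communities.
two_clique_net <- function() {
  cl <- function(prefix) {
    v <- paste0(prefix, 1:5)
    combn(v, 2, function(p) paste0(p[1], "-", p[2]))
  }
  protein_net(c(cl("a"), cl("b"), "a1-b1"))
}

test_that("planted two-community structure is recovered by all algorithms", {
  net <- two_clique_net()
  for (alg in default_cluster_algorithms()) {
    ms <- detect_clusters(net, algorithms = list(alg), seed = 3)
    expect_equal(length(ms), 2, info = alg$name)
    sizes <- sort(vapply(ms$modules, function(m) length(m$members),
                         integer(1)))
    expect_equal(sizes, c(5L, 5L), info = alg$name)
  }
})

test_that("clustering is deterministic under a fixed seed and pools algorithms", {
  net <- two_clique_net()
  ms1 <- detect_clusters(net, seed = 9)
  ms2 <- detect_clusters(net, seed = 9)
  expect_identical(ms1, ms2)
  # identical member sets from different algorithms are deduplicated
  all_members <- lapply(ms1$modules, `[[`, "members")
  expect_equal(anyDuplicated(all_members), 0)
})

test_that("edgeless graphs give an empty module set; unknown algorithm errors", {
  nodes <- data.frame(node = c("A", "B"), layer = "protein")
  net <- mlnet(nodes)
  expect_equal(length(detect_clusters(net)), 0)
  expect_error(detect_clusters(two_clique_net(),
                               algorithms = list(list(name = "nope"))),
               "unknown clustering algorithm")
})

test_that("clique filtering enforces size, maximality and pathway linkage", {
  small <- clique_fixture(10, "s")              # too small
  keep <- clique_fixture(17, "k")               # retained
  bad <- clique_fixture(20, "u", unlinked = "u1")  # one member unlinked
  nodes <- rbind(small$nodes, keep$nodes, bad$nodes)
  edges <- rbind(small$edges, keep$edges, bad$edges)
  net <- mlnet(nodes, edges)
  ms <- filtered_cliques(net)
  expect_equal(length(ms), 1)
  expect_equal(ms$modules[[1]]$members, sort(keep$members))
  # the 16-subcliques of the 17-clique are non-maximal: never reported
  for (m in ms$modules) expect_gte(length(m$members), 17)
  # completeness re-check: all pairs adjacent in the protein layer
  gp <- igraph::as_undirected(
    directionality_view(layer_subgraph(net, "protein"), "non_directed"))
  for (m in ms$modules) {
    pairs <- combn(m$members, 2)
    for (j in seq_len(ncol(pairs))) {
      expect_true(igraph::are_adjacent(gp, pairs[1, j], pairs[2, j]))
    }
  }
})

test_that("module distance averages hop counts, sentinel for unreachable", {
  star <- protein_net("H-L1", "H-L2", "H-L3")
  expect_equal(module_distance(star, "H", c("L1", "L2", "L3")), 1)
  path <- protein_net("A-B", "B-C")
  expect_equal(module_distance(path, "A", c("B", "C")), 1.5)
  # node inside a clique-module of size k: (k-1)/k, self-distance included
  k4 <- protein_net("A-B", "A-C", "A-D", "B-C", "B-D", "C-D")
  expect_equal(module_distance(k4, "A", c("A", "B", "C", "D")), 3 / 4)
  expect_error(module_distance(path, "A", character(0)), "empty")
  expect_equal(module_distance(path, "A", "A"), 0)
})

test_that("module feature matrix matches standalone distances", {
  fx <- default_fixture()
  ppi <- layer_subgraph(fx$network, "protein")
  ms <- detect_clusters(ppi, seed = 1)
  targets <- fx$labels$protein[1:3]
  sub <- module_set(ms$modules[1:4])
  fm <- module_feature_matrix(fx$network, targets, sub)
  expect_equal(dim(fm$values), c(3, 4))
  expect_true(all(is.finite(fm$values)))
  for (i in 1:3) for (j in 1:4) {
    expect_equal(fm$values[i, j],
                 module_distance(fx$network, targets[i],
                                 sub$modules[[j]]),
                 tolerance = 1e-12)
  }
  expect_true(all(fm$meta$category == "cluster"))
})

test_that("module-set serialization round-trips membership", {
  ms <- module_set(list(
    list(id = "m1", kind = "cluster", members = c("A", "B"),
         provenance = "test"),
    list(id = "m2", kind = "clique", members = c("B", "C", "D"),
         provenance = "test")))
  f <- withr::local_tempfile(fileext = ".tsv")
  fp <- withr::local_tempfile(fileext = ".tsv")
  write_module_set(ms, f, fp)
  mem <- read.delim(f)
  expect_equal(nrow(mem), 5)
  expect_setequal(mem$member[mem$module_id == "m2"], c("B", "C", "D"))
})
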