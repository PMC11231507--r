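test_that("signatures apply frequency and DEG thresholds", {
  tab <- data.frame(gene = c("g1", "g2"), frequency = c(0.06, 0.04))
  sig <- build_signature(tab, signature_criteria("mutation"))
  expect_equal(sig$members, "g1")
  deg <- data.frame(gene = c("a", "b", "c", "d"),
                    logFC = c(2.5, 2.5, -3, 1.5),
                    padj = c(0.01, 0.2, 0.01, 0.01))
  up <- build_signature(deg, signature_criteria("deg_up"))
  expect_equal(up$members, "a")  # b fails padj, d fails logFC
  down <- build_signature(deg, signature_criteria("deg_down"))
  expect_equal(down$members, "c")
  empty <- build_signature(data.frame(gene = character(),
                                      frequency = numeric()),
                           signature_criteria("sv"))
  expect_false(empty$usable)
  expect_error(build_signature(data.frame(gene = "g"),
                               signature_criteria("cna")),
               "frequency")
})

test_that("combining signatures unions members and infers kinds", {
  s1 <- signature_set("mut", "mutation", c("a", "b"))
  s2 <- signature_set("cna", "cna", c("b", "c"))
  s3 <- signature_set("up", "deg_up", c("d", "e", "f"))
  comb <- combine_signatures(list(s1, s2), "alt")
  expect_equal(comb$members, c("a", "b", "c"))
  expect_equal(comb$kind, "combined_alteration")
  expect_equal(combine_signatures(list(s3,
    signature_set("dn", "deg_down", "g")), "deg")$kind, "combined_deg")
  all3 <- combine_signatures(list(s1, s2, s3), "all")
  expect_equal(all3$kind, "combined_all")
  # order-invariance and idempotence of union
  expect_equal(combine_signatures(list(s2, s1), "alt")$members,
               comb$members)
  expect_equal(combine_signatures(list(s1, s1), "m")$members, s1$members)
  sp <- signature_set("p", "mutation", "x", layer = "protein")
  expect_error(combine_signatures(list(s1, sp), "bad"), "layers")
})

test_that("layer mapping intersects, fans out, and drops unmapped genes", {
  nodes <- data.frame(
    node = c("g1", "g2", "p1", "p2", "p3"),
    layer = c("gene", "gene", "protein", "protein", "protein"))
  net <- mlnet(nodes)
  sig <- signature_set("s", "mutation", c("g1", "g2", "g9"))
  gmap <- data.frame(gene = c("g1", "g1", "g2"),
                     protein = c("p1", "p2", "pX"))
  expect_message(
    psig <- map_signature_to_layer(sig, net, "protein", gmap),
    "without a protein")
  expect_equal(psig$members, c("p1", "p2"))  # fan-out; pX not in layer
  gsig <- map_signature_to_layer(sig, net, "gene")
  expect_equal(gsig$members, c("g1", "g2"))
  empty <- map_signature_to_layer(
    signature_set("z", "sv", "g9"), net, "gene")
  expect_false(empty$usable)
})

test_that("module refinement intersects and records parents", {
  sig <- signature_set("s", "combined_all", c("a", "b", "c", "x"))
  ms <- module_set(list(
    list(id = "m1", kind = "cluster", members = c("a", "b", "c", "d"),
         provenance = "t"),
    list(id = "m2", kind = "cluster", members = c("y", "z"),
         provenance = "t")))
  ref <- refine_by_modules(sig, ms, min_size = 2)
  expect_length(ref, 1)
  expect_equal(ref[[1]]$members, c("a", "b", "c"))
  expect_equal(ref[[1]]$parent_signature, "s")
  expect_equal(ref[[1]]$parent_module, "m1")
  # refined members are subsets of both parents
  expect_true(all(ref[[1]]$members %in% sig$members))
  expect_true(all(ref[[1]]$members %in% ms$modules[[1]]$members))
  expect_length(refine_by_modules(sig, ms, min_size = 4), 0)
})

test_that("a fully connected signature quartet inside a cluster refines to 4", {
  # four signature genes whose proteins form a clique within one community
  quartet <- c("q1", "q2", "q3", "q4")
  edges <- t(combn(quartet, 2))
  extra <- data.frame(from = c("q1", "r1", "r2"),
                      to = c("r1", "r2", "r3"))
  net <- mlnet(
    data.frame(node = c(quartet, paste0("r", 1:3)), layer = "protein"),
    data.frame(from = c(edges[, 1], extra$from),
               to = c(edges[, 2], extra$to), type = "ppi",
               directed = FALSE))
  ms <- detect_clusters(net, seed = 2)
  sig <- signature_set("all", "combined_all", quartet, layer = "protein")
  ref <- refine_by_modules(sig, ms, min_size = 2)
  sizes <- vapply(ref, function(s) length(s$members), integer(1))
  expect_true(any(sizes == 4))
  best <- ref[[which(sizes == 4)[1]]]
  expect_setequal(best$members, quartet)
})

test_that("signature distances share module-distance semantics", {
  star <- protein_net("H-L1", "H-L2", "H-L3")
  sig <- signature_set("leaves", "mutation", c("L1", "L2", "L3"),
                       layer = "protein")
  expect_equal(signature_distance(star, "H", sig), 1)
  self <- signature_set("self", "mutation", "H", layer = "protein")
  expect_equal(signature_distance(star, "H", self), 0)
  path <- protein_net("A-B", "B-C", "C-D")
  sig2 <- signature_set("bc", "cna", c("B", "D"), layer = "protein")
  # oracle by hand: d(A,B)=1, d(A,D)=3
  expect_equal(signature_distance(path, "A", sig2), 2)
  empty <- signature_set("e", "sv", character())
  expect_error(signature_distance(path, "A", empty), "empty")
})

test_that("signature feature matrix labels layers and matches standalone", {
  fx <- default_fixture()
  sigs <- list(
    signature_set("gs", "mutation",
                  fx$truth$signature_genes[1:5], layer = "gene"),
    signature_set("ps", "mutation",
                  fx$truth$disease_neighborhood[1:5], layer = "protein"))
  targets <- fx$labels$protein[1:3]
  fm <- signature_feature_matrix(fx$network, targets, sigs)
  expect_equal(dim(fm$values), c(3, 2))
  expect_equal(fm$meta$category, c("signature_gene", "signature_protein"))
  for (i in 1:3) {
    expect_equal(fm$values[i, 1],
                 signature_distance(fx$network, targets[i], sigs[[1]]))
  }
})

test_that("combined sets contain their parts (subset invariants)", {
  fx <- default_fixture()
  sigs <- build_signatures_from_tables(fx$signature_tables)
  expect_setequal(sigs$combined_deg$members,
                  union(sigs$deg_up$members, sigs$deg_down$members))
  for (nm in c("mutation", "sv", "cna", "deg_up", "deg_down")) {
    expect_true(all(sigs[[nm]]$members %in% sigs$combined_all$members))
  }
})
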