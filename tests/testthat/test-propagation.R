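test_that("transition matrix is column-stochastic with dangling flags", {
  net <- protein_net("A-B")
  tm <- build_transition_matrix(net, "non_directed")
  expect_equal(tm$W["B", "A"], 1)
  expect_equal(tm$W["A", "B"], 1)
  expect_false(any(tm$dangling))

  star <- protein_net("H-L1", "H-L2", "H-L3")
  tm2 <- build_transition_matrix(star, "non_directed")
  expect_equal(as.numeric(tm2$W[c("L1", "L2", "L3"), "H"]),
               rep(1 / 3, 3))

  dnet <- protein_net(directed_edges = "A>B")
  tm3 <- build_transition_matrix(dnet, "downstream")
  expect_true(tm3$dangling[match("B", tm3$nodes)])
  expect_false(tm3$dangling[match("A", tm3$nodes)])
  # every non-dangling column sums to 1
  cs <- Matrix::colSums(tm2$W)
  expect_true(all(abs(cs - 1) < 1e-12))
})

test_that("pure restart returns the seed indicator", {
  net <- protein_net("A-B", "B-C")
  p <- random_walk_restart(net, "B", restart = 1)
  expect_equal(unname(p$values[c("A", "B", "C")]), c(0, 1, 0))
})

test_that("two-node walk matches the hand-solved fixed point", {
  net <- protein_net("A-B")
  p <- random_walk_restart(net, "A", restart = 0.5)
  expect_equal(unname(p$values["A"]), 2 / 3, tolerance = 1e-10)
  expect_equal(unname(p$values["B"]), 1 / 3, tolerance = 1e-10)
})

test_that("walk profiles match a dense linear-solve oracle on random graphs", {
  for (s in 1:20) {
    net <- random_mlnet(sample(4:10, 1), sample(6:16, 1), seed = 100 + s)
    seed_node <- net$nodes$node[1]
    for (mode in c("downstream", "upstream", "non_directed")) {
      oracle <- rwr_dense_oracle(net, seed_node, 0.7, mode)
      for (method in c("solve", "power")) {
        p <- random_walk_restart(net, seed_node, restart = 0.7,
                                 mode = mode, method = method)
        expect_equal(unname(p$values[names(oracle)]), unname(oracle),
                     tolerance = 1e-8)
        expect_equal(sum(p$values), 1, tolerance = 1e-8)
        expect_true(all(p$values >= -1e-12))
      }
    }
  }
})

test_that("seed absent or bad restart raise errors", {
  net <- protein_net("A-B")
  expect_error(random_walk_restart(net, "Z"), "not in network")
  expect_error(random_walk_restart(net, "A", restart = 0), "restart")
  expect_error(shortest_path_profile(net, "Z"), "not in network")
})

test_that("shortest-path profiles: seed zero, asymmetry, sentinel", {
  dnet <- protein_net(directed_edges = "A>B")
  down <- shortest_path_profile(dnet, "A", "downstream")
  expect_equal(unname(down$values["A"]), 0)
  expect_equal(unname(down$values["B"]), 1)
  up <- shortest_path_profile(dnet, "A", "upstream")
  # B unreachable from A against the arrow: finite sentinel, max finite + 1
  expect_equal(unname(up$values["B"]), up$sentinel)
  expect_equal(up$sentinel, 1)
})

test_that("shortest paths agree with a Floyd-Warshall oracle", {
  for (s in 1:20) {
    net <- random_mlnet(12, 22, seed = 300 + s)
    mode <- c("downstream", "upstream", "non_directed")[(s %% 3) + 1]
    D <- floyd_warshall_oracle(net, mode)
    seed_node <- sample(net$nodes$node, 1)
    prof <- shortest_path_profile(net, seed_node, mode)
    expected <- D[seed_node, names(prof$values)]
    finite <- is.finite(expected)
    expect_identical(unname(prof$values[finite]), unname(expected[finite]))
    if (any(!finite)) {
      expect_true(all(prof$values[!finite] == max(expected[finite]) + 1))
    }
  }
})

test_that("propagation feature matrices have the contracted shape", {
  net <- protein_net("A-B", "B-C", "C-D", "D-E")
  fm <- propagation_feature_matrix(net, c("A", "C"), method = "rwr",
                                   mode = "non_directed")
  expect_equal(dim(fm$values), c(2, 5))
  expect_equal(unname(rowSums(fm$values)), c(1, 1), tolerance = 1e-8)
  expect_equal(unique(fm$meta$category), "rwr_non_directed")
  sp <- propagation_feature_matrix(net, c("A", "C"),
                                   method = "shortest_path")
  expect_true(all(sp$values == floor(sp$values)))
  expect_true(all(is.finite(sp$values)))
  expect_error(propagation_feature_matrix(net, character(0)), "empty")
})

test_that("on all-undirected networks the three modes coincide", {
  net <- protein_net("A-B", "B-C", "C-A", "C-D")
  for (method in c("rwr", "shortest_path")) {
    fms <- lapply(c("downstream", "upstream", "non_directed"), function(m)
      propagation_feature_matrix(net, c("A", "D"), method = method,
                                 mode = m)$values)
    expect_equal(fms[[1]], fms[[2]], ignore_attr = TRUE)
    expect_equal(fms[[1]], fms[[3]], ignore_attr = TRUE)
  }
})

test_that("walk profiles are equivariant under node relabeling", {
  net <- random_mlnet(8, 14, seed = 77)
  perm_names <- setNames(sprintf("z%02d", seq_len(8)), net$nodes$node)
  nodes2 <- data.frame(node = unname(perm_names[net$nodes$node]),
                       layer = net$nodes$layer)
  e <- net$edges
  edges2 <- data.frame(from = unname(perm_names[e$from]),
                       to = unname(perm_names[e$to]),
                       type = e$type, directed = e$directed)
  net2 <- mlnet(nodes2, edges2)
  seed_node <- net$nodes$node[2]
  p1 <- random_walk_restart(net, seed_node, mode = "downstream")
  p2 <- random_walk_restart(net2, unname(perm_names[seed_node]),
                            mode = "downstream")
  expect_equal(unname(p2$values[perm_names[names(p1$values)]]),
               unname(p1$values), tolerance = 1e-10)
})

test_that("seed holds maximal mass at high restart on connected graphs", {
  for (s in 1:5) {
    net <- protein_net("A-B", "B-C", "C-D", "D-A", "A-C")
    nd <- sample(c("A", "B", "C", "D"), 1)
    p <- random_walk_restart(net, nd, restart = 0.5 + s / 12)
    expect_equal(names(which.max(p$values)), nd)
  }
})
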