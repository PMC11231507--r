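# Small graph builders used across the suite.

# Protein-only network from an undirected edge list given as "A-B" strings.
protein_net <- function(..., directed_edges = character()) {
  und <- c(...)
  parse <- function(s) do.call(rbind, strsplit(s, "-", fixed = TRUE))
  edges <- NULL
  if (length(und) > 0) {
    m <- parse(und)
    edges <- data.frame(from = m[, 1], to = m[, 2], type = "ppi",
                        directed = FALSE)
  }
  if (length(directed_edges) > 0) {
    m <- do.call(rbind, strsplit(directed_edges, ">", fixed = TRUE))
    edges <- rbind(edges, data.frame(from = m[, 1], to = m[, 2],
                                     type = "reg", directed = TRUE))
  }
  nodes <- unique(c(edges$from, edges$to))
  mlnet(data.frame(node = nodes, layer = "protein"), edges)
}

# Random mixed-layer network for property tests: n nodes over all five
# layers, m edges with a mix of directed and undirected types.
random_mlnet <- function(n, m, seed, p_directed = 0.3) {
  set.seed(seed)
  layers <- sample(c("gene", "protein", "metabolite", "go", "pathway"),
                   n, replace = TRUE, prob = c(.3, .4, .1, .1, .1))
  nodes <- data.frame(node = sprintf("n%02d", seq_len(n)), layer = layers)
  m <- min(m, n * (n - 1) / 2)
  from <- integer(0); to <- integer(0); seen <- character(0)
  while (length(from) < m) {
    a <- sample.int(n, 1); b <- sample.int(n, 1)
    key <- paste(min(a, b), max(a, b))
    if (a != b && !key %in% seen) {
      from <- c(from, a); to <- c(to, b); seen <- c(seen, key)
    }
  }
  edges <- data.frame(from = nodes$node[from], to = nodes$node[to],
                      type = sample(c("ppi", "reg"), m, replace = TRUE),
                      directed = runif(m) < p_directed)
  mlnet(nodes, edges)
}

# Shared default fixture, generated once per test run.
fixture_cache <- new.env(parent = emptyenv())
default_fixture <- function() {
  if (is.null(fixture_cache$fx)) {
    fixture_cache$fx <- generate_fixture(fixture_spec(seed = 42L))
  }
  fixture_cache$fx
}

# Isolated k-clique of proteins, each linked to a pathway node except
# those listed in `unlinked`; used by the clique-filtering checks.
clique_fixture <- function(k, prefix, unlinked = character()) {
  v <- paste0(prefix, seq_len(k))
  edges <- t(combn(v, 2))
  e <- data.frame(from = edges[, 1], to = edges[, 2], type = "ppi",
                  directed = FALSE)
  pw <- paste0("pw_", prefix)
  linked <- setdiff(v, unlinked)
  e <- rbind(e, data.frame(from = linked, to = pw,
                           type = "pathway_membership", directed = FALSE))
  nodes <- data.frame(node = c(v, pw),
                      layer = c(rep("protein", k), "pathway"))
  list(nodes = nodes, edges = e, members = v)
}

# Dense RWR linear-solve oracle, independent of the package's sparse path:
# builds the column-stochastic matrix by hand from the directed view and
# solves (I - (1-r)(W + e_s d^T)) p = r e_s with base R.
rwr_dense_oracle <- function(net, seed_node, restart, mode) {
  g <- directionality_view(net, mode)
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  el <- igraph::as_edgelist(g)
  for (i in seq_len(nrow(el))) A[el[i, 2], el[i, 1]] <- 1
  outdeg <- colSums(A)
  W <- sweep(A, 2, pmax(outdeg, 1), "/")
  d <- as.numeric(outdeg == 0)
  e <- as.numeric(nodes == seed_node)
  M <- diag(n) - (1 - restart) * (W + outer(e, d))
  p <- solve(M, restart * e)
  setNames(p, nodes)
}

# Floyd-Warshall all-pairs oracle on a directionality view.
floyd_warshall_oracle <- function(net, mode) {
  g <- directionality_view(net, mode)
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  el <- igraph::as_edgelist(g)
  for (i in seq_len(nrow(el))) D[el[i, 1], el[i, 2]] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}
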