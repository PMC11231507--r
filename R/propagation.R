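#' Column-stochastic transition matrix of a directionality view
#'
#' Column j holds the uniform distribution over the out-neighbors of node j
#' in [directionality_view()]. Nodes with no out-arcs (possible under the
#' `downstream`/`upstream` views, or isolated nodes) are flagged dangling;
#' their columns are zero and the walk operator redistributes their mass to
#' the restart seed.
#'
#' @param net a [mlnet] object.
#' @param mode directionality mode.
#' @return list with `W` (sparse dgCMatrix), logical `dangling`, `nodes`
#'   and `mode`, of class `transition_matrix`.
#' @export
build_transition_matrix <- function(net, mode = "non_directed") {
  mode <- check_mode(mode)
  if (nrow(net$nodes) == 0) stop_np("network is empty")
  g <- directionality_view(net, mode)
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  el <- igraph::as_edgelist(g, names = FALSE)
  # W[i, j] = 1/outdeg(j) for arc j -> i
  outdeg <- tabulate(el[, 1], nbins = n)
  W <- Matrix::sparseMatrix(
    i = el[, 2], j = el[, 1],
    x = 1 / outdeg[el[, 1]],
    dims = c(n, n), dimnames = list(nodes, nodes)
  )
  structure(
    list(W = W, dangling = outdeg == 0, nodes = nodes, mode = mode),
    class = "transition_matrix"
  )
}

new_propagation_profile <- function(seed, method, mode, values, ...) {
  structure(list(seed = seed, method = method, mode = mode,
                 values = values, ...),
            class = "propagation_profile")
}

#' @export
print.propagation_profile <- function(x, ...) {
  cat(sprintf("propagation_profile: %s/%s from '%s' over %d nodes\n",
              x$method, x$mode, x$seed, length(x$values)))
  invisible(x)
}

rwr_solve <- function(tm, seed_idx, restart, lu = NULL) {
  n <- length(tm$nodes)
  A <- Matrix::Diagonal(n) - (1 - restart) * tm$W
  e <- numeric(n); e[seed_idx] <- 1
  q <- if (is.null(lu)) as.numeric(Matrix::solve(A, e)) else
    as.numeric(Matrix::solve(lu, e))
  dq <- sum(q[tm$dangling])
  cc <- restart / (1 - (1 - restart) * dq)
  p <- cc * q
  p
}

rwr_power <- function(tm, seed_idx, restart, tol, max_iter) {
  n <- length(tm$nodes)
  e <- numeric(n); e[seed_idx] <- 1
  p <- e
  for (it in seq_len(max_iter)) {
    m <- sum(p[tm$dangling])
    pn <- as.numeric((1 - restart) * (tm$W %*% p)) +
      ((1 - restart) * m + restart) * e
    res <- sum(abs(pn - p))
    p <- pn
    if (res < tol) return(list(p = p, iterations = it, residual = res))
  }
  stop_np("random walk did not converge in ", max_iter,
          " iterations (last L1 residual ", signif(res, 3), ")")
}

#' Random walk with restart from a seed node
#'
#' Iterates `p <- (1 - r) W p + r e_seed` on the chosen directionality
#' view, where `W` is the column-stochastic transition operator; mass at
#' dangling nodes is sent back to the seed, which keeps the operator
#' stochastic on directed views. The fixed point scores every node's
#' proximity to the seed.
#'
#' @param net a [mlnet] or a prebuilt `transition_matrix`.
#' @param seed seed node id.
#' @param restart restart probability in (0, 1]; default 0.7.
#' @param mode directionality mode (ignored when `net` is already a
#'   transition matrix).
#' @param tol L1 convergence tolerance for power iteration.
#' @param max_iter iteration cap for power iteration.
#' @param method `"solve"` (direct sparse linear solve, exact), `"power"`,
#'   or `"auto"` (solve for networks up to 2000 nodes, else power).
#' @return a `propagation_profile` whose `values` are nonnegative and sum
#'   to 1.
#' @export
random_walk_restart <- function(net, seed, restart = 0.7,
                                mode = "non_directed", tol = 1e-10,
                                max_iter = 1000,
                                method = c("auto", "solve", "power")) {
  method <- match.arg(method)
  tm <- if (inherits(net, "transition_matrix")) net else
    build_transition_matrix(net, mode)
  if (!(restart > 0 && restart <= 1)) {
    stop_np("restart probability must be in (0, 1]")
  }
  seed_idx <- match(seed, tm$nodes)
  if (is.na(seed_idx)) stop_np("seed node '", seed, "' not in network")
  n <- length(tm$nodes)
  if (method == "auto") method <- if (n <= 2000) "solve" else "power"
  if (restart == 1) {
    p <- numeric(n); p[seed_idx] <- 1
    res <- list(p = p, iterations = 0L, residual = 0)
  } else if (method == "solve") {
    res <- list(p = rwr_solve(tm, seed_idx, restart), iterations = NA,
                residual = 0)
  } else {
    res <- rwr_power(tm, seed_idx, restart, tol, max_iter)
  }
  new_propagation_profile(seed, "rwr", tm$mode,
                          setNames(res$p, tm$nodes),
                          restart = restart, iterations = res$iterations,
                          residual = res$residual)
}

#' Shortest-path hop profile from a seed node
#'
#' Unweighted hop distances from the seed to every node under the chosen
#' directionality view. Unreachable nodes carry a finite sentinel, the
#' largest finite distance in the profile plus one, so that downstream
#' set-averaging is never poisoned by infinities.
#'
#' @inheritParams random_walk_restart
#' @return a `propagation_profile` with integer-valued `values` and the
#'   sentinel recorded as `$sentinel`.
#' @export
shortest_path_profile <- function(net, seed, mode = "non_directed") {
  mode <- check_mode(mode)
  if (!seed %in% node_ids(net)) {
    stop_np("seed node '", seed, "' not in network")
  }
  g <- directionality_view(net, mode)
  d <- as.numeric(igraph::distances(g, v = seed, mode = "out"))
  names(d) <- igraph::V(g)$name
  finite <- is.finite(d)
  sentinel <- max(d[finite]) + 1
  d[!finite] <- sentinel
  new_propagation_profile(seed, "shortest_path", mode, d,
                          sentinel = sentinel)
}

#' Propagation feature matrix (one category = method x mode)
#'
#' One row per target, one column per network node; entries are the
#' target's RWR stationary probability at, or hop distance to, that node.
#' The six propagation categories arise from crossing the two methods with
#' the three directionality modes.
#'
#' @param net a [mlnet] object.
#' @param targets character vector of protein-layer node ids.
#' @param method `"rwr"` or `"shortest_path"`.
#' @param mode directionality mode.
#' @param restart restart probability for RWR.
#' @param tol convergence tolerance (power-iteration fallback).
#' @return a [feature_matrix] with category `"<rwr|sp>_<mode>"`.
#' @export
propagation_feature_matrix <- function(net, targets,
                                       method = c("rwr", "shortest_path"),
                                       mode = "non_directed", restart = 0.7,
                                       tol = 1e-10) {
  method <- match.arg(method)
  mode <- check_mode(mode)
  if (length(targets) == 0) stop_np("empty target list")
  lay <- node_layers(net)
  bad <- targets[is.na(lay[targets]) | lay[targets] != "protein"]
  if (length(bad) > 0) {
    stop_np("target(s) not in the protein layer: ",
            paste(head(bad, 5), collapse = ", "))
  }
  nodes <- node_ids(net)
  vals <- matrix(NA_real_, length(targets), length(nodes),
                 dimnames = list(targets, NULL))
  if (method == "rwr") {
    tm <- build_transition_matrix(net, mode)
    n <- length(tm$nodes)
    lu <- if (restart < 1 && n <= 2000) {
      Matrix::lu(Matrix::Diagonal(n) - (1 - restart) * tm$W)
    } else NULL
    for (i in seq_along(targets)) {
      si <- match(targets[i], tm$nodes)
      p <- if (restart == 1) {
        z <- numeric(n); z[si] <- 1; z
      } else if (!is.null(lu)) {
        rwr_solve(tm, si, restart, lu)
      } else {
        rwr_power(tm, si, restart, tol, 1000)$p
      }
      vals[i, ] <- p[match(nodes, tm$nodes)]
    }
    cat_name <- paste0("rwr_", mode)
  } else {
    g <- directionality_view(net, mode)
    d <- igraph::distances(g, v = targets, mode = "out")
    d <- d[, match(nodes, igraph::V(g)$name), drop = FALSE]
    for (i in seq_along(targets)) {
      row <- d[i, ]
      finite <- is.finite(row)
      sentinel <- max(row[finite]) + 1
      row[!finite] <- sentinel
      vals[i, ] <- row
    }
    cat_name <- paste0("sp_", mode)
  }
  ids <- paste0(cat_name, ":", nodes)
  colnames(vals) <- ids
  feature_matrix(vals, data.frame(
    feature_id = ids, category = cat_name, mode = mode,
    referenced_entity = nodes, stringsAsFactors = FALSE
  ))
}
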