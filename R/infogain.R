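# Entropy in bits of a class vector.
entropy_bits <- function(y) {
  p <- table(y)
  p <- p[p > 0] / length(y)
  -sum(p * log2(p))
}

# Fayyad-Irani MDL entropy-minimization discretization.
# Returns accepted cut points (possibly none). Recursively picks the cut
# minimizing weighted class entropy and accepts it only when the
# information gain exceeds the MDL criterion
#   gain > (log2(N-1) + delta) / N,
#   delta = log2(3^k - 2) - (k*E - k1*E1 - k2*E2).
# Candidate cuts are evaluated in one vectorized pass over cumulative
# class counts.
mdl_cuts <- function(x, y) {
  o <- order(x)
  x <- x[o]
  ycodes <- as.integer(factor(y))[o]
  ncls <- max(ycodes)
  # cumulative class counts: n x ncls
  cum <- vapply(seq_len(ncls), function(cl) cumsum(ycodes == cl),
                numeric(length(x)))
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  ent_rows <- function(counts, totals) {
    # entropy of each row of a counts matrix with row sums `totals`
    h <- numeric(length(totals))
    ok <- totals > 0
    for (cl in seq_len(ncol(counts))) {
      p <- counts[ok, cl] / totals[ok]
      h[ok] <- h[ok] - plogp(p)
    }
    h
  }
  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 2L) return(numeric(0))
    base <- if (lo > 1L) cum[lo - 1L, ] else numeric(ncls)
    tot <- cum[hi, ] - base
    k <- sum(tot > 0)
    if (k < 2L) return(numeric(0))
    cut_idx <- which(diff(x[lo:hi]) > 0)      # cut after position i
    if (length(cut_idx) == 0) return(numeric(0))
    left <- cum[lo + cut_idx - 1L, , drop = FALSE] -
      matrix(base, length(cut_idx), ncls, byrow = TRUE)
    right <- matrix(tot, length(cut_idx), ncls, byrow = TRUE) - left
    nl <- rowSums(left); nr <- rowSums(right)
    E <- ent_rows(matrix(tot, 1, ncls), sum(tot))[1]
    e1 <- ent_rows(left, nl)
    e2 <- ent_rows(right, nr)
    gain <- E - (nl / n) * e1 - (nr / n) * e2
    b <- which.max(gain)
    k1 <- sum(left[b, ] > 0); k2 <- sum(right[b, ] > 0)
    delta <- log2(3^k - 2) - (k * E - k1 * e1[b] - k2 * e2[b])
    if (gain[b] <= (log2(n - 1) + delta) / n) return(numeric(0))
    i <- cut_idx[b]
    cut <- (x[lo + i - 1L] + x[lo + i]) / 2
    c(recurse(lo, lo + i - 1L), cut, recurse(lo + i, hi))
  }
  recurse(1L, length(x))
}

#' Information gain of a feature about binary labels
#'
#' Entropy of the labels minus the conditional entropy given the feature,
#' in bits (log base 2). Continuous features are discretized by the
#' Fayyad-Irani MDL entropy-minimization criterion; when no split is
#' admissible the gain is 0.
#'
#' @param feature numeric vector.
#' @param labels factor/vector with exactly two classes present.
#' @return information gain in bits.
#' @export
information_gain <- function(feature, labels) {
  stopifnot(length(feature) == length(labels))
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2) {
    stop_np("labels must contain both classes")
  }
  if (length(unique(feature)) < 2) return(0)
  cuts <- mdl_cuts(feature, labels)
  if (length(cuts) == 0) return(0)
  bins <- findInterval(feature, sort(cuts))
  H <- entropy_bits(labels)
  cond <- 0
  for (b in unique(bins)) {
    sel <- bins == b
    cond <- cond + mean(sel) * entropy_bits(labels[sel])
  }
  H - cond
}

#' Bootstrap-averaged information gain per feature
#'
#' The information gain of every feature is averaged over `reps`
#' class-stratified bootstrap resamples (with replacement) of the rows.
#'
#' @param features a [feature_matrix] or numeric matrix (rows = samples).
#' @param labels binary labels, length `nrow`.
#' @param reps bootstrap repetitions (default 15).
#' @param seed integer seed; fixed seeds give identical scores.
#' @return named numeric vector of mean information gain (bits).
#' @export
bootstrap_information_gain <- function(features, labels, reps = 15,
                                       seed = 1L) {
  X <- if (inherits(features, "feature_matrix")) features$values else
    features
  stopifnot(is.matrix(X), nrow(X) == length(labels), reps >= 1)
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2) {
    stop_np("labels must contain both classes")
  }
  acc <- matrix(0, reps, ncol(X))
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, r))
    idx <- unlist(lapply(split(seq_along(labels), labels), function(ii) {
      sample(ii, length(ii), replace = TRUE)
    }), use.names = FALSE)
    yb <- labels[idx]
    for (j in seq_len(ncol(X))) {
      acc[r, j] <- information_gain(X[idx, j], yb)
    }
  }
  setNames(colMeans(acc), colnames(X))
}

#' Tukey upper fence of a score distribution
#'
#' `Q3 + 1.5 * (Q3 - Q1)` with linear-interpolation (type-7) quantiles;
#' used as the outlier threshold on a null information-gain distribution.
#'
#' @param values numeric vector of at least 4 values.
#' @export
tukey_upper_fence <- function(values) {
  if (length(values) < 4) stop_np("need at least 4 values for a fence")
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Degree-preserving rewiring of a multi-layer network
#'
#' Double-edge swaps within each (source layer, target layer, interaction
#' type, directedness) stratum, so node degrees and the layer-typing of
#' edges are preserved while all higher-order structure is destroyed.
#'
#' @param net a [mlnet].
#' @param seed integer seed.
#' @param attempts_per_edge swap attempts as a multiple of the stratum edge
#'   count (default 10).
#' @return a rewired [mlnet] over the same node set.
#' @export
rewire_network <- function(net, seed = 1L, attempts_per_edge = 10) {
  set.seed(derive_seed(seed, 7919L))
  lay <- node_layers(net)
  e <- net$edges
  lpair <- ifelse(e$directed,
                  paste(lay[e$from], lay[e$to], sep = ">"),
                  paste(pmin(lay[e$from], lay[e$to]),
                        pmax(lay[e$from], lay[e$to]), sep = "-"))
  strat <- paste(lpair, e$type, e$directed)
  pieces <- split(seq_len(nrow(e)), strat)
  for (ii in pieces) {
    m <- length(ii)
    if (m < 2) next
    sub <- e[ii, , drop = FALSE]
    directed <- sub$directed[1]
    key_of <- function(s) {
      if (directed) paste(s$from, s$to) else
        paste(pmin(s$from, s$to), pmax(s$from, s$to))
    }
    keys <- new.env(parent = emptyenv())
    for (k in key_of(sub)) assign(k, TRUE, envir = keys)
    n_attempts <- ceiling(attempts_per_edge * m)
    for (t in seq_len(n_attempts)) {
      ab <- sample.int(m, 2)
      i1 <- ab[1]; i2 <- ab[2]
      a <- sub$from[i1]; b <- sub$to[i1]
      c_ <- sub$from[i2]; d <- sub$to[i2]
      # proposed: a-d and c-b (keeps out/in degrees per stratum)
      if (a == d || c_ == b) next
      # layer consistency: for undirected strata with mixed endpoint
      # layers, only swap when endpoint layers line up
      if (!directed && lay[b] != lay[d]) next
      k1 <- if (directed) paste(a, d) else paste(min(a, d), max(a, d))
      k2 <- if (directed) paste(c_, b) else paste(min(c_, b), max(c_, b))
      if (k1 == k2 || exists(k1, envir = keys) || exists(k2, envir = keys)) {
        next
      }
      old1 <- key_of(sub[i1, ]); old2 <- key_of(sub[i2, ])
      rm(list = c(old1, old2), envir = keys)
      sub$to[i1] <- d; sub$to[i2] <- b
      assign(k1, TRUE, envir = keys); assign(k2, TRUE, envir = keys)
    }
    e[ii, ] <- sub
  }
  mlnet(net$nodes, e, net$attrs)
}

#' Null information-gain threshold from a rewired network
#'
#' Rewires the network degree-preservingly, re-runs one feature-extraction
#' recipe on the rewired network, computes the bootstrap information gain
#' of every null feature, and returns the Tukey upper fence of the null
#' distribution. Features scoring above this fence on the real network
#' carry more class information than random topology produces.
#'
#' @param net a [mlnet].
#' @param targets character vector of target node ids (rows).
#' @param labels binary labels aligned with `targets`.
#' @param recipe list naming one extraction category and its parameters:
#'   `list(category = "rwr_non_directed", restart = 0.7)` etc.; see
#'   [extract_category()].
#' @param seed integer seed.
#' @param reps bootstrap repetitions for the null information gain.
#' @return threshold in bits.
#' @export
null_ig_threshold <- function(net, targets, labels, recipe, seed = 1L,
                              reps = 15) {
  if (is.null(recipe$category)) stop_np("recipe must name a category")
  rnet <- rewire_network(net, seed = seed)
  fm <- extract_category(rnet, targets, recipe$category, recipe)
  if (ncol(fm$values) < 4) stop_np("null recipe produced too few features")
  ig <- bootstrap_information_gain(fm, labels, reps = reps,
                                   seed = derive_seed(seed, 2L))
  tukey_upper_fence(ig)
}
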