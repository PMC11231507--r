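# Stratified k-fold assignment; folds never leave a training side without
# both classes provided each class has >= 2 members.
make_stratified_folds <- function(y, k) {
  y <- factor(y)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Stratified bootstrap resample (with replacement) of row indices.
stratified_bootstrap <- function(y) {
  unlist(lapply(split(seq_along(y), factor(y)), function(ii) {
    sample(ii, length(ii), replace = TRUE)
  }), use.names = FALSE)
}

inv_freq_weights <- function(y) {
  y <- factor(y)
  tab <- table(y)
  w <- length(y) / (nlevels(y) * tab)
  setNames(as.numeric(w), names(tab))
}

#' Greedy correlation pruning
#'
#' Repeatedly finds the feature pair with the highest absolute Pearson
#' correlation above `cutoff` and drops the member with the larger mean
#' absolute correlation to all remaining features, until no pair exceeds
#' the cutoff. Zero-variance features are excluded from the correlation
#' computation and always kept, unless they duplicate another constant
#' feature exactly.
#'
#' @param features a [feature_matrix] or numeric matrix.
#' @param cutoff absolute-correlation cutoff (default 0.95).
#' @return character vector of kept feature names.
#' @export
correlation_filter <- function(features, cutoff = 0.95) {
  X <- if (inherits(features, "feature_matrix")) features$values else
    features
  stopifnot(is.matrix(X))
  if (ncol(X) < 2) return(colnames(X))
  sds <- apply(X, 2, sd)
  const <- !is.finite(sds) | sds == 0
  const_keep <- character(0)
  if (any(const)) {
    Xc <- X[, const, drop = FALSE]
    dup <- duplicated(t(Xc))
    const_keep <- colnames(Xc)[!dup]
  }
  vary <- colnames(X)[!const]
  if (length(vary) < 2) return(c(vary, const_keep))
  C <- abs(cor(X[, vary, drop = FALSE]))
  diag(C) <- 0
  keep <- rep(TRUE, length(vary))
  repeat {
    sub <- C[keep, keep, drop = FALSE]
    if (max(sub) <= cutoff) break
    pos <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- rownames(sub)[pos]
    means <- rowMeans(sub[pair, , drop = FALSE])
    drop_name <- pair[which.max(means)]
    keep[match(drop_name, vary)] <- FALSE
  }
  c(vary[keep], const_keep)
}

glmnet_xy <- function(X) {
  # glmnet needs >= 2 columns; pad with an inert zero column when needed
  if (ncol(X) >= 2) return(list(X = X, pad = FALSE))
  list(X = cbind(X, .pad. = 0), pad = TRUE)
}

#' Repeated adaptive-LASSO feature selection
#'
#' Each repetition draws a stratified bootstrap of the rows, fits a ridge
#' logistic model with the penalty chosen by stratified cross-validation,
#' uses 1/|ridge coefficient| as per-feature penalty factors in an
#' L1-penalized logistic fit (again tuned by stratified CV), and records
#' the features with nonzero coefficients. Features selected in at least
#' `keep_fraction` of repetitions form the selected set. Class imbalance is
#' absorbed by inverse-frequency observation weights.
#'
#' @param features a [feature_matrix] or numeric matrix.
#' @param labels binary labels.
#' @param reps repetitions (default 80).
#' @param folds cross-validation folds (default 10, reduced to the
#'   smallest class size when necessary).
#' @param keep_fraction selection-frequency threshold (default 0.8).
#' @param seed integer seed.
#' @return list with `frequencies` (named numeric) and `selected`
#'   (character vector).
#' @export
adaptive_lasso_selection <- function(features, labels, reps = 80,
                                     folds = 10, keep_fraction = 0.8,
                                     seed = 1L) {
  X <- if (inherits(features, "feature_matrix")) features$values else
    features
  stopifnot(is.matrix(X), nrow(X) == length(labels))
  y <- factor(labels)
  if (nlevels(droplevels(y)) < 2) stop_np("labels must contain both classes")
  counts <- matrix(0, 1, ncol(X), dimnames = list(NULL, colnames(X)))
  wmap <- inv_freq_weights(y)
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, r))
    idx <- stratified_bootstrap(y)
    Xb <- X[idx, , drop = FALSE]
    yb <- y[idx]
    k <- min(folds, min(table(yb)))
    if (k < 2) stop_np("a class is too small for cross-validation")
    padded <- glmnet_xy(Xb)
    w <- as.numeric(wmap[as.character(yb)])
    ridge <- tryCatch(
      suppressWarnings(
        glmnet::cv.glmnet(padded$X, yb, family = "binomial", alpha = 0,
                          weights = w,
                          foldid = make_stratified_folds(yb, k),
                          standardize = TRUE)),
      error = function(e) NULL)
    if (is.null(ridge)) next
    beta <- as.numeric(coef(ridge, s = "lambda.min"))[-1]
    pf <- 1 / pmax(abs(beta), .Machine$double.eps)
    lasso <- tryCatch(
      suppressWarnings(
        glmnet::cv.glmnet(padded$X, yb, family = "binomial", alpha = 1,
                          weights = w, penalty.factor = pf,
                          foldid = make_stratified_folds(yb, k),
                          standardize = TRUE)),
      error = function(e) NULL)
    if (is.null(lasso)) next
    # parsimonious CV choice: within one SE of the best penalty, the
    # sparser model (selection, not prediction, is the goal here)
    cf <- as.numeric(coef(lasso, s = "lambda.1se"))[-1]
    nz <- colnames(padded$X)[cf != 0]
    nz <- setdiff(nz, ".pad.")
    counts[1, intersect(nz, colnames(X))] <-
      counts[1, intersect(nz, colnames(X))] + 1
  }
  freq <- counts[1, ] / reps
  list(frequencies = freq,
       selected = names(freq)[freq >= keep_fraction & keep_fraction > 0 |
                                (keep_fraction == 0 & freq > 0)])
}

# Maximum-chord-distance ("kneedle") elbow on a sorted-descending curve,
# with both axes normalized to [0, 1]. Returns the number of leading points
# to keep: the points strictly before the elbow (the elbow itself is the
# first background point); on a degenerate/linear curve (chord distance 0
# everywhere) the selection is minimal (one point).
elbow_cut <- function(values) {
  n <- length(values)
  if (n <= 2) return(n)
  x <- (seq_len(n) - 1) / (n - 1)
  rng <- values[1] - values[n]
  if (rng <= 0) return(1L)
  y <- (values - values[n]) / rng
  x1 <- 0; y1 <- 1; x2 <- 1; y2 <- 0
  num <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1)
  den <- sqrt((y2 - y1)^2 + (x2 - x1)^2)
  dist <- num / den
  if (max(dist) < 1e-9) return(1L)  # linear decay: no elbow, keep minimal
  e <- which.max(dist)
  max(e - 1L, 1L)
}

#' Repeated random-forest importance selection with an elbow cut
#'
#' Each repetition draws a stratified bootstrap and stratified CV folds;
#' a random forest (inverse-frequency class weights) is fitted on each
#' training side and per-feature permutation importance (mean decrease in
#' accuracy) is recorded. Importances are averaged over all reps x folds
#' fits, sorted, and cut at the point of maximum perpendicular distance to
#' the chord joining the first and last points.
#'
#' @param features a [feature_matrix] or numeric matrix.
#' @param labels binary labels.
#' @param reps repetitions (default 100).
#' @param folds folds per repetition (default 10).
#' @param seed integer seed.
#' @param ntree trees per forest (default 500).
#' @return list with `importances` (named, sorted descending) and
#'   `selected`.
#' @export
rf_importance_selection <- function(features, labels, reps = 100,
                                    folds = 10, seed = 1L, ntree = 500) {
  X <- if (inherits(features, "feature_matrix")) features$values else
    features
  stopifnot(is.matrix(X), nrow(X) == length(labels))
  y <- factor(labels)
  if (nlevels(droplevels(y)) < 2) stop_np("labels must contain both classes")
  total <- setNames(numeric(ncol(X)), colnames(X))
  nfits <- 0L
  wmap <- inv_freq_weights(y)
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, r))
    idx <- stratified_bootstrap(y)
    Xb <- X[idx, , drop = FALSE]
    yb <- droplevels(y[idx])
    k <- min(folds, min(table(yb)))
    fold <- make_stratified_folds(yb, k)
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(yb[tr])) < 2) next
      fit <- randomForest::randomForest(
        x = Xb[tr, , drop = FALSE], y = yb[tr], ntree = ntree,
        importance = TRUE, classwt = wmap[levels(yb)])
      imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
      total[names(imp)] <- total[names(imp)] + imp
      nfits <- nfits + 1L
    }
  }
  mean_imp <- sort(total / max(nfits, 1L), decreasing = TRUE)
  # permutation importance <= 0 means "no better than noise": only the
  # positive part of the curve is a candidate for the elbow
  pos <- mean_imp[mean_imp > 0]
  if (length(pos) == 0) {
    warning("no positive random-forest importance; empty selection",
            call. = FALSE)
    return(list(importances = mean_imp, selected = character(0)))
  }
  cut <- elbow_cut(as.numeric(pos))
  list(importances = mean_imp, selected = names(pos)[seq_len(cut)])
}

#' Configuration for the selection cascade
#'
#' Defaults follow the source protocol: 15 information-gain bootstraps
#' with a Tukey-fence null threshold, 0.95 correlation cutoff, 80
#' adaptive-LASSO repetitions at a 0.8 selection-frequency threshold, and
#' 100 random-forest repetitions of (up to) 10-fold CV with an elbow cut.
#'
#' @param ig_reps,ig_threshold,null_perms information-gain stage: bootstrap
#'   count, explicit threshold in bits (e.g. from [null_ig_threshold()]),
#'   and the number of label permutations used to build a null fence when
#'   no explicit threshold is supplied.
#' @param cor_cutoff correlation-pruning cutoff.
#' @param lasso_reps,lasso_folds,lasso_keep adaptive-LASSO stage.
#' @param rf_reps,rf_folds,rf_ntree random-forest stage.
#' @export
selection_config <- function(ig_reps = 15, ig_threshold = NULL,
                             null_perms = 20, cor_cutoff = 0.95,
                             lasso_reps = 80, lasso_folds = 10,
                             lasso_keep = 0.8, rf_reps = 100,
                             rf_folds = 10, rf_ntree = 200) {
  list(ig_reps = ig_reps, ig_threshold = ig_threshold,
       null_perms = null_perms, cor_cutoff = cor_cutoff,
       lasso_reps = lasso_reps, lasso_folds = lasso_folds,
       lasso_keep = lasso_keep, rf_reps = rf_reps, rf_folds = rf_folds,
       rf_ntree = rf_ntree)
}

# Label-permutation null fence, used when no rewired-network threshold is
# available (e.g. feature matrices without an attached network). Two
# design points: (1) the null scores come from the same bootstrap-mean
# procedure as the observed scores — bootstrap resampling inflates plain
# information gain (duplicated rows make MDL splits admissible), so a
# plain-IG null would sit far below the observed noise distribution and
# filter nothing; (2) the fence is taken over the per-permutation *maxima*
# (a Westfall-Young-style familywise null), because here every observed
# feature is compared against the same exchangeable null and a pooled
# fence would admit its natural outlier rate times the feature count.
permutation_ig_fence <- function(X, y, perms, seed, ig_reps = 15) {
  maxima <- numeric(perms)
  for (p in seq_len(perms)) {
    set.seed(derive_seed(seed, 5000L + p))
    yp <- sample(y)
    maxima[p] <- max(bootstrap_information_gain(
      X, yp, reps = ig_reps, seed = derive_seed(seed, 6000L + p)))
  }
  tukey_upper_fence(maxima)
}

#' Per-category feature-selection cascade
#'
#' Stages: (1) bootstrap information gain, keeping features above a null
#' threshold (an explicit rewired-network fence, else a label-permutation
#' fence); (2) greedy correlation pruning; (3) repeated adaptive LASSO and
#' repeated random-forest importance on the survivors; final set = union
#' of the two methods' selections. Every intermediate set is recorded.
#'
#' @param features a [feature_matrix] or numeric matrix (one category).
#' @param labels binary labels.
#' @param config a [selection_config()] list.
#' @param seed integer seed; the whole cascade is reproducible under it.
#' @param category category label carried into the result.
#' @return an object of class `selection_result`.
#' @export
select_features <- function(features, labels, config = selection_config(),
                            seed = 1L, category = NA_character_) {
  X <- if (inherits(features, "feature_matrix")) features$values else
    features
  stopifnot(is.matrix(X))
  y <- factor(labels)
  ig <- bootstrap_information_gain(X, y, reps = config$ig_reps, seed = seed)
  thr <- config$ig_threshold %||%
    permutation_ig_fence(X, y, config$null_perms, seed,
                         ig_reps = config$ig_reps)
  kept_ig <- names(ig)[ig > thr]
  res <- list(category = category, ig_scores = ig, ig_threshold = thr,
              kept_after_ig = kept_ig, kept_after_correlation = character(0),
              lasso_frequencies = setNames(numeric(0), character(0)),
              lasso_selected = character(0),
              rf_importances = setNames(numeric(0), character(0)),
              rf_selected = character(0), final = character(0))
  class(res) <- "selection_result"
  if (length(kept_ig) == 0) return(res)
  kept_cor <- correlation_filter(X[, kept_ig, drop = FALSE],
                                 cutoff = config$cor_cutoff)
  res$kept_after_correlation <- kept_cor
  if (length(kept_cor) == 0) return(res)
  Xs <- X[, kept_cor, drop = FALSE]
  las <- adaptive_lasso_selection(Xs, y, reps = config$lasso_reps,
                                  folds = config$lasso_folds,
                                  keep_fraction = config$lasso_keep,
                                  seed = derive_seed(seed, 11L))
  rf <- rf_importance_selection(Xs, y, reps = config$rf_reps,
                                folds = config$rf_folds,
                                seed = derive_seed(seed, 13L),
                                ntree = config$rf_ntree)
  res$lasso_frequencies <- las$frequencies
  res$lasso_selected <- las$selected
  res$rf_importances <- rf$importances
  res$rf_selected <- rf$selected
  res$final <- union(las$selected, rf$selected)
  res
}

#' Serialize a selection result as JSON plus a per-feature score TSV
#'
#' @param result a `selection_result`.
#' @param json_path output JSON (stage survivor sets and threshold).
#' @param scores_path output TSV of per-feature scores (information gain,
#'   LASSO selection frequency, RF importance, final membership).
#' @export
write_selection_result <- function(result, json_path, scores_path) {
  stopifnot(inherits(result, "selection_result"))
  jsonlite::write_json(list(
    category = result$category, ig_threshold = result$ig_threshold,
    kept_after_ig = result$kept_after_ig,
    kept_after_correlation = result$kept_after_correlation,
    lasso_selected = result$lasso_selected,
    rf_selected = result$rf_selected, final = result$final
  ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  feats <- names(result$ig_scores)
  tab <- data.frame(
    feature_id = feats,
    information_gain = as.numeric(result$ig_scores),
    lasso_frequency = as.numeric(result$lasso_frequencies[feats]),
    rf_importance = as.numeric(result$rf_importances[feats]),
    final = feats %in% result$final
  )
  write.table(tab, scores_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(json_path)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "selection_result (%s): %d scored -> IG %d -> corr %d -> final %d\n",
    x$category, length(x$ig_scores), length(x$kept_after_ig),
    length(x$kept_after_correlation), length(x$final)))
  invisible(x)
}
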