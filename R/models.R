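#' Matthews correlation coefficient from confusion counts
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, the balanced
#' binary-classification score in [-1, 1]. Any zero factor in the
#' denominator yields 0, the no-information value (covers, e.g., a model
#' that always predicts the majority class).
#'
#' @param tp,tn,fp,fn nonnegative confusion counts, total > 0.
#' @export
mcc <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# MCC directly from truth/prediction vectors.
mcc_from_labels <- function(truth, pred, positive = "positive") {
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  mcc(tp, tn, fp, fn)
}

#' Stratified train/test split
#'
#' Allocates a fixed fraction of each class to the test side (rounded to
#' the nearest sample), so class proportions in train and test match the
#' overall proportion to within one sample.
#'
#' @param labels class labels.
#' @param test_fraction fraction held out (default 0.2).
#' @param seed integer seed; identical seeds give identical splits.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  y <- factor(labels)
  if (nlevels(droplevels(y)) < 2) stop_np("both classes must be present")
  if (any(table(y) < 2)) stop_np("every class needs at least 2 members")
  set.seed(derive_seed(seed, 17L))
  test <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_test <- round(length(idx) * test_fraction)
    n_test <- min(max(n_test, 1L), length(idx) - 1L)
    test <- c(test, sample(idx, n_test))
  }
  list(train = setdiff(seq_along(y), test), test = sort(test))
}

#' Classifier specification
#'
#' @param name one of `"random_forest"`, `"weighted_svm"`,
#'   `"naive_bayes"`, `"weighted_knn"`.
#' @param grid data.frame of hyperparameter combinations (one row per grid
#'   point); `NULL` uses a modest default grid. Ties during tuning resolve
#'   to the earliest grid row, so order grids from simplest to most
#'   complex.
#' @param ntree trees for random forest fits.
#' @export
model_spec <- function(name = c("random_forest", "weighted_svm",
                                "naive_bayes", "weighted_knn"),
                       grid = NULL, ntree = 500) {
  name <- match.arg(name)
  if (is.null(grid)) {
    grid <- switch(name,
      random_forest = data.frame(mtry_factor = c(0.5, 1, 2)),
      weighted_svm = expand.grid(cost = c(0.1, 1, 10),
                                 gamma_factor = c(0.5, 1, 2)),
      naive_bayes = data.frame(laplace = c(0, 1)),
      weighted_knn = expand.grid(k = c(3, 5, 7, 9, 11),
                                 class_weight = c("none", "sqrt",
                                                  "inverse"),
                                 stringsAsFactors = FALSE)
    )
  }
  if (nrow(grid) == 0) stop_np("hyperparameter grid is empty")
  structure(list(name = name, grid = grid, ntree = ntree),
            class = "model_spec")
}

# Distance-decay weighted k-nearest-neighbour classifier. Features are
# z-scored on the training statistics (so no column dominates the
# Euclidean metric); each of the k nearest training rows votes with
# weight classwt[class]/(d + eps). The class-weight rule is itself a
# tunable: "none" (pure distance weighting), "sqrt" (square root of the
# inverse class frequency) or "inverse" (full inverse frequency, under
# which one positive neighbour can outvote several negatives).
fit_weighted_knn <- function(X, y, k, class_weight = "none") {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  Xs <- scale(X, center = mu, scale = sdv)
  wmap <- switch(class_weight,
                 none = setNames(rep(1, nlevels(y)), levels(y)),
                 sqrt = sqrt(inv_freq_weights(y)),
                 inverse = inv_freq_weights(y),
                 stop_np("unknown class_weight rule: ", class_weight))
  list(X = Xs, y = y, k = min(k, nrow(X)), wmap = wmap, mu = mu,
       sdv = sdv)
}

predict_weighted_knn <- function(fit, newX) {
  eps <- 1e-8
  lv <- levels(fit$y)
  newXs <- scale(newX, center = fit$mu, scale = fit$sdv)
  out <- character(nrow(newXs))
  for (i in seq_len(nrow(newXs))) {
    d <- sqrt(colSums((t(fit$X) - newXs[i, ])^2))
    nn <- order(d)[seq_len(fit$k)]
    w <- as.numeric(fit$wmap[as.character(fit$y[nn])]) / (d[nn] + eps)
    score <- tapply(w, factor(fit$y[nn], levels = lv), sum, default = 0)
    out[i] <- lv[which.max(score)]
  }
  factor(out, levels = lv)
}

# Fit one model at one grid point; returns list(predict = function(newX)).
fit_model <- function(spec, params, X, y) {
  y <- droplevels(factor(y))
  switch(spec$name,
    random_forest = {
      mtry <- max(1L, min(ncol(X),
                          round(sqrt(ncol(X)) * (params$mtry_factor %||% 1))))
      nmin <- min(table(y))
      fit <- randomForest::randomForest(
        x = X, y = y, ntree = spec$ntree, mtry = mtry,
        strata = y, sampsize = rep(nmin, nlevels(y)))
      list(predict = function(newX) predict(fit, newX),
           features = colnames(X))
    },
    weighted_svm = {
      gamma <- (params$gamma_factor %||% 1) / max(ncol(X), 1)
      fit <- e1071::svm(x = X, y = y, cost = params$cost %||% 1,
                        gamma = gamma, kernel = "radial",
                        class.weights = inv_freq_weights(y))
      list(predict = function(newX) predict(fit, newX),
           features = colnames(X))
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(x = X, y = y,
                               laplace = params$laplace %||% 0)
      list(predict = function(newX)
        predict(fit, as.data.frame(newX)), features = colnames(X))
    },
    weighted_knn = {
      fit <- fit_weighted_knn(X, y, params$k %||% 5,
                              class_weight = params$class_weight %||%
                                "none")
      list(predict = function(newX) predict_weighted_knn(fit, newX),
           features = colnames(X))
    })
}

#' Tune a classifier by repeated stratified cross-validation and refit
#'
#' Every grid point is scored by the mean Matthews correlation coefficient
#' over `reps` repetitions of stratified `folds`-fold cross-validation;
#' the best point (ties resolve to the earliest grid row) is refit on all
#' rows.
#'
#' @param spec a [model_spec()].
#' @param X numeric matrix of features (rows = targets).
#' @param y binary labels.
#' @param folds CV folds (default 10, reduced to the smallest class size
#'   when necessary).
#' @param reps CV repetitions (default 10).
#' @param seed integer seed; all fold draws flow from it.
#' @return list with `model` (fitted on all rows), `best_params`,
#'   `cv_mean`, `cv_sd` and the per-grid-point `cv_table`.
#' @export
tune_and_train <- function(spec, X, y, folds = 10, reps = 10, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), is.matrix(X),
            nrow(X) == length(y))
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop_np("both classes must be present")
  k <- min(folds, min(table(y)))
  if (k < 2) stop_np("a class is too small for cross-validation")
  grid <- spec$grid
  scores <- matrix(NA_real_, nrow(grid), reps)
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, 31L + r))
    fold <- make_stratified_folds(y, k)
    for (gi in seq_len(nrow(grid))) {
      preds <- factor(rep(NA_character_, length(y)), levels = levels(y))
      for (f in seq_len(k)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2) next
        m <- fit_model(spec, as.list(grid[gi, , drop = FALSE]),
                       X[tr, , drop = FALSE], y[tr])
        preds[!tr] <- m$predict(X[!tr, , drop = FALSE])
      }
      ok <- !is.na(preds)
      scores[gi, r] <- mcc_from_labels(y[ok], preds[ok])
    }
  }
  cv_mean <- rowMeans(scores)
  cv_sd <- apply(scores, 1, sd)
  best <- which.max(cv_mean)  # which.max takes the first maximum
  model <- fit_model(spec, as.list(grid[best, , drop = FALSE]), X, y)
  list(model = model, spec = spec,
       best_params = as.list(grid[best, , drop = FALSE]),
       cv_mean = cv_mean[best], cv_sd = cv_sd[best],
       cv_table = data.frame(grid, cv_mean = cv_mean, cv_sd = cv_sd))
}

#' Evaluate a fitted model on held-out rows
#'
#' @param fit result of [tune_and_train()] (or its `model` element).
#' @param X held-out feature matrix (same feature set as training).
#' @param y held-out labels.
#' @return list with confusion counts (`tp`, `tn`, `fp`, `fn`) and `mcc`.
#' @export
evaluate_model <- function(fit, X, y) {
  model <- if (!is.null(fit$model)) fit$model else fit
  if (!identical(colnames(X), model$features)) {
    stop_np("feature set of the evaluation matrix does not match training")
  }
  y <- factor(y)
  pred <- model$predict(X)
  pos <- "positive"
  list(
    tp = sum(y == pos & pred == pos), tn = sum(y != pos & pred != pos),
    fp = sum(y != pos & pred == pos), fn = sum(y == pos & pred != pos),
    mcc = mcc_from_labels(y, pred), n = length(y)
  )
}
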