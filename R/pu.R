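#' Positive-vote counts from a repeated cross-validation ensemble
#'
#' Positive-unlabeled calling by vote: in each of `reps` repetitions,
#' stratified `folds`-fold cross-validation predicts every target exactly
#' once as a held-out fold member; a target's vote count is the number of
#' repetitions predicting it positive. Fold assignment is re-randomized
#' every repetition from the seed stream.
#'
#' @param features a [feature_matrix] or numeric matrix (all targets,
#'   training and test pooled).
#' @param labels binary labels (`positive` / anything else).
#' @param spec a [model_spec()]; the model is used at fixed,
#'   previously-tuned hyperparameters.
#' @param params list of hyperparameters for `spec` (e.g. from
#'   [tune_and_train()]`$best_params`).
#' @param reps repetitions (default 100).
#' @param folds folds (default 10).
#' @param seed integer seed.
#' @return named integer vector of votes in `[0, reps]`.
#' @export
ensemble_positive_counts <- function(features, labels, spec, params,
                                     reps = 100, folds = 10, seed = 1L) {
  X <- if (inherits(features, "feature_matrix")) features$values else
    features
  stopifnot(is.matrix(X), nrow(X) == length(labels))
  y <- droplevels(factor(labels))
  if (nlevels(y) < 2) stop_np("both classes must be present")
  k <- min(folds, min(table(y)))
  if (k < 2) stop_np("a class is too small for cross-validation")
  votes <- setNames(integer(nrow(X)), rownames(X))
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, 101L + r))
    fold <- make_stratified_folds(y, k)
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) next
      m <- fit_model(spec, params, X[tr, , drop = FALSE], y[tr])
      pred <- m$predict(X[!tr, , drop = FALSE])
      votes[!tr] <- votes[!tr] + as.integer(pred == "positive")
    }
  }
  votes
}

#' Call repositioning candidates from ensemble votes
#'
#' Unlabeled targets predicted positive at least `threshold` times are
#' called candidates; originally-positive targets are excluded (they are
#' knowns, not repositioning calls). The threshold is inclusive.
#'
#' @param votes named vote counts from [ensemble_positive_counts()].
#' @param labels binary labels aligned with `votes` (by name when both are
#'   named).
#' @param threshold minimum votes (default 50, for 100 repetitions).
#' @return character vector of called targets.
#' @export
call_candidates <- function(votes, labels, threshold = 50) {
  if (length(votes) == 0) return(character(0))
  if (!is.null(names(labels)) && !is.null(names(votes))) {
    labels <- labels[names(votes)]
  }
  stopifnot(length(labels) == length(votes))
  called <- names(votes)[votes >= threshold & labels != "positive"]
  called %||% character(0)
}

#' Cross-category consensus of called candidates
#'
#' @param called_sets list of per-category called sets (character
#'   vectors).
#' @param mode `"intersection"` (default: a candidate must be called by
#'   every contributing category, favouring reliable calls) or `"union"`.
#' @return character vector.
#' @export
consensus_candidates <- function(called_sets,
                                 mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  stopifnot(length(called_sets) >= 1)
  if (mode == "intersection") {
    sort(Reduce(intersect, called_sets))
  } else {
    sort(Reduce(union, called_sets))
  }
}

#' Write ensemble votes and calls as TSV
#' @param votes_by_category named list of vote vectors.
#' @param called_by_category named list of called sets.
#' @param threshold vote threshold used.
#' @param path output TSV path.
#' @export
write_votes <- function(votes_by_category, called_by_category, threshold,
                        path) {
  rows <- list()
  for (cat_name in names(votes_by_category)) {
    v <- votes_by_category[[cat_name]]
    rows[[cat_name]] <- data.frame(
      target = names(v), category = cat_name, votes = as.integer(v),
      called = names(v) %in% called_by_category[[cat_name]]
    )
  }
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
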