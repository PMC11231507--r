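#' Feature matrix with per-feature metadata
#'
#' A `feature_matrix` pairs a numeric targets-by-features matrix with a
#' metadata table recording, for each feature, its category (one of the 11
#' extraction categories), the directionality mode where relevant, and the
#' referenced entity (node, module or signature the feature measures a
#' relation to).
#'
#' @param values numeric matrix, rownames = target ids, colnames = feature
#'   ids.
#' @param meta data.frame with at least `feature_id`, `category`, `mode`,
#'   `referenced_entity`; row order must match `colnames(values)`.
#' @export
feature_matrix <- function(values, meta) {
  stopifnot(is.matrix(values), is.data.frame(meta))
  if (is.null(rownames(values)) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    stop_np("feature matrix needs row and column names")
  }
  need <- c("feature_id", "category", "mode", "referenced_entity")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) stop_np("meta lacks column(s): ",
                                paste(miss, collapse = ", "))
  if (ncol(values) == 0 && nrow(meta) > 0) {
    stop_np("meta feature_id must match matrix column names in order")
  }
  if (ncol(values) > 0 &&
      !identical(unname(as.character(meta$feature_id)),
                 unname(colnames(values)))) {
    stop_np("meta feature_id must match matrix column names in order")
  }
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d targets x %d features\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$meta$category)
  cat("  categories:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values

#' Column-bind feature matrices over the same targets
#' @param ... feature_matrix objects with identical row names.
#' @export
fm_cbind <- function(...) {
  fms <- list(...)
  if (length(fms) == 1 && is.list(fms[[1]]) &&
      !inherits(fms[[1]], "feature_matrix")) {
    fms <- fms[[1]]
  }
  stopifnot(length(fms) >= 1)
  rn <- rownames(fms[[1]]$values)
  for (fm in fms) stopifnot(identical(rownames(fm$values), rn))
  metas <- lapply(fms, function(fm) fm$meta)
  common <- Reduce(union, lapply(metas, names))
  metas <- lapply(metas, function(m) {
    for (col in setdiff(common, names(m))) m[[col]] <- NA
    m[, common, drop = FALSE]
  })
  feature_matrix(do.call(cbind, lapply(fms, function(fm) fm$values)),
                 do.call(rbind, metas))
}

#' Subset the columns of a feature matrix
#' @param fm a feature_matrix.
#' @param features character vector of feature ids to keep.
#' @export
fm_subset <- function(fm, features) {
  idx <- match(features, colnames(fm$values))
  if (anyNA(idx)) stop_np("unknown feature id(s)")
  feature_matrix(fm$values[, idx, drop = FALSE],
                 fm$meta[idx, , drop = FALSE])
}

#' Write / read a feature matrix as TSV plus a metadata sidecar
#' @param fm a feature_matrix.
#' @param path values TSV (targets as rows).
#' @param meta_path metadata TSV.
#' @export
write_feature_matrix <- function(fm, path, meta_path) {
  df <- data.frame(target = rownames(fm$values), fm$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(fm$meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, meta_path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$target
  meta <- read.delim(meta_path, stringsAsFactors = FALSE,
                     colClasses = "character")
  meta$feature_id <- as.character(meta$feature_id)
  feature_matrix(m, meta)
}
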