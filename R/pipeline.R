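#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end run with its default: restart
#' probability 0.7; all three directionality modes; clique size bounds 15
#' and 50; signature thresholds (mutation 5%, SV 1%, CNA 12%, |log2FC| > 2
#' with adjusted p < 0.05); the selection cascade (15 IG bootstraps, 0.95
#' correlation cutoff, 80 LASSO repetitions at a 0.8 frequency threshold,
#' 100 RF repetitions); a stratified 80/20 split; 10x10 CV tuning; a
#' 100-repetition ensemble with vote threshold 50; intersection consensus.
#'
#' @param edges,node_attrs,labels,signatures,gene_to_protein input paths;
#'   `signatures` is a named list of per-kind statistic TSVs (kinds
#'   `mutation`, `sv`, `cna`, `deg`).
#' @param restart RWR restart probability.
#' @param clique_bounds clique size bounds.
#' @param refine_min_size minimum refined-signature size.
#' @param selection a [selection_config()].
#' @param test_fraction held-out fraction.
#' @param cv_folds,cv_reps tuning cross-validation shape.
#' @param models character vector of [model_spec()] names to tune.
#' @param ensemble_model model used inside the PU ensemble.
#' @param ensemble_reps,vote_threshold ensemble shape.
#' @param ensemble_categories `"auto"` (the two categories with the best
#'   test MCC) or an explicit character vector.
#' @param consensus_mode `"intersection"` or `"union"`.
#' @param seed master seed; every stage derives its stream from it.
#' @export
run_config <- function(edges, labels, node_attrs = NULL,
                       signatures = list(), gene_to_protein = NULL,
                       restart = 0.7, clique_bounds = c(15, 50),
                       refine_min_size = 2,
                       selection = selection_config(),
                       test_fraction = 0.2, cv_folds = 10, cv_reps = 10,
                       models = "weighted_knn",
                       ensemble_model = "weighted_knn",
                       ensemble_reps = 100, vote_threshold = 50,
                       ensemble_categories = "auto",
                       consensus_mode = "intersection", seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as YAML
#' @param config a [run_config()] list.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- run_config(edges = cfg$edges, labels = cfg$labels)
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  base$clique_bounds <- as.numeric(base$clique_bounds)
  class(base) <- "run_config"
  base
}

#' Build the eight standard signatures from statistics tables
#'
#' Applies the default [signature_criteria()] per kind to the provided
#' tables (`mutation`, `sv`, `cna`, `deg`) and adds the three combined
#' sets (`combined_deg`, `combined_alteration`, `combined_all`); empty
#' signatures are dropped.
#'
#' @param tables named list of data.frames.
#' @return named list of [signature_set] objects.
#' @export
build_signatures_from_tables <- function(tables) {
  sigs <- list()
  for (kind in c("mutation", "sv", "cna")) {
    if (!is.null(tables[[kind]])) {
      sigs[[kind]] <- build_signature(tables[[kind]],
                                      signature_criteria(kind))
    }
  }
  if (!is.null(tables$deg)) {
    sigs$deg_up <- build_signature(tables$deg, signature_criteria("deg_up"))
    sigs$deg_down <- build_signature(tables$deg,
                                     signature_criteria("deg_down"))
  }
  alt <- sigs[intersect(c("mutation", "sv", "cna"), names(sigs))]
  degs <- sigs[intersect(c("deg_up", "deg_down"), names(sigs))]
  if (length(degs) > 1) {
    sigs$combined_deg <- combine_signatures(degs, "combined_deg")
  }
  if (length(alt) > 1) {
    sigs$combined_alteration <- combine_signatures(alt,
                                                   "combined_alteration")
  }
  if (length(alt) + length(degs) > 1) {
    sigs$combined_all <- combine_signatures(c(alt, degs), "combined_all")
  }
  Filter(function(s) s$usable, sigs)
}

#' Run the full target-prioritization pipeline
#'
#' Build -> extract (11 feature categories) -> per-category selection
#' cascade (with a rewired-network null information-gain threshold) ->
#' classifier tuning and held-out evaluation -> PU voting ensemble on the
#' best categories -> cross-category consensus. Every intermediate
#' artifact, a log, and a machine-readable summary (per-category
#' extracted/selected feature counts and test MCC, per-model MCCs, called
#' candidates) are written to `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created).
#' @return the summary list, invisibly; artifacts under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    cat(msg, "\n", file = log_path, append = TRUE)
    message(msg)
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  cfg_hash <- fnv1a_hash(readLines(cfg_path))
  stage <- "build"
  result <- tryCatch({
    logf("stage build: reading network and labels")
    net <- read_edge_list(config$edges, config$node_attrs)
    labels_tab <- read_target_labels(config$labels, net)
    g2p <- if (!is.null(config$gene_to_protein)) {
      read.delim(config$gene_to_protein, stringsAsFactors = FALSE)
    } else NULL
    sig_tabs <- lapply(config$signatures, read.delim,
                       stringsAsFactors = FALSE)
    sigs <- build_signatures_from_tables(sig_tabs)
    logf(sprintf("network: %d nodes, %d edges; %d signatures",
                 nrow(net$nodes), nrow(net$edges), length(sigs)))

    # druggability filter: only verified-druggable targets are learnable
    keep <- labels_tab$druggable
    targets <- labels_tab$protein[keep]
    y <- setNames(labels_tab$label[keep], targets)

    stage <- "extract"
    logf("stage extract: 11 feature categories")
    feats <- extract_all_features(
      net, targets, signatures = sigs, gene_to_protein = g2p,
      restart = config$restart, clique_bounds = config$clique_bounds,
      refine_min_size = config$refine_min_size, seed = config$seed)
    for (cat_name in names(feats)) {
      write_feature_matrix(
        feats[[cat_name]],
        file.path(out_dir, sprintf("features_%s.tsv", cat_name)),
        file.path(out_dir, sprintf("features_%s_meta.tsv", cat_name)))
    }

    stage <- "split"
    split <- stratified_split(y, config$test_fraction, seed = config$seed)
    train_ids <- targets[split$train]
    test_ids <- targets[split$test]

    stage <- "select"
    selections <- list()
    for (cat_name in names(feats)) {
      fm <- feats[[cat_name]]
      if (ncol(fm$values) == 0) {
        logf(sprintf("select %s: no features extracted", cat_name))
        next
      }
      thr <- tryCatch(
        null_ig_threshold(
          net, train_ids, y[train_ids],
          recipe = list(category = cat_name, restart = config$restart,
                        signatures = sigs, gene_to_protein = g2p,
                        min_size = config$clique_bounds[1],
                        max_size = config$clique_bounds[2],
                        seed = config$seed),
          seed = derive_seed(config$seed, 3L),
          reps = config$selection$ig_reps),
        error = function(e) NULL)
      sel_cfg <- config$selection
      sel_cfg$ig_threshold <- thr
      selections[[cat_name]] <- select_features(
        fm_values_rows(fm, train_ids), y[train_ids], config = sel_cfg,
        seed = derive_seed(config$seed, 5L), category = cat_name)
      write_selection_result(
        selections[[cat_name]],
        file.path(out_dir, sprintf("selection_%s.json", cat_name)),
        file.path(out_dir, sprintf("selection_%s_scores.tsv", cat_name)))
      logf(sprintf("select %s: %d -> %d features", cat_name,
                   ncol(fm$values), length(selections[[cat_name]]$final)))
    }

    stage <- "train"
    model_rows <- list()
    cat_mcc <- list()
    tuned <- list()
    for (cat_name in names(selections)) {
      final <- selections[[cat_name]]$final
      if (length(final) == 0) next
      fm <- feats[[cat_name]]
      Xtr <- fm_values_rows(fm, train_ids)[, final, drop = FALSE]
      Xte <- fm_values_rows(fm, test_ids)[, final, drop = FALSE]
      for (mname in config$models) {
        fit <- tune_and_train(model_spec(mname), Xtr, y[train_ids],
                              folds = config$cv_folds,
                              reps = config$cv_reps,
                              seed = derive_seed(config$seed, 23L))
        ev_tr <- evaluate_model(fit, Xtr, y[train_ids])
        ev_te <- evaluate_model(fit, Xte, y[test_ids])
        model_rows[[length(model_rows) + 1L]] <- data.frame(
          category = cat_name, model = mname, cv_mcc = fit$cv_mean,
          train_mcc = ev_tr$mcc, test_mcc = ev_te$mcc,
          difference = ev_tr$mcc - ev_te$mcc)
        if (mname == config$ensemble_model) {
          tuned[[cat_name]] <- fit
          cat_mcc[[cat_name]] <- ev_te$mcc
        }
        logf(sprintf("train %s/%s: cv=%.3f train=%.3f test=%.3f",
                     cat_name, mname, fit$cv_mean, ev_tr$mcc, ev_te$mcc))
      }
    }
    model_table <- do.call(rbind, model_rows)
    write.table(model_table, file.path(out_dir, "model_performance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "predict"
    ens_cats <- config$ensemble_categories
    if (identical(ens_cats, "auto")) {
      ranked <- names(sort(unlist(cat_mcc), decreasing = TRUE))
      ens_cats <- head(ranked, 2)
    }
    if (length(ens_cats) == 0) stop_np("no category with selected features")
    logf("ensemble categories: ", paste(ens_cats, collapse = ", "))
    votes_by_cat <- list()
    called_by_cat <- list()
    for (cat_name in ens_cats) {
      final <- selections[[cat_name]]$final
      Xall <- fm_values_rows(feats[[cat_name]], targets)[, final,
                                                         drop = FALSE]
      votes <- ensemble_positive_counts(
        Xall, y, spec = model_spec(config$ensemble_model),
        params = tuned[[cat_name]]$best_params,
        reps = config$ensemble_reps, folds = config$cv_folds,
        seed = derive_seed(config$seed, 41L))
      votes_by_cat[[cat_name]] <- votes
      called_by_cat[[cat_name]] <- call_candidates(
        votes, y, threshold = config$vote_threshold)
      logf(sprintf("ensemble %s: %d candidates called", cat_name,
                   length(called_by_cat[[cat_name]])))
    }
    consensus <- consensus_candidates(called_by_cat,
                                      mode = config$consensus_mode)
    write_votes(votes_by_cat, called_by_cat, config$vote_threshold,
                file.path(out_dir, "votes.tsv"))

    summary <- list(
      config_hash = cfg_hash,
      n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
      n_targets = length(targets),
      n_positive = sum(y == "positive"),
      categories = lapply(setNames(names(feats), names(feats)),
        function(cat_name) list(
          extracted = ncol(feats[[cat_name]]$values),
          selected = length(selections[[cat_name]]$final %||% character(0)),
          test_mcc = cat_mcc[[cat_name]] %||% NA)),
      models = if (!is.null(model_table)) {
        stats_by_model <- split(model_table, model_table$model)
        lapply(stats_by_model, function(d) list(
          mean_train_mcc = mean(d$train_mcc),
          mean_test_mcc = mean(d$test_mcc),
          mean_difference = mean(d$difference)))
      } else list(),
      ensemble = list(categories = ens_cats,
                      vote_threshold = config$vote_threshold,
                      reps = config$ensemble_reps,
                      called = called_by_cat,
                      consensus_mode = config$consensus_mode,
                      consensus = consensus)
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    logf("run complete")
    summary
  }, error = function(e) {
    cat(sprintf("FAILED at stage '%s': %s\n", stage, conditionMessage(e)),
        file = log_path, append = TRUE)
    stop_np("pipeline failed at stage '", stage, "': ",
            conditionMessage(e))
  })
  invisible(result)
}

# Row-subset of a feature matrix's values by target id.
fm_values_rows <- function(fm, ids) {
  fm$values[match(ids, rownames(fm$values)), , drop = FALSE]
}
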