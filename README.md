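# netprio

Target repositioning on heterogeneous multi-layer biological networks.

Therapeutic targets for a disease are proteins that drugs can engage to
produce benefit. `netprio` predicts *new* candidate targets among already
druggable proteins by learning what distinguishes the known targets'
position in a five-layer biological network (gene, protein, metabolite,
Gene Ontology, pathway; mixed directed/undirected edges), without
assuming candidates must sit next to any particular gene list.

The method, end to end:

1. **Extract** eleven categories of per-target features:
   * random walk with restart — fixed point of
     `p ← (1−r)·W·p + r·e_seed` — and shortest-path hop profiles, each
     under three directionality views (*downstream*, *upstream*,
     *non-directed*): 6 categories;
   * topological metrics (degree, closeness, harmonic, eigenvector,
     betweenness, eccentricity) plus inverse-log-weighted
     common-neighbor similarity `Σ_z 1/ln deg(z)`: 1 category;
   * Guney-style mean shortest-path distance to detected PPI communities
     and to filtered maximal cliques (15–50 proteins, all
     pathway-linked): 2 categories;
   * the same set distance to disease gene signatures (mutation ≥ 5%,
     SV ≥ 1%, CNA ≥ 12%, |log2FC| > 2 & padj < 0.05, their unions, and
     signature-by-module refinements) mapped to the gene and protein
     layers: 2 categories.
2. **Select** features per category: bootstrap information gain against
   a degree-preserving rewired-network null (Tukey-fence threshold),
   correlation pruning at |r| > 0.95, then the union of repeated
   adaptive-LASSO (80×, kept at ≥ 80% frequency) and repeated
   random-forest importance (100×, elbow cut) selections.
3. **Learn** on druggable targets only (80/20 stratified split):
   classifiers tuned by 10×10-fold stratified CV, scored by the Matthews
   correlation coefficient
   `(tp·tn − fp·fn)/√((tp+fp)(tp+fn)(tn+fp)(tn+fn))`.
4. **Call candidates** positive-unlabeled style: 100 repetitions of
   10-fold CV over the merged target pool; unlabeled targets predicted
   positive ≥ 50 times are candidates, and the final list is the
   consensus (intersection) of the two most predictive categories.

## Worked example

```r
library(netprio)

# A synthetic five-layer study: 600 nodes, 120 druggable targets,
# 12 known positives, 6 hidden positives planted 2 SD closer to the
# disease neighborhood than background.
fx <- generate_fixture(fixture_spec(seed = 1))
dir <- tempfile(); write_fixture(fx, dir)

net     <- read_edge_list(file.path(dir, "edges.tsv"),
                          file.path(dir, "node_attrs.tsv"))
labels  <- read_target_labels(file.path(dir, "labels.tsv"), net)
sigs    <- build_signatures_from_tables(fx$signature_tables)
targets <- labels$protein
y       <- setNames(labels$label, targets)

feats <- extract_all_features(net, targets, signatures = sigs,
                              gene_to_protein = fx$gene_to_protein)
print(names(feats))
#>  [1] "rwr_downstream"    "sp_downstream"     "rwr_upstream"
#>  [4] "sp_upstream"       "rwr_non_directed"  "sp_non_directed"
#>  [7] "topological"       "cluster"           "clique"
#> [10] "signature_gene"    "signature_protein"
length(feats)
#> [1] 11

# cascade + tuned weighted KNN + PU voting on one category
thr <- null_ig_threshold(net, targets, y,
                         list(category = "topological"), seed = 3)
sel <- select_features(feats$topological, y,
                       selection_config(ig_threshold = thr,
                                        lasso_reps = 40, rf_reps = 20,
                                        rf_ntree = 200),
                       seed = 4, category = "topological")
print(sel)
#> selection_result (topological): 606 scored -> IG 94 -> corr 91 -> final 15

X   <- feats$topological$values[, sel$final, drop = FALSE]
fit <- tune_and_train(model_spec("weighted_knn"), X, y, seed = 5)
fit$best_params
#> $k
#> [1] 11
#> $class_weight
#> [1] "sqrt"
v   <- ensemble_positive_counts(X, y, model_spec("weighted_knn"),
                                fit$best_params, reps = 100, seed = 9)
called <- call_candidates(v, y, threshold = 50)
print(called)
#> [1] "p005" "p029" "p035" "p081" "p091" "p145"
mean(called %in% fx$truth$hidden_positives)
#> [1] 0.6666667
```

The cascade keeps 15 of 606 topological features; the tuned KNN
(k = 11, square-root class weights, cross-validated MCC 0.79) votes six
unlabeled targets positive in at least half of 100 cross-validation
repetitions, and four of the six are the planted hidden positives —
unlabeled proteins whose network position mimics the known targets.
`run_pipeline(run_config(...), out_dir)` performs the
whole build → extract → select → train → predict sequence on files and
writes per-category feature counts, model MCCs, votes and the consensus
to a run directory; `inst/cli/netprio` wraps it for the shell.

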