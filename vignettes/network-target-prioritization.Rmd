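---
title: "Prioritizing therapeutic targets on a multi-layer biological network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing therapeutic targets on a multi-layer biological network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Target repositioning asks which proteins that are already druggable —
bound by an approved drug or a bioactive small molecule — could be
therapeutic targets for a disease they were never developed against.
netprio implements a network-based answer: known targets of the disease
are the positive class, every other druggable protein is unlabeled, and a
classifier learns what distinguishes the positives *from their position in
a heterogeneous biological network* rather than from any single curated
annotation.

The network has five typed layers (gene, protein, metabolite, Gene
Ontology term, molecular pathway) with mixed edge semantics: undirected
physical interactions (protein–protein, protein–metabolite), directed
regulation (transcription factor → gene, miRNA → gene), directed
gene → protein translation, and undirected membership edges to GO and
pathway nodes. Directionality matters: the *downstream* view follows
stored arrows (a target's influence on the network), *upstream* reverses
them (the network's influence on the target), and *non-directed* ignores
them. Undirected edges are traversable both ways in every view.

## Feature extraction: eleven categories

Each druggable target is described by features from four families, split
into eleven categories so their predictive value can be compared:

1. **Propagation (6 categories = 2 methods × 3 modes).** Random walk
   with restart (RWR) iterates $p \leftarrow (1-r)\,W p + r\,e_{seed}$,
   where $W$ is the column-stochastic transition operator of the chosen
   view and $r$ the restart probability; its fixed point scores every
   node's proximity to the target. Unweighted shortest-path hop counts
   are the second method. One feature per (target, node) pair.
2. **Topological metrics (1 category).** Degree, closeness, harmonic
   centrality, eigenvector centrality (max-normalized), betweenness and
   eccentricity, plus the inverse-log-weighted similarity
   $s(u,v) = \sum_{z \in N(u) \cap N(v)} 1/\ln \deg(z)$ between the
   target and every node.
3. **Module proximity (2 categories).** Communities from several
   algorithms (leading eigenvector; modularity optimization at
   resolutions 1, 1.5, 2; short random walks with 4 and 5 steps) on the
   protein layer, and maximal cliques of 15–50 proteins whose members all
   touch a pathway node. The feature is the Guney-style set distance: the
   mean shortest-path hop count from the target to each module member.
4. **Signature proximity (2 categories).** Disease gene signatures —
   mutated genes (frequency ≥ 5%), structural variants (≥ 1%),
   copy-number alterations (≥ 12%), and differentially expressed genes
   (|log2FC| > 2, adjusted p < 0.05, split by sign) — plus their three
   unions (combined DEG, combined alteration, combined all), mapped to
   the gene layer and (through a gene-to-protein table) to the protein
   layer. Signatures are additionally *refined* by intersecting their
   protein images with each detected module (refined protein sets are
   mapped back to genes for the gene-layer category), yielding small
   functional units of disease-associated nodes. Features are the same
   set distance as for modules.

## Feature selection cascade

Selection runs independently per category:

1. **Information gain vs a rewired null.** Per-feature information gain
   (bits) is averaged over 15 class-stratified bootstrap resamples.
   Continuous features are discretized by the Fayyad–Irani MDL
   entropy-minimization criterion; a feature with no admissible split
   scores 0. The keep threshold is the Tukey upper fence
   ($Q_3 + 1.5\,\mathrm{IQR}$, type-7 quantiles) of the null information
   gain obtained by re-extracting the same category on a
   degree-preservingly rewired network (double-edge swaps within each
   (layer pair, interaction type, directedness) stratum). When no network
   is attached to a feature matrix, the fence is computed from
   label-permutation nulls instead.
2. **Correlation pruning.** Greedy removal at |r| > 0.95: the member of
   the worst pair with the larger mean absolute correlation to the
   remaining features is dropped first.
3. **Adaptive LASSO, repeated.** 80 repetitions; each draws a stratified
   bootstrap, fits a CV-tuned ridge logistic model for the adaptive
   weights ($\gamma = 1$, ridge rather than OLS because $p$ can exceed
   $n$), then an L1 logistic model with penalty factors
   $1/|\hat\beta_{ridge}|$, with the penalty chosen by stratified 10-fold
   CV at the one-standard-error rule. Features with nonzero coefficients
   in ≥ 80% of repetitions are kept. The one-SE choice (rather than the
   CV minimum) is deliberate: the goal of this stage is support recovery,
   and the CV-minimum penalty admitted noise features at high frequency
   on label-free data.
4. **Random-forest importance, repeated.** Mean permutation importance
   (mean decrease in accuracy) over 100 repetitions of stratified
   10-fold fits, sorted; the kept set is the features strictly before the
   elbow, found as the point of maximum perpendicular distance to the
   chord of the axis-normalized importance curve. An exactly linear decay
   has no elbow and keeps the single top feature.
5. **Final set = union** of the LASSO and random-forest selections.

## Learning and positive-unlabeled calling

Targets are filtered to druggable ones, split 80/20 with stratification,
and classifiers (random forest with balanced per-class sampling, RBF SVM
with inverse-frequency class weights, naive Bayes, weighted KNN) are
tuned by 10 repetitions of stratified 10-fold CV scored with the Matthews
correlation coefficient, the balanced score for heavily imbalanced
classes; a zero denominator is defined as MCC 0, the no-information
value.

The weighted KNN z-scores features on training statistics and lets each
of the $k$ nearest neighbors vote with weight $w_{class}/(d+\epsilon)$.
The class-weight rule is a tuned hyperparameter with three levels — none,
square-root inverse frequency, inverse frequency — alongside
$k \in \{3,5,7,9,11\}$. Full inverse-frequency weighting is kept in the
grid but is rarely chosen: at a 9:1 imbalance it lets a single positive
neighbor outvote the rest and floods the positive calls, which is exactly
what cross-validated MCC penalizes.

For repositioning calls, train and test sets are merged and the tuned
model is run through 100 repetitions of stratified 10-fold
cross-validation; every target is predicted exactly once per repetition
as a held-out fold member. Unlabeled targets predicted positive in at
least 50 repetitions are called candidates (known positives are excluded
— they are knowns, not calls). The final consensus intersects the called
sets of the two most predictive categories (ranked by MCC); intersection
is the default because agreement across feature families is what makes a
small candidate list reliable, and a union mode is available.

## The synthetic fixture and what it does (not) show

`generate_fixture()` builds a five-layer network (~600 nodes by default:
200 genes, 200 proteins with a preferential-attachment PPI backbone, 60
metabolites, 80 GO terms, 60 pathways), the five signature statistic
tables, and a PU label table over 120 druggable targets (12 positives, 6
hidden positives planted among the unlabeled). All druggable targets get
the same number of uniformly placed extra PPI edges, so degree itself
carries no label signal. Positives and hidden positives are then wired
into the disease neighborhood — the proteins of the signature genes —
until each one's mean hop distance to that neighborhood lies
`effect_size` background standard deviations below the background mean.
The separation is therefore calibrated directly in SD units;
`effect_size = 0` plants nothing and the groups are exchangeable
(verified by a null calibration over 20 seeds), while the default
`effect_size = 2` separates the planted targets' proximity essentially
always (power calibration, 20 seeds; separation is monotone in the
effect size).

The fixture emulates degree heterogeneity, mixed directionality, typed
layers and a proximity-based disease signal. It does **not** emulate real
interactome biology: no literature bias, no correlated signatures, no
hub-target confounding, and its clique layer is empty at default density
(maximal cliques of 15+ require far denser graphs, so clique filtering is
exercised on purpose-built fixtures instead). Passing tests therefore
demonstrate that the machinery recovers a planted, proximity-shaped
signal at a stated strength — not that any particular disease's targets
are predictable.

## Numerical choices and degenerate inputs

* RWR defaults: restart 0.7 (the walk-with-restart literature's usual
  range; no stated value governs it), L1 tolerance 1e-10, max 1000
  iterations; networks ≤ 2000 nodes use a sparse direct solve (one LU
  factorization shared across targets via a rank-one dangling
  correction), larger ones power iteration. A walker at a node with no
  out-arcs jumps back to the seed, keeping the operator stochastic.
* Unreachable shortest-path distances take a finite per-profile sentinel
  (largest finite distance + 1) so set averages are never poisoned by
  infinities.
* Harmonic centrality uses the standard $\sum_{v \ne u} 1/d(u,v)$ (with
  $1/\infty = 0$); a literal "inverse of the mean distance" would
  duplicate closeness up to scale and add no information.
* Similarity rows are computed against all nodes by default
  (`restrict_to = "protein"` narrows them).
* Duplicate modules from different algorithms are deduplicated (first
  provenance wins); singleton communities are dropped; refined signatures
  need ≥ 2 members, since a singleton would duplicate a single-node
  proximity feature.
* Mixed-directedness duplicate edges: two directed arcs A→B and B→A of
  the same interaction type are kept as two arcs — merging them into one
  undirected edge would erase regulatory asymmetry. Self-loops are
  dropped with a warning on load. The edge-list reader tolerates
  undirected edges listed once or twice (A–B and B–A collapse).
* Constant features are excluded from correlation computations and kept
  unless exactly duplicated; glmnet's two-column minimum is satisfied by
  an inert zero pad when a single feature survives.
* All randomness flows from one master seed through per-stage derived
  streams, so every result — including the ARPACK-based eigenvector
  centrality, which runs under a fixed internal RNG state — is
  reproducible bit-for-bit.

## Problem sizes used by the test and acceptance runs

The default fixture (600 nodes, 120 targets) runs the full pipeline in
minutes. The cascade-recovery benchmarks use the per-operation defaults
(80 LASSO repetitions, 100 random-forest repetitions of 10-fold CV) on
a 300 × 205 planted matrix and a 200 × 60 all-noise matrix. The PU
ensemble benchmark extracts all categories from the default fixture and,
for the four categories that carry the planted proximity signal
(non-directed RWR, topological, and the two signature categories), runs a
fixture-scale cascade (40 LASSO repetitions, 20 random-forest repetitions
at 200 trees) before tuning and 100-repetition voting; these are the
package's chosen benchmark sizes for a ~600-node network and are
configuration, not method, parameters.

## Known limitations

* The walk treats the merged heterogeneous network with uniform neighbor
  transitions; no per-layer jump probabilities or supra-adjacency
  multiplex formulation (out of scope by design).
* Edge weights are ignored everywhere; inputs are assumed pre-filtered
  to high-confidence interactions.
* Cluster detection runs per parameterization with fixed seeds; no
  consensus clustering across algorithms.
* The PU strategy calls few candidates by construction; it trades recall
  for precision, and a category whose classifier over-calls is penalized
  by MCC during tuning rather than repaired.
* External clustering tools can be plugged into the registry
  (`register_cluster_algorithm()`), but none ship with the package.
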