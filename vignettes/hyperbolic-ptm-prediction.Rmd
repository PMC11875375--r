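---
title: "Predicting directed PTM interactions from hyperbolic network geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting directed PTM interactions from hyperbolic network geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Phosphorylation and dephosphorylation are directed events: a kinase or
phosphatase (the *effector*) modifies a *target*. Protein-interaction
databases, however, store undirected edges, and only a small curated set of
interactions carries enzymatic-reaction annotations from which a direction
can be read off. `hyperptm` implements a pipeline that learns to recognise
directed post-translational-modification interactions (PTM-PPIs) from the
*topology* of the interaction network alone, using the geometry the network
acquires when embedded in the two-dimensional hyperbolic plane.

The pipeline is: confidence-filter a scored edge list and keep the largest
connected component; embed it in the hyperbolic disc; cluster proteins along
the angular dimension; assemble 14 geometric and centrality features per
directed pair; train a random forest on curated directed pairs with
under-sampled repeated cross-validation; and finally score every edge of the
network in both directions.

## The popularity-similarity model and hyperbolic distance

Scale-free, clustered networks arise naturally when nodes occupy a
hyperbolic disc and connect preferentially over short hyperbolic distances.
In the popularity-similarity (PS) growth model, node \(i\) arrives at radius
\(r_i = 2\ln i\) with a uniform angle \(\theta_i\); as the network grows,
earlier nodes drift outward (popularity fading)
\[
  r_j(i) \;=\; \beta\, 2\ln j + (1-\beta)\, 2\ln i,
  \qquad \beta = \frac{1}{\gamma - 1},
\]
where \(\gamma > 2\) is the degree exponent the grown network attains. A
newcomer links to the \(m\) hyperbolically closest nodes (temperature
\(T = 0\)) or samples partners with the Fermi-Dirac probability
\[
  p(d) \;=\; \frac{1}{1 + e^{(d - R_i)/(2T)}},
\]
with \(R_i\) calibrated so the expected number of links is \(m\) (the
standard PS-model disc radius; `ps_disc_radius()` in the source). The
distance between points \((r_1,\theta_1)\) and \((r_2,\theta_2)\) is the
hyperbolic law of cosines at curvature \(-1\):
\[
  \cosh d \;=\; \cosh r_1 \cosh r_2 - \sinh r_1 \sinh r_2 \cos\Delta\theta .
\]
`hyperbolic_distance()` clamps the `acosh` argument at 1 and returns
\(|r_1-r_2|\) outright when \(\Delta\theta < 10^{-12}\), where the general
formula suffers catastrophic cancellation.

The radial coordinate encodes *popularity* (hubs sit near the centre, and
radius correlates with seniority); the angular coordinate encodes
*similarity* — functionally related proteins occupy nearby angles.

## Inferring coordinates: LaBNE + HyperMap refinement

Given only the observed network, `embed_network()` infers coordinates in
two steps.

**Radii** follow directly from degree rank: the \(k\)-th node by decreasing
degree (ties broken by node ID for determinism) receives
\(r_k = 2\beta\ln k + 2(1-\beta)\ln N\).

**Angles** are initialised by Laplacian eigenmaps (`labne_angles()`): solve
\(L v = \lambda D v\) for the graph Laplacian \(L = D - A\) and read the
angle of each node from the eigenvectors of the 2nd and 3rd smallest
eigenvalues, \(\theta = \operatorname{atan2}(v_3, v_2)\). The eigen-gauge
(rotation/reflection/sign) is arbitrary, so *every* accuracy statement about
angles in this package is made through `circular_correlation()`, the
absolute Fisher-Lee circular correlation, which is invariant to rotation
and reflection. A dense symmetric solver is used up to 2000 nodes; larger
networks switch to igraph's ARPACK interface on the normalised adjacency.

**Refinement** (`hypermap_refine()`) then sweeps the nodes in
decreasing-degree order and moves each node's angle to the best of
`n_candidates` equally spaced proposals within `window` of its current
value, scoring the Fermi-Dirac log-likelihood of all its edges and
non-edges (with \(R = \max_k r_k\)). The incumbent angle is always among
the candidates, and pairs not involving the moved node are untouched, so
the total likelihood never decreases — a property the tests assert
directly. Defaults are `window = pi/6`, `n_candidates = 60`, one pass; the
non-edge sum is exact up to 2000 nodes and subsampled (2000 seeded
non-neighbours per node) beyond, which keeps a full-interactome refinement
linear in the node count per pass. The likelihood is degenerate at
\(T = 0\), so refinement requires \(T \ge 0.01\).

For the human interactome the published embedding parameters are
\(\gamma = 2.97\), \(T = 0.83\), \(w = 2\pi\); they are the package
defaults (`ptm_config()`). The exact refinement schedule behind the
published coordinate table is not recoverable, so when published
coordinates are available they should be used as-is (`ptm_reference_path()`)
rather than re-derived.

## Angular-gap clustering

Sorting all angles and cutting the circle wherever the gap between
consecutive angles exceeds a threshold \(g\) partitions the proteins into
angularly contiguous sectors (`cluster_by_gap()`). The published analysis
uses \(g = 0.0077\) with a minimum sector size of 3 (yielding 24 sectors on
the published coordinates), and subclusters the first sector at
\(g = 0.0042\) with minimum size 5. Two choices needed fixing that the
published description leaves open:

* **Strictness.** A gap exactly equal to \(g\) does *not* cut (strict
  `>`); only larger gaps do.
* **Subcluster gap.** The methods text gives 0.0042 while a figure caption
  gives 0.042; the methods value is the default and either can be passed
  explicitly.

If the requested \(g\) produces an undersized sector, `cluster_by_gap()`
fails rather than silently merging; `select_gap_size()` scans the observed
gap values and returns the smallest threshold whose clustering satisfies
the size constraint (the smallest valid \(g\) maximises the number of
sectors). Duplicate angles sort stably by node ID, and clustering is
invariant to rotating all angles, which the tests check explicitly.

## The 14 features and the classifier

For a directed pair (effector candidate, target candidate),
`assemble_features()` emits, in fixed order: \(r\), \(\theta\), degree,
betweenness, closeness and eigenvector centrality of the effector; the same
six for the target; then the hyperbolic distance between the two and
\(|r_\mathrm{eff} - r_\mathrm{tgt}|\). The edge features are orientation
invariant; swapping a pair swaps the node blocks only.

Centrality conventions are the package's own (the published analysis does
not state them): raw degree, betweenness normalised by
\((n-1)(n-2)/2\), closeness \((n-1)/\sum_u d(v,u)\), eigenvector
centrality scaled to maximum 1. A random forest is invariant to strictly
monotone per-feature transforms, so these conventions affect nothing but
readability; they are fixed for determinism and validated against
brute-force oracles in the tests.

**Training data.** Directed positives come from enzymatic-reaction
annotations (PSI-MI codes MI:0217 phosphorylation, MI:0203
dephosphorylation) oriented by effector catalogs: a pair with exactly one
effector is oriented effector \(\to\) target; a kinase-phosphatase pair
yields both orientations; pairs with no effector or two effectors of the
same type are discarded (direction undecidable). A protein listed as both
kinase and phosphatase is ambiguous, and pairs whose orientation would
hinge on it are discarded — a conservative choice the published rules do
not address. Negatives are all remaining directed orientations of network
edges; by default the *reverse* orientation of a positive is also excluded
from the pool, because its true label is unknown (the classifier
demonstrably struggles with pure direction), with a flag restoring the
literal "everything else" reading.

**Protocol.** `split_train_test()` makes a stratified 70/30 split.
`train_rf()` runs 5-fold cross-validation repeated 10 times inside the
training partition; within each fold's training portion the majority class
is randomly down-sampled to the minority size (the under-sampling record is
kept and asserted balanced in the tests); the final forest (500 trees) is
refit on the under-sampled training partition. `mtry = 14` — all features
tried at every split — is the published optimum and the default, even
though it disables the forest's feature subsampling and reduces it to an
ensemble of bootstrapped CART trees; it is honoured as published and can be
lowered. A pair's score is the fraction of trees voting positive.

**Evaluation.** `evaluate_model()` reports the confusion matrix at 0.5,
accuracy, sensitivity, specificity, the ROC step curve with trapezoid AUC
(equal, with ties counted one half, to the Mann-Whitney concordance — the
tests compare against an independent pairwise-concordance oracle at
\(10^{-9}\)), and the precision-recall curve. `feature_importance()` uses
permutation importance (mean accuracy drop over 20 seeded permutations per
feature): it is model-agnostic and reproducible, whereas the impurity-based
alternative depends on implementation details of the tree library.
`ablation_study()` retrains on nested feature subsets; since "removing
features one by one" cannot produce five models from fourteen features, the
default series masks two features per step (14, 12, 10, 8, 6), removing the
most important first.

**Proteome-wide scoring.** `score_all_edges()` scores every edge in both
orientations — exactly \(2|E|\) records, streamed in chunks — and
`threshold_counts()` summarises the score distribution at 0.5 and 0.9. The
two orientations of an edge are scored independently and need not sum
to one; both can be high, which matches the observed behaviour of such
classifiers on, e.g., mutually regulating kinase pairs.

## What the synthetic generator emulates — and what it does not

`generate_ps_network()` + `plant_effectors()` + `plant_positive_pairs()`
produce a complete synthetic study: a PS network with ground-truth
coordinates, effector sets concentrated in angular sectors (mimicking the
empirical crowding of kinases in a narrow region of the similarity
dimension), and directed positives sampled from effector-incident edges
with weight \(e^{-d/\lambda}\), so positives sit at shorter hyperbolic
distances than background — the direction of the empirical signal.

Default study conditions used throughout the tests and the acceptance
script: \(N = 1000\), \(m = 4\), \(\gamma = 2.5\), \(T = 0.3\), 5% kinases
(sector centre 1.8, half-width 0.3), 2% phosphatases (centre 4.5), 150
positives, \(\lambda = 2\), and balanced negatives. These are chosen as a
realistic small-network regime: \(\gamma\) and \(T\) in the middle of the
range reported for real interactomes (strong but not extreme clustering),
a network two orders of magnitude smaller than the human interactome so the
full protocol runs in seconds, and an effector fraction similar to the
kinome's share of the proteome. The embedding-recovery checks use
\(N = 500\), \(m = 4\), \(T = 0.1\), where Laplacian eigenmaps are known to
work well; the degree-exponent check uses \(N = 10{,}000\) with a
maximum-likelihood tail fit (\(x_{\min} = 10\)).

Passing on this synthetic world shows the machinery is correct — the
generator produces the geometry the features assume, and the classifier
recovers planted signal. It does **not** show that real interactomes carry
as clean a signal: real curated positives are biased toward well-studied
kinases, effector catalogs are incomplete, the interactome is itself a
noisy sample, and the real angular organisation is shaped by function, not
planted by construction. Reproducing the published human-interactome
numbers therefore requires the published tables (see
`?ptm_reference_path`).

## Numerical choices

* Hyperbolic distance: `acosh` argument clamped at 1; collinear pairs
  short-circuit to \(|r_1-r_2|\).
* Eigen-solver: dense symmetric up to 2000 nodes, ARPACK beyond; all
  angle comparisons gauge-invariant.
* Degree ties in radial ranking and duplicate angles in clustering break
  by node ID; equal-size components break toward the lexicographically
  smallest node set; edges store endpoints sorted.
* Confidence filtering is inclusive (\(\ge\)).
* At \(T > 0\) the generator keeps exactly \(m\) links per arrival by
  Bernoulli sweeps capped at 50, then topping up with the closest
  remaining candidates; the realised edge count is therefore the closed
  form \(\sum_i \min(i-1, m)\) at every temperature.
* One seed drives each stochastic stage (split, folds, under-sampling,
  trees, permutations) through R's generator in a fixed call order;
  identical inputs and seed give byte-identical outputs.

## Limitations

* The embedding likelihood refinement is a single greedy pass by default;
  it improves the initialisation monotonically but is not a global
  optimiser, and published coordinates cannot be reproduced bit-for-bit.
* `mtry = 14` removes the forest's main decorrelation mechanism; the
  ensemble still averages over bootstrap resamples only.
* Cluster labels are purely geometric; merging neighbouring sectors by
  biological function requires annotation databases and is out of scope.
* Identifier mapping between naming systems is out of scope; inputs must
  share one identifier namespace.
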