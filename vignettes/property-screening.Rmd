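---
title: "Property-based screening for zinc-binding fragments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Property-based screening for zinc-binding fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`znscreen` packages a classification-driven workflow for characterizing
inhibitors of zinc-dependent metalloenzymes and screening fragment
libraries for candidate zinc-binding fragments (ZnBFs). This vignette is
the methods account: the model and its assumptions, the parameters that
matter, what the synthetic-data generator does and does not emulate, the
numerical choices, and the known limitations.

## The statistical model

The workflow treats activity as a two-class problem rather than a
regression: ligands of many different zinc enzymes cannot share one
quantitative structure–activity model, but they can share a *property
profile* that separates strong binders from weak ones. The activity scale
is `lg(Ki)` with Ki in nM. Classes are deliberately separated by a buffer
band:

* high activity: `lg(Ki) < 2` (Ki below 100 nM),
* low activity: `lg(Ki) > 3` (Ki above 1 µM),
* the band `[2, 3]` is excluded from modeling entirely.

The buffer absorbs inter-assay noise: a ligand measured at 150 nM in one
complex and 800 nM in another should not flip classes. The same reasoning
drives record merging — multiple Ki entries for one ligand are averaged on
the log scale when their spread is at most one log unit and the ligand is
discarded otherwise, because a >10-fold disagreement means the
measurements are not describing the same binding event.

Redundancy pruning (MACCS Tanimoto > 0.75, within each class) prevents
congeneric series from dominating the classes; without it, cross-validation
folds contain near-copies of training molecules and accuracy is
overestimated. The threshold is strict: a pair at exactly 0.75 is kept.

## Classifiers and selectors

Eight interpretable learners are implemented under one contract
(`fit_classifier()` / `predict()`): Gaussian naive Bayes, k-nearest
neighbours on min–max standardized features (IBK), a C4.5-style
gain-ratio decision tree with pessimistic pruning (J48), their
attribute-selected variants (CFS runs inside the model on the training
fold), and the ZeroR/OneR rule baselines that calibrate what "better than
nothing" means. The tuned hyperparameters are the IBK neighbour count `k`
and the J48 minimum leaf size `min_obj`; everything else is fixed at the
conventional defaults (OneR bucket size 6, pruning confidence 0.25).

Descriptor selection offers the four standard regimes. CFS maximizes
`merit(S) = k·r̄_cf / sqrt(k + k(k−1)·r̄_ff)` over subsets `S` of size `k`,
with `r̄_cf` the mean absolute feature–class (point-biserial) correlation
and `r̄_ff` the mean absolute feature–feature correlation, under forward
best-first search with backtracking. One algebraic consequence worth
knowing: an exact duplicate of a selected feature leaves the merit
unchanged (`2r/√(2+2) = r`), and a *partially* correlated second
informative feature can raise it — the formula rewards coverage, not
minimality, and the search's strict-improvement rule is what keeps the
subsets small. The gain-ratio ranker discretizes each feature by the
supervised binary split maximizing information gain and keeps features
with positive gain ratio (a permissive cut — on noisy data the best split
of almost any feature has nominally positive gain, so `top_k` is the
practical control). The wrapper scores subsets by seeded cross-validated
naive Bayes accuracy with fold assignments drawn once per search, so that
subset comparisons are paired and the search is deterministic.

## Validation machinery

Model quality is reported as repeated stratified cross-validation
(10 folds × 10 seeds by default), replicated random 7:3 splits of the
modeling set with a fixed external test set, ROC/AUC by the rank statistic
(ties get half credit, which equals the trapezoidal area), and the three
screening formulas: accuracy, `Active_detected% = TP/(TP+FP)` (screen
precision) and `HR = TP/A` (recall against the whole database). The best
replicate is chosen by external accuracy with external AUC and then
replicate index as tie-breaks; its false positives are listed with
structures, since systematically misclassified chemotypes (e.g.
sulfonamides in the low-activity class) are themselves informative.

The 7:3 inner split is "cluster-balanced": k-means (k = max(2, n/10)) on
standardized descriptors, then a seeded 7:3 draw within each cluster. The
intent is that training and internal test cover the same structural space;
plain stratified draws are the fallback when no descriptors are supplied.

## The screening gate

Screening is a two-stage AND filter. A library molecule must first be
predicted `high` by the trained model; it must then have every gated
descriptor inside `[μ − 1.96σ, μ + 1.96σ]`, where μ and σ are computed
over the high-activity reference ligands. The gated set defaults to the
eight electronic descriptors (JGI8, JGI9, BCUTp-1h, PEOE_VSA-4,
PEOE_VSA+1, PEOE_VSA-0, nAtomP, HBA_Count) because metal–ligand binding is
dominated by electronic structure: polarizability, local charge
concentration, π-system size and acceptor count. The 1.96 multiplier is
the central 95% band of a normal population; bounds are inclusive, and a
zero-variance descriptor degenerates to an exact-match interval with a
warning. The reference population (high-activity ligands vs the pooled
set) is configurable via `profile_descriptors(reference = )`.

Retained hits can be searched against the shipped ZnBF SMARTS table
(`znbf_patterns()`): best-effort encodings of the known zinc chelators
(hydroxamic acid, sulfonamide, urea, phosphonate) plus candidate
fragments, each annotated with binding-atom positions and denticity and
flagged `known`/`candidate` in the provenance column. SMARTS matching
stands in for pharmacophore-feature searches: it preserves the logic
(require a ZnBF-bearing substructure) without proprietary feature
perception. Ranking of hits is by model score with matched-pattern count
as tie-break; docking-based prioritization is out of scope. For 3D
complexes, `extract_binding_atoms()` applies the standard geometric rule:
O/N/S/F heteroatoms within 2.8 Å of the metal are the binding atoms, and a
fragment's denticity is its count of binding atoms to one metal.

## The descriptor provider

No open R package computes the named electronic descriptors, so the
package implements them from their published definitions on the
hydrogen-suppressed molecular graph (structures parsed via OpenBabel):

* `JGIk`: Galvez topological charge indices — `G_k = ½ Σ |m_ij − m_ji|`
  over atom pairs at topological distance k, with `M = A·D*`, `A` the
  adjacency matrix and `D*` the inverse-square distance matrix,
  normalized by (n − 1).
* `BCUTp-1h/-1l`: extreme eigenvalues of a Burden matrix with tabulated
  atomic polarizabilities on the diagonal, 0.1 × bond order for bonded
  pairs and 0.001 elsewhere.
* `PEOE_VSA-4/+1/-0`: Gasteiger–Marsili partial equalization of orbital
  electronegativities (6 damped iterations, implicit hydrogens attached
  explicitly), with each atom's approximate accessible van der Waals
  surface (sphere area minus neighbour caps at covalent-radius bond
  lengths) summed into the charge bins [−0.25, −0.20), [0.05, 0.10) and
  [−0.05, 0.00).
* `nAtomP`: size of the largest connected subgraph of atoms incident to
  multiple bonds (aromatic systems count via their Kekulé forms).
* `HBA_Count` / `HBD_Count`: N+O acceptor count; N/O atoms bearing
  hydrogens.

These are faithful 2D implementations, not re-derivations of any
commercial package's exact values; quantum-chemical (DFT) descriptors are
supported only through CSV ingestion (`read_descriptor_csv()`, which
median-imputes sparse gaps and drops columns with more than 20% missing).
The cascade's activity correlation is Pearson by default (Spearman behind
a flag), computed against continuous `lg(Ki)`; class-facing
interpretation uses the point-biserial correlation plus a Mann–Whitney U
test (exact enumeration when the smaller class has ≤ 8 untied values,
normal approximation with tie correction otherwise).

## What the generator emulates — and what it does not

`synthetic_spec()` fixes the study conditions: 208 ligands at the 131:77
high/low ratio, `lg(Ki)` spanning [−4, 7] from a two-component
distribution (high centred near 0.6, low near 4.6, both clear of the
class cut-offs so per-record jitter cannot flip classes), 30% of ligands
with 2–4 Ki records of which 15% are discordant (spread > 1, guaranteed
by construction), 12% structural near-duplicates, and 8 informative
descriptors at a standardized effect size of 1.5 against 42 noise
columns. Structures come from a closed fragment grammar — scaffold ×
linker × cap, with hydroxamate/sulfonamide/urea/phosphonate caps on
high-activity ligands and inert caps on decoys — so fingerprints and
SMARTS behave chemically sensibly. Near-duplicates are single-atom edits
verified against the parent's MACCS fingerprint at generation time, which
makes the "> 0.75 similarity" property true by construction rather than
by hope. A zero-variance column and a collinear pair are always planted
to exercise the cascade. All randomness flows from one root seed through
named substreams, so each stage is reproducible in isolation.

What the generator does *not* emulate: real structure–activity coupling
(descriptor signal is statistical, drawn class-conditionally, not
computed from the structures), real descriptor covariance, assay
heterogeneity beyond log-normal jitter, and any particular enzyme's SAR.
Passing tests therefore demonstrate that the machinery recovers planted
truth under honest noise — not that the classifier generalizes to any
real screening library. Accuracies near 99% on the defaults reflect the
planted effect size, not expected real-world performance.

## Numerical choices

* "Arbitrary" redundancy removal is made deterministic: ascending
  ligand-id greedy, keep iff similarity to every kept same-class ligand
  is ≤ 0.75; the result is idempotent under re-pruning.
* Naive Bayes class-conditional SDs are floored at 1e-6 to avoid singular
  likelihoods; posteriors are computed in log space.
* IBK ties are broken toward the class with the nearer mean neighbour
  distance, then lexicographically; features are min–max standardized, so
  predictions are invariant to affine rescaling of any feature.
* J48 thresholds are midpoints between consecutive sorted distinct
  values; pruning is C4.5-style pessimistic estimation at confidence
  0.25 (toggleable); `min_obj ≥ n` degenerates to a single-leaf tree with
  a warning rather than an error.
* Best-first searches stop after 5 consecutive non-improving expansions;
  improvement requires exceeding the incumbent by 1e-12, which biases
  ties toward smaller subsets.
* Cascade stage 3 processes pairs in descending pairwise |r|; ties on the
  activity correlation drop the lexicographically later name, making the
  surviving *set* independent of column order.
* Gate bounds are inclusive ("within the range" read inclusively); the
  boundary value μ + 1.96σ passes, μ + 2σ fails.
* Stratified CV folds are dealt round-robin within class after a seeded
  shuffle; every instance is tested exactly once per repeat.

## Problem sizes in the test suite

The suite exercises the pipeline at deliberately modest sizes chosen to
make the statistical assertions sharp but cheap: oracle equivalence on
200 enumerable toys (n ≤ 20, ≤ 2 features), CFS optimality against
exhaustive 2^k enumeration for k ≤ 12, parameter recovery over 50 seeds
at n = 200 with 5 informative among 50 descriptors, and screening
enrichment over 20 seeds on 2000-molecule libraries at 5% prevalence.
These sizes give binomial assertion thresholds (≥ 80%, ≥ 90% of seeds)
comfortable margins over their observed rates.

## Limitations

* Descriptor values are 2D-graph approximations; absolute values will not
  match any particular commercial implementation, although orderings and
  class contrasts behave equivalently on the synthetic conditions.
* The ZnBF SMARTS table encodes named chelator classes, not any specific
  figure's exact fifteen fragments; `provenance` separates the known
  chelators from candidate encodings.
* Binary classes only; the excluded `[2, 3]` band is discarded, not
  modelled as a third class.
* No docking, pose generation or binding-affinity prediction; substructure
  search is the final computational stage.
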