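---
title: "Methods: pair features, resampled ensembles and the combination index"
author: "synergyscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pair features, resampled ensembles and the combination index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`synergyscreen` implements a screening pipeline for synergistic
small-molecule drug combinations — in its motivating use case, pairs of a
traditional-Chinese-medicine (TCM) ingredient and a Western drug for
rheumatoid arthritis. The pipeline has four stages: (1) sixteen pair
features computed from drug fingerprints, ADME descriptors, and the drugs'
protein targets; (2) statistical and recursive-feature-elimination (RFE)
screening of those features; (3) an ensemble of classifiers trained on
repeatedly undersampled training sets, whose positive votes rank candidate
pairs; and (4) Chou–Talalay median-effect evaluation of measured
combinations via the combination index (CI). This vignette documents the
model behind each stage, the tunable parameters and their defaults, the
numerical policies, and what the synthetic-data generator does and does not
emulate.

## The sixteen pair features

For a drug pair $(d_A, d_B)$ with fingerprints $A, B$, ADME vectors
$x^A, x^B$ and target sets $T_A, T_B$:

* **S_FP** — Tanimoto similarity
  $A\cdot B / (\lVert A\rVert^2 + \lVert B\rVert^2 - A\cdot B)$ of the
  binary fingerprints (input data; the package computes no fingerprints).
  An all-zero fingerprint makes the ratio 0/0 and is rejected as a
  degenerate input.
* **S_ADME** — Euclidean distance of the descriptor vectors after per-slot
  min–max normalization over the whole drug universe. Min–max is used
  because it bounds each slot's contribution to $[0,1]$; a slot that is
  constant across the universe carries no information and contributes 0
  (logged). The descriptor count K is inferred from the input table
  (default 12).
* **S_Seqmin/max/med/mean** — order statistics, over all
  $|T_A|\times|T_B|$ target cross pairs, of normalized Smith–Waterman
  local-alignment similarity
  $sw(a,b)/\sqrt{sw(a,a)\,sw(b,b)}$ (BLOSUM62, gap open 10, gap extend
  0.5). Raw local-alignment scores grow with sequence length; dividing by
  the geometric mean of the self-scores makes self-similarity exactly 1
  and bounds the value to $[0,1]$. A consequence worth knowing: a short
  sequence embedded exactly in a longer one scores
  $\sqrt{sw(a,a)/sw(b,b)} < 1$, not 1. The median of an even count of
  values is the mean of the two central values everywhere in the package.
* **S_GOmin/max/med/mean** — the same cross-pair order statistics applied
  to gene-level Gene Ontology similarity. Term-level similarity uses
  Wang's graph-based measure: a term's semantic profile assigns S-value 1
  to itself and propagates $S(\text{parent}) = \max_e w_e S(\text{child})$
  through the ontology DAG (edge weights 0.8 for `is_a`, 0.6 for
  `part_of`); two terms are scored by shared semantic weight over total
  semantic weight. Gene-level similarity combines the two genes' term
  sets by best-match average (BMA). Wang's measure was chosen because it
  needs no annotation corpus (information-content measures do); a Jaccard
  fallback over term sets is available via `go_method = "jaccard"` for
  speed.
* **S_Pathway** — cosine similarity of the drugs' pathway membership
  vectors. The pathway universe is fixed per run: hypergeometric
  over-representation of the pooled target set of *all* drugs against
  each pathway, Benjamini–Hochberg correction, and inclusion at
  $p < 0.05$ and $q < 0.05$. A drug's vector has bit $k = 1$ iff its
  targets intersect enriched pathway $k$. A drug hitting no enriched
  pathway would make the cosine 0/0; the package defines the similarity
  as 0 in that case (no shared pathway signal).
* **S_PPImin/max/med/mean and S_np** — shortest-path distances $d(a,b)$
  between targets in the protein–protein-interaction network, mapped
  through $\sigma(d) = 1/(1+e^{-d})$ for the min, max and median; the
  mean distance $\langle d_{AB}\rangle$ is mapped through a mean-transform
  sigma whose exponent sign is configurable (`ppi_sigmoid_sign`). The
  default `"as-printed"` uses the same $\sigma$ as the other three, which
  confines $\sigma(\langle d\rangle)$ to $[0.5, 1)$ for non-negative
  distances; the `"inverted-mean"` alternative uses $1/(1+e^{+d})$, which
  instead decreases with distance. Both are provided because reference
  feature tables in this family of screens show mean-PPI values below 0.5,
  which only the inverted form can produce; the package takes no position
  and defaults to the printed formula. Network proximity is
  $S_{np} = \sigma_m(\langle d_{AB}\rangle) -
  \tfrac12[\sigma_m(\langle d_{AA}\rangle) +
  \sigma_m(\langle d_{BB}\rangle)]$, with within-drug means over ordered
  pairs of *distinct* targets and $d = 0$ for a singleton target set.
  Because the between-drug mean includes the zero diagonal when
  $T_A = T_B$, self proximity is exactly 0 only for singleton target
  sets. Disconnected target pairs receive distance (diameter + 1) under
  the default policy (keeping every feature finite); the strict
  alternative `"drop-pair"` removes them from the aggregates.

Every feature is symmetric in the two drugs, and each aggregate family
satisfies min ≤ med ≤ max and min ≤ mean ≤ max; both properties are
enforced by tests on randomly generated universes.

## Feature screening

Two group-difference tests per feature (combination vs non-combination
pairs): a Welch two-sided t-test (unequal variances, the safer default
when group sizes differ by 5:1) and a two-sided Mann–Whitney U test
(delegated to `stats::wilcox.test`, which uses exact enumeration for small
untied samples and the tie-corrected normal approximation otherwise). A
feature constant in both groups is reported with p = 1 and a degenerate
flag rather than NA, so downstream tabulation never drops rows.

RFE is run once per resampled training set: within each of 5 stratified
inner folds a random forest ranks features by impurity importance, subset
sizes 1..16 are each scored by held-out accuracy, the best mean-accuracy
size wins (ties to the smaller size), and the returned subset is the
top-k of a full-data ranking. The per-feature selection frequency over
the `n_resamples` training sets is compared with the retention cutoff
(default 0.70, i.e. the feature must appear in at least 70% of
selections). The inner fold count (5), the candidate size grid (1..16)
and the RFE forest size (`rfe_ntree = 50`) are recorded configuration
choices, not inferred from any reference implementation.

## The resampled ensemble and its evaluation

Positive (combination) pairs are scarce next to the non-combination pool,
so a single undersampled training set wastes most of the pool and a single
oversampled one overfits. The protocol instead draws `n_resamples`
(default 1000; 50 at the toy scale) training sets, each holding **all**
positives plus `ratio_neg_per_pos` (default 5) times as many negatives
drawn uniformly without replacement. One classifier is fitted per
resample — by default a 300-tree probability random forest restricted to
the screened feature subset. Candidate pairs are scored by every member;
a member votes "combination" when its positive-class probability is at
least 0.5, and candidates are ranked by vote count.

Vote bins follow the printed cutpoints at the 1000-resample scale
(> 500, 100–500, 1–100, 0) and rescale as the same fractions of R
(0.5 and 0.1) for other ensemble sizes, as does the report-selection
threshold (default 700, strictly exceeded); with R = 50 the threshold is
therefore "more than 35 votes". Boundary values fall downward (a
vote count of exactly 500 is in the 100–500 bin; exactly 700 is not
selected).

Evaluation uses repeated stratified k-fold cross-validation (default
3 × 10-fold) per member: confusion counts are pooled over the folds of a
repeat at threshold 0.5, precision/recall/accuracy/F1 computed from the
pooled counts, AUROC by trapezoidal integration of the tie-aware ROC
staircase (equal to the Mann–Whitney U statistic with ties counted one
half), and AUPRC by right-continuous stepwise integration. Metrics are
averaged over repeats, then reported mean ± sd over ensemble members.
Classifier families available behind the same interface: `rf`, `knn`
(k = 5), `nb` (Gaussian naive Bayes), `svm_rbf` (Platt-scaled
probabilities), and `adaboost` (discrete AdaBoost.M1 over depth-1
decision stumps, 50 rounds, implemented in-package).

Two evaluation paths exist because screens of this kind report both: the
repeated-CV path above (the package default, and what the bundled
recovery study reports — it uses every row for evaluation and yields a
spread) and a stratified 70/30 internal-validation holdout
(`holdout_validate()`), which evaluates a single fit on untouched rows.
The defaults favor CV because at toy scale a 30% holdout of a 270-row
training set holds only ~13 positives and its metrics are
correspondingly coarse.

All randomness derives from `master_seed` through a per-stage string-hash
derivation, so any single resample, fold split or classifier fit is
reproducible in isolation and two runs with the same master seed agree to
full precision.

## Median-effect model and combination index

A single agent's dose–response is summarized by the median-effect
equation $f_a/f_u = (D/D_m)^m$ with $f_u = 1 - f_a$: a straight line of
slope $m$ and intercept $-m\log_{10} D_m$ on the plot of
$\log_{10}(f_a/f_u)$ against $\log_{10} D$. Fitting is ordinary least
squares on that plot after (1) dropping zero-dose rows, (2) averaging
replicate wells at the same dose, and (3) clipping observed $f_a$ into
$[0.005, 0.995]$ — the transform is undefined at 0 and 1, and the clip
bound is an explicit, logged policy. A fit with non-positive slope or
all-clipped data is flagged degenerate. IC50 equals $D_m$ by
construction; fitted values above the tested dose range are reported as
"> top-dose" strings in formatted output.

The effect-equivalent dose is $D_x = D_m (f_a/f_u)^{1/m}$, and a
combination observed at doses $(D_A, D_B)$ with fraction affected
$f_a$ has $CI = D_A/(D_A)_x + D_B/(D_B)_x$: below 1 synergy, 1 additivity
(within 1e-9), above 1 antagonism. CI is computed per observed dose pair
(no CI-versus-fa curve interpolation), and combination tables also carry
the per-pair minimum CI so that a "best observed synergy" per pair can be
read without asserting any particular pair-level rule.

## The synthetic universe and what it shows

The generator builds a toy universe whose defaults are: 30 drugs, 60
druggable targets inside a 200-protein preferential-attachment PPI
network, 15 pathways of size 8–14, a 40-term GO DAG (random tree plus 20%
shortcut edges), 1024-bit fingerprints at 10% density, and 12 correlated
ADME slots. Four "disease" pathways own disjoint 12-target druggable
slices; each drug is assigned one home pathway (round-robin, so the share
of home-sharing pairs is stable near 1/4) and draws 90% of its 4–6
targets from the home slice. Co-pathway targets adopt a shared GO theme
term only half the time, so GO similarity correlates with pathway sharing
without duplicating it.

Labels are planted by a logistic model on the *computed* features —
default weight 4 on `S_Pathway`, 2 on `S_np`, intercept calibrated by
root-finding so the mean positive probability equals the base rate
(default 0.10). Two consequences of those choices are worth making
explicit. First, with a weight of 4 on a $[0,1]$ feature the attainable
log-odds spread is 4, which caps the Bayes-optimal AUROC of *any*
classifier near the mid-0.8s; the universe geometry above was shaped so
that the planted signal sits near that optimum rather than below it, and
the end-to-end recovery check (pathway feature in the top-3 RFE
frequencies, ensemble CV AUROC above 0.8) operates close to that ceiling
by design. Second, the base rate must stay below 1/(1 + ratio) — at 0.10
with ratio 5 the negative pool of a 435-pair universe comfortably covers
every resample.

The generator emulates the *statistical shape* of the real inputs —
sparse fingerprints, correlated descriptors, scale-free interactome,
set-structured annotations, planted label dependence on pathway
similarity, and median-effect dose–response curves with known $(m, D_m)$
and known CI. It does not emulate real chemistry or biology: sequences
are uniform random strings (so sequence features are uninformative noise
here), GO terms and pathways carry no real identifiers, and fingerprints
are unrelated to the targets. Passing recovery tests therefore
demonstrates that the pipeline's machinery recovers a known planted
signal at realistic sample sizes — not that the features are informative
on any real drug universe.

## Problem sizes and runtime choices

The default toy scale (30 drugs = 435 pairs, 50 resamples, 5-fold RFE
over sizes 1..16, 3×10-fold member CV) runs a full planted-signal
recovery in roughly a minute and a half per master seed; the bundled
recovery study uses 10 master seeds. The RFE forests use 50 trees
(importance rankings stabilize far below the main model's 300), and all
forest fitting is single-threaded for reproducibility. The 200-replicate
noisy median-effect recovery uses the 7-point dose ladder of the
motivating assay design.

## Known limitations

* The mean-PPI sigmoid ambiguity is deliberately unresolved; results
  using `S_PPImean`/`S_np` should state which `ppi_sigmoid_sign` was
  used.
* Pathway enrichment treats the pooled target set of all drugs as the
  draw; per-drug enrichment is not implemented.
* `knn` produces tied vote fractions rather than calibrated
  probabilities; its AUROC on small sets is coarse.
* The AdaBoost implementation is the classic discrete variant with
  stumps; it is not tuned to match any external implementation.
* Pair-level synergy verdicts from multi-dose combination tables are
  reported as per-row CI plus the per-pair minimum; no single pair-level
  rule is asserted.
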