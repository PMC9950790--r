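# synergyscreen

Screening synergistic small-molecule drug combinations — pairs of a
traditional-Chinese-medicine (TCM) ingredient and a Western drug in the
motivating rheumatoid-arthritis use case — by machine learning over
drug-pair features, with Chou–Talalay median-effect evaluation of the
predicted combinations.

The package is aimed at computational pharmacology groups who have, for
each drug, a binary molecular fingerprint, an ADME descriptor panel and a
protein-target set, plus shared context (target sequences, GO annotations
and ontology, pathway sets, a protein–protein-interaction network), and
who want a tested, reproducible implementation of the full screen:

1. **Pair features.** Sixteen characteristic variables per unordered drug
   pair: fingerprint Tanimoto similarity
   `S_FP = A·B/(‖A‖² + ‖B‖² − A·B)`; Euclidean ADME distance after
   min–max normalization; min/max/median/mean of normalized
   Smith–Waterman similarity `sw(a,b)/√(sw(a,a)·sw(b,b))` over all target
   cross pairs; the same four aggregates of Wang-method GO semantic
   similarity (best-match average at the gene level); cosine similarity
   of membership vectors over the hypergeometrically enriched pathway
   universe (p < 0.05 and BH q < 0.05); and sigmoid-transformed PPI
   shortest-path statistics `σ(d) = 1/(1+e^{−d})` with the
   separation-style network proximity
   `S_np = σ(⟨d_AB⟩) − [σ(⟨d_AA⟩)+σ(⟨d_BB⟩)]/2`.
2. **Feature screening.** Welch t and Mann–Whitney tests per feature,
   plus recursive feature elimination run on each of R resampled
   training sets; features selected in ≥ 70% of resamples are retained.
3. **Resampled ensemble.** R training sets (default 1000; 50 at the toy
   scale), each all positives + 5× negatives drawn without replacement;
   one 300-tree probability random forest per resample (k-NN, naive
   Bayes, SVM-RBF and AdaBoost are pluggable); evaluation by 3×10-fold
   stratified CV (precision, recall, accuracy, F1, AUROC, AUPRC).
   Candidate pairs are ranked by positive votes over the members and
   binned (>500 / 100–500 / 1–100 / 0 at R = 1000, rescaled fractions
   otherwise); pairs strictly above the report threshold (700 votes at
   R = 1000) are selected.
4. **Synergy evaluation.** Median-effect fits `fa/fu = (D/Dm)^m` per
   single agent, effect-equivalent doses `Dx = Dm(fa/fu)^{1/m}`, and the
   combination index `CI = D_A/(D_A)_x + D_B/(D_B)_x` per combination
   observation (CI < 1 synergy, = 1 additive, > 1 antagonism).

A synthetic-data module generates a complete toy universe (drugs,
targets, GO DAG, pathways, scale-free PPI network, planted logistic
labels, median-effect dose–response curves with known ground truth) so
the whole pipeline is testable offline; see the methods vignette
(`vignettes/synergy-screening-methods.Rmd`) for the model and every
default.

## Worked example

The `analysis/` directory holds the numbered pipeline drivers; each reads
the previous stage's output under `results/`:

```sh
Rscript analysis/01_simulate.R 1   # simulate + serialize the universe
Rscript analysis/02_featurize.R 1  # 16 features for all 435 pairs + labels
Rscript analysis/03_screen.R 1     # tests + resampled RFE frequencies
Rscript analysis/04_train.R 1      # 50-member ensemble + model comparison
Rscript analysis/05_predict.R 1    # candidate votes, bins, selection
Rscript analysis/06_synergy.R 1    # median-effect fits + CI tables
```

A run with seed 1 prints, among other lines:

```
featurized 435 pairs: 44 positive, 391 in the negative pool
mean pathway similarity, positives vs negatives: 0.794 vs 0.253
features with Mann-Whitney p < 0.05: S_Seqmax, S_Seqmean, S_GOmax, S_GOmean, S_Pathway, S_PPImin, S_PPImean, S_np
retained at the 70% RFE frequency cutoff (4 of 16): S_FP, S_Seqmean, S_Pathway, S_np
ensemble CV metrics (mean +/- sd over 50 members):
    metric      mean          sd
  accuracy 0.8356818 0.008843941
 precision 0.5126246 0.044442825
    recall 0.3172727 0.039219919
        f1 0.3905831 0.038782763
     auroc 0.8193023 0.013693650
     auprc 0.4523569 0.031472819
single-resample CV AUROC by model: rf 0.820, knn 0.783, nb 0.825, svm_rbf 0.760, adaboost 0.800
candidates: 20 TCM x 10 Western = 200 pairs
vote bins (of 50 resamples): >25: 17, 5-25: 13, 1-5: 14, zero: 156
14 pair(s) selected above the rescaled threshold (> 35 votes)
median-effect fits (5% noise):
  agent m_true dm_true m_fit dm_fit     r2  ic50
 agentA    1.2       8 1.078  8.843 0.9647  8.84
 agentB    2.0      25 1.576 28.583 0.9852 28.58
simulated combinations: additive rows recover CI 1.0000-1.0000, fixed-0.4 rows 0.4000-0.4000
reference combination table: 5 of 7 pairs have minimum CI below 0.7
```

Read: the planted pathway signal is recovered — pathway similarity
separates the label groups (0.794 vs 0.253), survives both
group-difference tests and the resampled RFE screen — and the 50-member
forest ensemble, trained on the four retained features, reaches CV
AUROC ≈ 0.82 against a planted-label Bayes ceiling in the mid-0.8s.
Vote binning partitions all 200 cross-category candidates, the
median-effect refit recovers the simulated agents' parameters from noisy
4-point curves, and the combination-index calculator returns the exact
ground-truth CI of simulated additive (CI = 1) and synergistic (CI = 0.4)
mixtures. The last line summarizes the bundled reference
combination-index table (`inst/extdata/reported_combination_ci.tsv`).

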