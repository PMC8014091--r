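---
title: "Methods: targeted PRM quantification and co-abundance network analysis of detergent-insoluble proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted PRM quantification and co-abundance network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Protein aggregation is a hallmark of neurodegenerative disease. After
detergent (sarkosyl) extraction and ultracentrifugation of brain tissue,
the insoluble pellet is enriched for aggregated proteins; quantifying a
targeted panel of RNA-binding proteins (RBPs) in that fraction across
control, asymptomatic Alzheimer's disease (AsymAD), AD and Parkinson's
disease (PD) cases asks which protein complexes shift into (or out of)
the aggregated state, and at which disease stage.

`prminsol` implements the full quantitative workflow for such a study as
reusable, tested components: parallel reaction monitoring (PRM)
transition-level quantification, spike-in reference drift normalization,
protein roll-up and preprocessing, differential-insolubility statistics,
a signed weighted co-abundance network with eigenproteins and
module-trait correlation, and Fisher-exact ontology over-representation.
A synthetic cohort generator reproduces the study's design so that every
stage is testable end to end without any instrument data.

## Quantification model

PRM quantifies a fixed inclusion list of peptides via their fragment-ion
chromatogram peak areas. The workflow takes integrated areas as input
(long format: injection, peptide, charge, fragment ion, area) and:

1. ranks each peptide's fragment ions by mean area across all injections
   and keeps the strongest `k` (default 5, at least 3) as quantifiers —
   an experiment-wide ranking gives a stable quantifier set;
2. sums quantifier areas into a peptide quantity per injection; an
   injection with fewer than 3 nonzero quantifier ions yields 0
   (missing);
3. sums corrected peptide quantities into protein (entity) quantities.

The amyloid-beta peptide region (residues 597–638 of APP, 695
numbering) is rolled up as its own entity, separate from APP, since
plaque-derived amyloid-beta and full-length APP behave differently in
the insoluble fraction.

## Drift normalization

A reference mix — 6 peptide sequences × 5 isotopologues in a tenfold
dilution series (0.0001× to 1×) — is spiked at a constant nominal amount
into every injection. Any trend of reference signal over the injection
sequence is therefore technical drift. Following the intensity-ratio
construction:

* `IR_ij = A_ij / mean_j(A_ij)` scales each reference peptide *i* to
  mean 1 across injections *j*;
* the calibration level is the 0.01× isotopologue, and the 4 (of 6)
  peptides with the highest R² of area against injection index are used
  — the most linear responders;
* `CF_j = 1 / mean_i(IR_ij)` is a per-injection multiplicative
  correction applied to every peptide quantity of injection *j*.

An ordinary least-squares fit of the mean ratio series against
injection index (slope, intercept, R²) is reported as a diagnostic; the
correction always uses the observed per-injection ratios, not the
fitted line. Percent CV of the selected reference peptides before and
after correction quantifies the improvement.

One identifiability note: because intensity ratios are normalized to
per-peptide mean 1, the correction recovers drift-free quantities only
up to the constant `mean_j d(j)` for a true drift profile `d`. That
global scalar cancels in every ratio, fold change and log2 difference
downstream, so it is irrelevant to the analysis; the package's
exact-cancellation tests assert recovery up to this scalar at 1e-9
relative tolerance.

## Preprocessing

The protein matrix advances through enforced, ordered stages:

1. **Imputation.** Zeros are replaced by half the row's minimum nonzero
   value — the conventional noise-floor imputation for rare missing
   values in targeted proteomics. Rows with no nonzero value are
   dropped with a warning naming them.
2. **log2 transform.**
3. **Covariate residualization.** Per protein, OLS on age at death, sex
   (0/1, male = 1) and post-mortem interval; the output is the residual
   plus the protein's grand mean, so group locations stay
   interpretable. Constant covariates are dropped with a warning.
   Residuals are exactly orthogonal to each retained covariate.

The order impute → log2 → residualize is fixed by the stage flags;
out-of-order calls raise ordering errors rather than silently producing
a differently-scaled matrix.

## Differential insolubility

Pairwise volcano tables (AsymAD/CTL, AD/CTL, PD/CTL) use the log2 fold
change of group means and a two-tailed equal-variance Student t test.
A protein is flagged changed beyond a 50% fold change (|log2 FC| >
log2 1.5) with p < 0.05. No multiple-testing adjustment is applied in
the default path — the small cohort limits power even unadjusted — and
p-values are floored at 1e-300. One-way ANOVA and Kruskal–Wallis
omnibus tests annotate each protein with 0.05/0.01/0.001 stars. Per
module, the fraction of members significant at p < 0.05 and the mean
log2 FC of those members summarize module-wise disease shifts.

## The co-abundance network

The network machinery is implemented from scratch (matrix algebra on
base R), with each primitive checked against an independent brute-force
oracle:

* **Biweight midcorrelation (bicor)** with the conventional 9×MAD
  tuning constant: `u = (x − median)/(9 MAD)`, weights `(1 − u²)²` for
  `|u| < 1`. A zero-MAD variable falls back to Pearson (mean-centered,
  unit weights); a constant variable yields NA.
* **Signed adjacency** `a = ((1 + ρ)/2)^β` with β = 23, the power
  established for protein abundance networks; `pick_soft_power()`
  implements the scale-free criterion (lowest power reaching R² 0.80,
  else the plateau power where the R² gain drops below 0.01) as a
  diagnostic.
* **Topological overlap** with the mean denominator:
  `TOM_ij = (L_ij + a_ij)/(mean(k_i, k_j) − a_ij + 1)`; `1 − TOM` is
  the clustering dissimilarity.
* **Tree cut.** Average-linkage clustering, then a simplified dynamic
  hybrid cut: every merge height is evaluated and the cut yielding the
  most clusters of at least `min_module_size` (5) is taken, with
  `deep_split` (default 4) allowing coarser near-optimal cuts at lower
  settings; leftover entities are PAM-assigned to the nearest module by
  average dissimilarity when they are distinctly closer to it than to
  the remaining assigned entities, restricted to their dendrogram
  branch when `pam_respects_dendro`. Bit-compatibility with the
  reference WGCNA implementation is explicitly not promised;
  planted-structure recovery (adjusted Rand index against ground truth)
  is the correctness criterion.
* **Eigenproteins.** First right singular vector of the
  member-standardized submatrix, unit norm, sign fixed to correlate
  positively with the module mean profile (ties toward a positive first
  coordinate). Two orthogonal members split the variance evenly (0.5);
  two perfectly anticorrelated members are rank one, so the first
  component carries all the variance.
* **Merge and cleanup.** Fixed-point iteration (capped at 100 rounds):
  modules merge while their eigenprotein correlation exceeds
  1 − 0.07 = 0.93; members with own-module kME (bicor to the module
  eigenprotein) below 0.30 move to the unassigned bin; an entity moves
  to another module when its kME there is significantly higher
  (one-sided Fisher-z correlation-difference test at p < 0.05 — an
  independence approximation of the dependent-correlation test, chosen
  for robustness and simplicity). Modules are relabelled M1..Mk by
  decreasing size, M0 collecting unassigned entities.
* **Module–trait correlation.** Bicor of each eigenprotein with CERAD
  and Braak scores and one-vs-rest diagnosis indicators, with Student
  t p-values for the correlation.
* **Pathology ranking.** Bicor of every protein profile against the
  amyloid-beta and tau (MAPT) entity profiles across cases, ranked
  descending.

## Ontology over-representation

Fisher's exact test (two-tailed) on the 2×2 overlap table of module
members against each annotation term over a fixed background universe.
Significance requires the Z-score equivalent of the two-tailed p
(`Z = qnorm(p/2, lower = FALSE)`, signed by direction) to exceed 1.96
*and* at least 3 overlapping symbols; under-represented terms carry a
negative Z and are never flagged. The module × term Z matrix is
co-clustered with Manhattan (L1) distance and Ward linkage and cut into
a requested number of macro-clusters (default 6). Annotation input is a
plain GMT or two-column file; no ontology-graph propagation is
performed.

## The synthetic cohort generator

The generator defines the study conditions under which everything is
tested:

* **Cohort.** 12 CTL / 8 AsymAD / 12 AD / 12 PD cases; age, PMI, sex,
  CERAD (0–3), Braak (0–6), ABC (0–3) and binary DLB-neocortex scores
  drawn per group from the cohort summary distributions (truncated
  normals rounded to valid scores). Cases are randomly permuted over 50
  injections with 6 pooled-standard (GPS) injections at evenly spaced
  positions — the even spacing is an assumption, since the true GPS
  injection order is not specified by the design.
* **Targets.** 870 peptides over 390 entities: 385 RBPs (2–3 tryptic
  peptides each), 35 MAPT peptides, 9 APP peptides outside the
  amyloid-beta window, 3 amyloid-beta peptides inside residues
  597–638, and 2 standard slots. Peptide sequences are random
  tryptic-like strings; precursor m/z is computed from monoisotopic
  masses with fixed carbamidomethyl-Cys (+57.0215 Da).
* **Planted structure.** 29 modules with fixed sizes 5–60 exhausting
  the 390 entities; within-module correlation 0.7 via a shared
  per-module latent factor (`x = √r·f + √(1−r)·ε`) at biological SD
  0.5 log2 units. MAPT, APP and amyloid-beta sit in one module that is
  shifted +0.8 log2 in AsymAD and +1.2 in AD; a second module is +1.0
  in AD; two further modules are −1.0 in PD and −0.8 in AD — the
  qualitative stage-specific enrichment/depletion pattern reported for
  insoluble RBP complexes. Small age/sex/PMI slopes are injected so
  residualization is testable.
* **Measurement layer.** Peptides carry fixed lognormal ionization
  weights and 3–6 y-ion fragments with fixed fractional intensities;
  observed area = true quantity × a shared per-injection multiplicative
  drift (default the linear ratio profile 1.417 − 0.0167·j) × lognormal
  noise (default CV 0.15, consistent with the post-normalization
  reference variability scale). The reference mix follows its tenfold
  design times the same drift; two of the six reference sets get 4×
  noisier to make the R²-based selection meaningful.
* **Missingness.** A protein × case cell is missing with probability
  0.0073, implemented by zeroing all of that protein's transitions in
  that sample, so the 390 × 44 protein matrix carries exactly a
  binomial 0.73% zero rate (≈125 of 17,160 values in expectation). A
  peptide-level-only mechanism cannot reproduce a protein-level rate,
  because a protein-level zero would then require all of its peptides
  to vanish simultaneously.
* **Determinism.** Every generator function seeds its own RNG stream
  from `seed` plus a fixed offset; identical seeds give byte-identical
  outputs.

What the generator deliberately does **not** emulate: chromatographic
peak shapes and interference, retention-time drift, intensity-dependent
(left-censored) missingness, peptide-level PTM heterogeneity,
correlated fragment noise, and batch structure beyond the single linear
drift. Passing tests therefore demonstrate the correctness of the
algorithms under a faithful but idealized measurement model, not
robustness to every artifact of real LC-MS/MS data.

## Numerical choices and degenerate inputs

* Sample SD (n−1) for percent CV; CV is an error for fewer than 2
  values or zero mean.
* R² of a zero-variance ratio series is defined as 1 (the line fits
  exactly with slope 0).
* Equal pairwise dissimilarities cut to a single module (documented tie
  rule); fewer entities than `min_module_size` yield an all-unassigned
  partition with a warning.
* Entities whose values are tied within every group get omnibus p = 1
  with a warning rather than an error.
* Fisher p-values come from `stats::fisher.test`; tests verify equality
  with exhaustive hypergeometric enumeration to 1e-12 over all margins
  up to 30.
* p-values are floored at 1e-300 and never truncated to 0.

## Problem sizes used by the test suite

Unit tests run the full design (390 proteins × 44 cases, 870 peptides,
50 injections) where the contract is about bookkeeping, and a reduced
design (60 proteins, 120 peptides, 8 modules) where many replicates are
needed; statistical calibration uses 3 × 390 null entities for
false-positive rates, 50 generator seeds for the imputed-fraction
check, and 20 seeds for planted-module recovery. These sizes are the
package's choices for a desk-scale, fully reproducible test bed.

## Known limitations

* The tree cut is a simplified dynamic hybrid; on dendrograms whose
  within- and between-module merge heights overlap heavily it will be
  more conservative than the reference implementation.
* The kME reassignment test treats the two correlations as independent;
  a dependent-correlation test (e.g. Steiger's) would be slightly more
  powerful.
* Planted disease shifts shared by two modules induce genuine
  between-module correlation; at some seeds the eigenprotein merge step
  therefore joins co-shifted modules — visible as a module count
  slightly below the planted 29 with the corresponding trait
  correlation concentrated in the merged module.
* Covariates that co-vary with diagnosis (age, PMI) absorb part of a
  group effect during residualization, attenuating small shifts in
  groups with distinctive covariate profiles — a property of the
  regression design shared with the real study, not an artifact of this
  implementation.
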