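# prminsol

Targeted PRM quantification and co-abundance network analysis of
detergent-insoluble proteins across neurodegenerative disease groups.

## What this is for

Sarkosyl extraction of post-mortem brain tissue leaves an insoluble
pellet enriched for aggregated proteins. Quantifying a targeted panel of
RNA-binding proteins (RBPs) in that fraction across control, asymptomatic
Alzheimer's disease (AsymAD), AD and Parkinson's disease cases reveals
which protein complexes shift into — or out of — the aggregated state,
and at which disease stage. `prminsol` implements the complete
quantitative workflow for such a parallel-reaction-monitoring (PRM)
study, for proteomics analysts who have transition-level peak areas (a
Skyline-style report) and want reproducible, tested statistics on the
other end. A synthetic cohort generator emulating the full study design
(44 cases, 870 peptides over 390 entities, 50 injections with pooled
standards and a 6 × 5 reference dilution series) makes every stage
runnable and testable with no instrument data at all.

## The methods at its core

* **Spike-in drift normalization.** For reference peptide *i* at
  injection *j*, the intensity ratio is IRᵢⱼ = Āᵢⱼ / Ī(Pᵢ); the mean
  ratio over the four most linear reference peptides at the 0.01×
  dilution level gives the per-injection correction factor
  CFⱼ = 1 / Ī(Rⱼ), multiplied into all peptide quantities of injection
  *j*. An OLS fit of Ī(Rⱼ) on *j* and percent CV before/after diagnose
  the drift.
* **Quantification and roll-up.** Peptide quantity = sum of its 3–6
  strongest product-ion areas; protein quantity = sum of corrected
  peptide quantities; half-minimum imputation of rare zeros; log2; OLS
  residualization of age, sex and PMI.
* **Differential insolubility.** Per-protein log2 fold change and
  equal-variance Student t per pairwise comparison, flagged at
  |FC| > 1.5 and p < 0.05 (no FDR adjustment in the default path), plus
  ANOVA / Kruskal–Wallis omnibus tests.
* **Signed weighted co-abundance network**, from scratch: biweight
  midcorrelation, signed adjacency ((1+ρ)/2)^β with β = 23, topological
  overlap (mean denominator), average-linkage clustering with an
  adaptive tree cut (minimum module size 5, deep split 4), module
  eigenproteins (first principal component), kME cleanup at 0.30,
  eigenprotein merging at correlation > 0.93, module–trait bicor
  correlations and protein-vs-pathology (amyloid-beta, tau) rankings.
* **Ontology over-representation.** Two-tailed Fisher exact test per
  module × term, Z-score transform with the Z > 1.96 and ≥ 3-symbol
  rules, and Manhattan/Ward co-clustering of the Z matrix into
  macro-clusters.

See `vignettes/insoluble-prm-workflow.Rmd` for the full methods
account, including the generator's measurement model and all numerical
conventions.

## Worked example

```r
library(prminsol)

cfg     <- sim_config(seed = 1)          # the default 44-case study design
cohort  <- generate_cohort(cfg)
targets <- generate_target_list(cfg)
gen     <- generate_transitions(cohort, targets, cfg)

pep   <- quantify_peptides(gen$transitions)
panel <- reference_panel(gen$reference)
fit_drift(panel)
#> drift_fit: y = 1.460550 -0.018061 * j, R^2 = 0.9084
sprintf("reference CV: %.2f%% -> %.2f%%",
        reference_cv(panel), reference_cv(panel, corrected = TRUE))
#> "reference CV: 30.78% -> 12.52%"
```

The fitted drift diagnostic recovers (within this seed's noise) the
planted linear signal depreciation of about −0.017 ratio units per
injection, and applying the correction factors more than halves the
reference-peptide CV. Continuing through the protein matrix and the
statistics:

```r
corrected <- apply_correction(pep, setNames(panel$correction_factor,
                                            colnames(panel$area)))
prot  <- rollup_proteins(corrected, targets)
cases <- intersect(colnames(prot), cohort$case_id)
prot  <- abundance_matrix(unclass(prot)[, cases],
                          level = "protein", stages = "corrected")
final <- preprocess_matrix(prot, cohort)   # impute -> log2 -> residualize
final
#> abundance_matrix: 390 protein(s) x 44 sample(s);
#>   stages: corrected -> imputed -> log2 -> residualized

volc <- volcano(final, cohort, "AD/CTL")
table(volc$flag)["up"]
#> 35                         # proteins enriched in the AD insoluble fraction

part <- build_network(final)
part
#> module_partition: 390 entities, 29 modules, 1 unassigned

head(module_trait_correlations(part, cohort), 3)  # strongest, by p
#>  module trait   rho        p     stars
#>      M6 cerad 0.786  2.7e-10    ***
#>      M9 dx_AD 0.707  7.9e-08    ***
#>      M9 braak 0.705  9.1e-08    ***

head(pathology_ranking(final), 4)
#>  entity bicor_tau bicor_abeta
#>    MAPT     1.000       0.907
#>  RBP184     0.916       0.912
#>  RBP185     0.910       0.878
#>  RBP189     0.909       0.890
```

The network recovers the 29 planted co-abundance modules; the modules
carrying the planted AD insolubility shifts correlate with CERAD/Braak
scores and the AD diagnosis indicator, and the proteins sharing the
tau-hosting module top the tau/amyloid-beta pathology ranking — the
synthetic analogue of co-aggregating spliceosomal RBPs tracking plaque
and tangle pathology.

The numbered drivers under `analysis/` run the same workflow as a
staged, resumable pipeline with a manifest, writing all tables under
`results/run/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_quantify_normalize.R
Rscript analysis/03_differential.R
Rscript analysis/04_network.R
Rscript analysis/05_enrichment.R
```

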