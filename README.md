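# mutlikeAML

Discovering a "mutant-like" expression subtype in AML cohorts.

TP53-mutant AML is the most rapidly fatal AML subtype, but unsupervised
analysis of bulk RNA-seq (PCA, hierarchical clustering) does not separate
mutant from wild-type transcriptomes. A supervised route does: a ridge
(L2-penalized) logistic regression trained on z-scored expression yields a
per-sample **ridge score** — the linear predictor β₀ + xᵀβ — measuring how
closely a gene expression profile resembles the TP53-mutant profile.
Wild-type samples in the **top decile** of wild-type ridge scores form a
*TP53-mutant-like* class that shares the mutants' poor overall survival,
broad ex vivo drug resistance, and pathway activity. This package is for
computational hematology/oncology researchers who want that derivation as
a tested, reusable pipeline:

* ridge mutant-vs-rest classifier with cross-validated penalty selection,
  scoring, and held-out evaluation (AUROC with tie half-credit);
* top-decile mutant-like labelling (nearest-rank quantile, strict cut);
* a complementary wild-type-only model for cross-cohort transfer over a
  harmonized gene space;
* a compact core gene signature from 100 rounds of elastic-net selection
  on bootstrap resamples (top-25 genes by selection frequency), refit as
  a small ridge classifier;
* Kaplan–Meier / log-rank survival comparison of the MUT / MUTLIKE / WT
  groups, clinical and per-drug t-tests with Benjamini–Hochberg FDR, drug
  AUC sensitivity z-scores, preranked GSEA with permutation NES/FDR, and
  the cross-dataset concordance filters;
* a negative-binomial synthetic-cohort generator with planted ground
  truth (program activation, hidden mutant-like class, survival and drug
  coupling) used to validate every stage.

See `vignettes/mutant-like-subtyping.Rmd` for the model, its assumptions,
and all numerical conventions.

## Worked example

```r
library(mutlikeAML)

cfg <- simulationConfig(seed = 1)          # 400 samples, 2,000 genes,
sim <- generateCohort(cfg)                 # 50-gene program, 9% mutants
res <- runFullPipeline(sim$cohort, drugsA = sim$drugs, seed = 1)

res$assignmentA
#> SubtypeAssignment: 400 samples (36 MUT, 36 MUTLIKE, 328 WT), cutoff -2.699

round(res$mutEvaluation$auroc, 3)          # held-out mutant classifier
#> [1] 0.965

res$survivalA$medians                      # Kaplan-Meier medians (days)
#>     group   n   median
#> 1      WT 328 648.5767
#> 2     MUT  36 227.3162
#> 3 MUTLIKE  36 174.6536

subset(res$survivalA$tests, group2 == "MUTLIKE" | group1 == "MUTLIKE")
#>   group1  group2  chi_square      p_value
#> 2     WT MUTLIKE 52.61207663 4.063826e-13
#> 3    MUT MUTLIKE  0.08194265 7.746819e-01

head(selectionCounts(res$signature), 5)    # elastic-net selection counts
#>   gene_id selection_count
#> 1  G00205             100
#> 2  G00572             100
#> 3  G00735             100
#> 4  G01102             100
#> 5  G01429             100

round(res$signatureRefit$evaluation$auroc, 3)  # 25-gene refit, held out
#> [1] 1
```

Reading: of 400 simulated samples, the 36 wild-type samples above the
90th-percentile ridge-score cutoff are labelled mutant-like; their median
survival (175 days) is indistinguishable from the mutants' (227 days,
log-rank p = 0.77) and far below the remaining wild-type samples'
(649 days, p ≈ 4e-13) — the planted structure, recovered. The 25-gene
signature refit classifies held-out mutant-like samples perfectly here
because every core gene is a planted program gene.

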