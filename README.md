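# paritykit

Statistical toolkit for quantifying how an early full-term pregnancy
(parity) remodels the mammary basal stem/progenitor cell compartment. It is
aimed at stem-cell and mammary-gland biologists who have dose-response
transplantation tables, expression matrices, promoter binding-site counts,
gene-set collections, or stained tissue micrographs, and want the
corresponding inference with planted-truth testability built in.

Five analysis stages, each usable alone or through a single pipeline
configuration:

1. **Limiting dilution** — maximum-likelihood inference of the mammary
   repopulating unit (MRU) frequency under the single-hit Poisson model
   `P(negative | dose d) = exp(-f d)`, with Wald or profile 95% intervals
   on `log f`, likelihood-ratio group comparison, and a deviance
   goodness-of-fit check.
2. **Differential expression** — empirical-Bayes moderated t
   (variances shrunk via a method-of-moments prior on `log s²`), BH
   adjustment, and the linear fold-change (>1.5 or >2.0) / adjusted-p
   (<0.05 or <0.001) / average-linear-expression (>4) filters.
3. **Motif activity** — ridge inference of transcription-factor motif
   activities from `expression ≈ site_counts × activities`, with
   cross-validated penalty and moderated z-scores for parity-induced
   activity changes.
4. **Gene-set enrichment** — weighted Kolmogorov-Smirnov enrichment scores
   with a gene-set permutation null, reporting ES, NES, nominal p, FDR q
   and FWER.
5. **IHC quantification** — Mahalanobis-distance color segmentation of RGB
   micrographs against a fitted reference stain distribution, thresholded
   at a chi-square(3) quantile.

A seeded generator family (`simulation_config()` + `simulate_*()`)
produces inputs with the exact statistical structure each stage assumes,
so every estimator is tested against planted ground truth without any data
download.

## Worked example: repopulating frequency after parity

The packaged fixture carries the cleared-fat-pad transplantation tables
for basal stem/progenitor cells from age-matched virgin and parous donors,
under three outgrowth-scoring stringencies (c: ≥25% of fat pad filled,
d: ≥10%, e: ≥3%).

```r
library(paritykit)
tabs <- parity_transplant_tables()

fit_single_hit(tabs$virgin_c)
#> Single-hit repopulating frequency: virgin_c
#>   1/507  (95% CI 1/838 - 1/306)
#>   f_hat = 1.974e-03, SE(log f) = 0.2567, logLik = -15.597

fit_single_hit(tabs$parous_c)
#> Single-hit repopulating frequency: parous_c
#>   1/2468  (95% CI 1/5511 - 1/1105)
#>   f_hat = 4.052e-04, SE(log f) = 0.4099, logLik = -15.826

compare_frequencies(tabs$virgin_c, tabs$parous_c)
#> Frequency comparison (virgin_c vs parous_c): chi2 = 12.665, df = 1, p = 0.0003725
```

Read: in virgin donors about 1 cell in 507 is a repopulating unit; after
parity that drops about five-fold to 1 in 2468, and the likelihood-ratio
test puts p ≈ 4e-4 on the difference. Under the permissive rudimentary
scoring the difference is not significant
(`compare_frequencies(tabs$virgin_d, tabs$parous_e)` gives p ≈ 0.076):
parity reduces the cells' proliferative output more than their ability to
engraft at all.

The same stages run end to end from one config:

```r
report <- run_pipeline(list(
  seed = 7,
  simulation = list(n_genes = 2000, n_motifs = 20),
  stages = list(lda = list(),                 # packaged tables
                de = list(simulate = TRUE),
                mara = list(simulate = TRUE, lambda = 1),
                gsea = list(simulate = TRUE, n_perm = 500),
                ihc = list(simulate = TRUE))))
```

`inst/scripts/paritykit-pipeline.R` is a thin command-line wrapper:
`Rscript inst/scripts/paritykit-pipeline.R config.yaml output_dir`.

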