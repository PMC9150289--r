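# concur

Integration of copy-number variation (CNV) and gene-expression profiles to
discover **concurrent genes** — genes whose DNA dosage and transcription
change coherently — and to build prognostic models from them.

Tumours with chromosomal instability carry recurrent gains and losses whose
clinical meaning is hard to read from DNA alone. A gene whose expression
tracks its own copy number is a natural candidate for a functionally
relevant, dosage-driven driver, and a panel of such genes can carry
prognostic information. `concur` implements the full desk-side workflow for
this idea on paired SNP-array / expression cohorts:

1. **Segmentation and calling.** Per-sample log-ratio profiles are
   segmented by circular binary segmentation (arc-maximal two-sample
   statistic, within-segment permutation reference, accept level
   α = 0.01 with 1000 permutations), smoothed for singleton outliers,
   post-processed by a MergeLevels step, and called into five states
   against per-array MAD thresholds: amplification above `1·MAD`, gain
   above `0.5·MAD`, and symmetrically for deletions (strict inequalities).
2. **Recurrent regions.** GISTIC-style per-marker G-scores
   `G_gain(m) = Σ_s max(x_sm − θ, 0)` with a resampled null (per-sample
   marker permutation), Benjamini-Hochberg q-values, maximal significant
   runs, and gene-set enrichment in those regions by random sampling.
3. **Concurrency.** Gene-centric CNV (mean log ratio of markers inside
   each gene) is correlated with expression per gene (Spearman, t
   approximation). Correlations from two discovery cohorts of very unequal
   size are combined by Fisher's z:
   `Z_r = arctanh(r)`, `V(Z_r) = 1/(n−3)`,
   `Z̄ = ((n1−3)z1 + (n2−3)z2)/(n1+n2−6)`, `r̄ = tanh(Z̄)`,
   `V(Z̄) = 1/(n1+n2−6)`; the universal concurrent set is filtered at
   α = 10⁻³ on the combined p.
4. **Prognostic modelling.** Supervised principal-component survival
   model: univariate Cox screen at α = 0.001, PC1 of the standardized
   selected genes (the "supergene"), an oriented prognostic index,
   percentile risk groups (50th/75th), nested leave-one-out
   cross-validation, log-rank testing, and IPCW time-dependent AUC at a
   landmark time.
5. **Class prediction.** For dichotomous outcomes: pooled t filter, a
   global multivariate permutation test, and six LOOCV classifiers
   (compound covariate, Bayesian compound covariate with posterior CV-AUC,
   diagonal LDA, 1-/3-nearest-neighbour, nearest centroid, linear SVM) with
   ≥1000-permutation p-values.
6. **Synthetic cohorts.** A generator with full ground truth (segments,
   concurrent genes, signature genes, hazards) so every stage has
   parameter-recovery tests without any external download.

## Worked example

```r
library(concur)

cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 80,
                  n_genes = 40, seg_event_rate = 2, seg_mean_length = 25,
                  marker_noise_sd = 0.12, concurrent_fraction = 0.3,
                  target_rho = 0.7, signature_size = 8,
                  log_hazard_coef = 1.2, censoring_rate = 0.3,
                  logistic_slope = 2)
rep <- run_pipeline(pipeline_config(sim = cfg, cohort_sizes = c(12L, 40L),
                                    cbs_n_perm = 200, gistic_n_perm = 200,
                                    cohort_alpha = 0.05, filter_alpha = 0.01,
                                    seed = 91))
rep
#> Concurrent-gene pipeline report
#>   gene funnel:
#>     genes_simulated        40
#>     genes_tested           40
#>     concurrent_cohort1     6
#>     concurrent_cohort2     14
#>     universal_concurrent   10
#>     cox_selected           4
#>   CV log-rank: chi2 = 13.103, p = 0.0002948
#>   landmark AUC (t = 65.8): 0.829
#>   LOOCV bcc misclassification: 0.300
#>   CV-AUC: 0.790
```

The funnel mirrors the filtering cascade: of 40 simulated genes, 6 pass
the per-cohort concurrency screen in the 12-sample cohort and 14 in the
40-sample cohort, 10 form the universal concurrent set from the combined
correlation, and 4 survive the Cox screen to form the supergene. The
cross-validated risk groups separate survival (log-rank p ≈ 3e-4), the
prognostic index discriminates events at the landmark (AUC 0.83), and the
Bayesian compound covariate classifies the dichotomous outcome with CV-AUC
0.79.

A fitted model is a first-class object:

```r
co  <- simulate_cohort(cfg)
fit <- fit_risk_model(co$expression, co$survival, alpha = 0.01)
print(fit); coef(fit); predict(fit, co$expression)
```

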