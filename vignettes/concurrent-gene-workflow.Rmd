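---
title: "Concurrent-gene discovery and prognostic modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concurrent-gene discovery and prognostic modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concur)
```

## The model

`concur` operationalizes a simple biological hypothesis: in chromosomally
unstable tumours, a gene whose transcript abundance follows its own DNA
copy number is more likely to be a functional participant in the aberration
than a passenger. The workflow therefore measures, per gene, the
association between a *gene-centric copy-number value* (the mean
log-intensity ratio of the markers falling inside the gene body) and the
gene's expression across paired samples, and carries the surviving genes
into survival and classification models.

The pipeline has four statistical layers:

**Segmentation and calling.** A sample's marker-level log-ratio profile is
assumed piecewise constant plus noise. Change points are found by circular
binary segmentation: each current segment is bent into a circle, the arc
maximizing the standardized two-sample difference between arc and
complement is the candidate split, and it is accepted when its
within-segment permutation p-value is at most α (default 0.01, 1000
permutations). Splitting recurses until no further split is accepted.
Segment means are arithmetic means of member markers, so on noiseless
piecewise-constant input the generating partition is recovered exactly.
Singleton outliers (a point more than 4 estimated SDs from *both*
neighbours) are shrunk to 2 SDs from the nearer neighbour before
segmentation; a MergeLevels pass then repeatedly merges the genome-wide
pair of segment levels whose member markers a Wilcoxon rank-sum test
cannot distinguish (p > 0.05), so segmentation noise does not inflate the
number of copy-number levels. Five-state calls compare each segment mean
with the array's own noise scale, the unscaled median absolute deviation
of its log ratios: strictly above 1·MAD is amplification, above 0.5·MAD a
gain, symmetrically for losses. Strictness at the boundary matters for
reproducibility and is pinned by tests; a mean exactly at a threshold
takes the lower-magnitude state.

**Recurrent aberrations.** Across samples, each marker accumulates an
amplitude-over-threshold score `G_gain(m) = Σ_s max(x_sm − θ, 0)` (θ =
0.1, configurable; `G_loss` symmetric). The null redistributes each
sample's values across the genome independently and pools all resampled
scores per direction; a marker's p is the pooled-null exceedance fraction.
We deliberately use the pooled per-marker null rather than a
maximum-statistic null: the pooled null is calibrated (≈5% of markers at
p < 0.05 on signal-free data), and multiplicity is handled by
Benjamini-Hochberg q-values with significant regions defined as maximal
runs at q < 0.25. Gene-set enrichment in those regions uses equal-size
random gene draws with the add-one empirical p, which bounds p below by
1/(1+B) and keeps it positive.

**Concurrency and meta-combination.** Expression platforms are reduced to
one row per gene by keeping the probe with the largest IQR (ties:
lexicographically smallest probe id), and each dataset is median-centred
gene-wise before any cross-dataset modelling. Per gene, the Spearman
correlation r between gene-centric CNV and expression is tested with the
t approximation on n − 2 df; genes with fewer than 4 complete pairs or
constant input are flagged undefined rather than zero-filled. Two
discovery cohorts are combined on the Fisher-z scale with weights n − 3:

$$\bar Z = \frac{(n_1-3)z_1 + (n_2-3)z_2}{n_1+n_2-6},\qquad
  \bar r = \tanh(\bar Z),\qquad V(\bar Z) = \frac{1}{n_1+n_2-6}.$$

The combined two-sided p refers $\bar Z/\sqrt{V(\bar Z)}$ to the standard
normal — the variance expressions fix the reference implicitly, and the
normal is the standard companion of the z transform. The universal
concurrent set is `p_combined < 0.001`; per-cohort screens at 0.05 and
0.01 are exposed because both conventions are in common use. Deriving the
universal set from the *combined* statistic rather than intersecting
per-cohort lists lets a large cohort rescue genes underpowered in a small
one, which is the point of the weighting. Concurrency is treated as
sign-agnostic in filtering (two-sided p); the sign is reported for
inspection since biology expects positive dosage effects.

**Prognostic modelling.** The survival model is supervised principal
component regression: genes are screened by a univariate Cox
proportional-hazards score test at α = 0.001, the selected genes are
standardized and their first right-singular vector (unit norm) defines the
supergene; a sample's prognostic index is the loading-weighted sum of its
standardized values. Because a principal component's sign is arbitrary,
loadings are flipped when the index's own Cox association is negative, so
larger index always means larger estimated hazard. Risk groups split at a
percentile of the training indices (50th by default; 75th for
high-censoring sensitivity analyses), with ties at the threshold going to
low risk. Evaluation uses nested leave-one-out cross-validation — the
filter, loadings, orientation *and* threshold are refit on every fold, so
the held-out sample can never influence its own label (a property the
tests assert directly by perturbing held-out outcomes) — followed by a
two-group log-rank test and a cumulative-case/dynamic-control
time-dependent AUC with inverse-probability-of-censoring weights from the
Kaplan-Meier estimate of the censoring distribution. For dichotomous
outcomes, a pooled-variance t screen at 0.001 feeds six classifiers
(compound covariate, Bayesian compound covariate, diagonal LDA, 1- and
3-nearest-neighbour on fold-standardized genes, nearest centroid, linear
SVM at cost 1), all refit inside each LOOCV fold; significance comes from
rerunning the whole cross-validation under label permutations (add-one p,
conventionally ≥1000 permutations). The "neural network" reading of the
NN columns in some published tables is treated as an erratum: the methods
convention here is k-nearest-neighbours, as the accompanying text
describes.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` (CBS) | 0.01 | permutation level to accept a change point |
| `n_perm` (CBS) | 1000 | within-segment permutations |
| `k`, `offset` (smoothing) | 4, 2 | outlier detection / shrink distances in SD units |
| `merge_p` | 0.05 | rank-sum p above which two levels merge |
| `high_mult`, `low_mult` | 1.0, 0.5 | MAD multipliers for high-/low-level calls |
| `theta_gain/theta_loss` | ±0.1 | G-score amplitude thresholds |
| `q_cut` | 0.25 | q-value defining significant recurrent regions |
| cohort / universal alphas | 0.01 / 0.001 | concurrency screen levels |
| `alpha` (Cox, t) | 0.001 | supervised screening level |
| `percentile` | 50 | risk-group threshold (75 = conservative variant) |

Smoothing constants, the MergeLevels test, the unscaled MAD (a 1.4826
consistency factor is available behind a flag), and the GISTIC θ/q
settings follow the conventional implementations of each method; all are
configurable rather than baked in.

## The synthetic-data generator

Every downstream stage is tested against cohorts with known ground truth.
The generator emulates: segmental CNV (Poisson event counts per
chromosome, geometric lengths, later-event-wins overlap, equiprobable-ish
states with rarer high-level events) with i.i.d. Gaussian marker noise; a
chosen fraction of genes with a linear dosage→expression effect;
survival times that are exponential with log-hazard proportional to the
standardized mean expression of a signature gene set; independent
Uniform(0, c) censoring with c solved numerically for a target censoring
fraction (matching the high, variable censoring typical of public
survival cohorts); dichotomous labels through a logistic link on the same
score; and multiple cohorts sharing one truth with independent noise and
optional redundant probes (the informative probe has the largest IQR).
Because the realized gene-level CNV variance differs per gene, the
`target_rho` option sizes the dosage slope per gene so concurrent genes
have a common generating correlation — this is how "true ρ ≈ 0.6" study
conditions are expressed.

What the generator does *not* emulate: GC waves and batch effects,
B-allele frequencies, tumour purity/ploidy mixtures, mutation calls, or
platform-specific probe behaviour. Passing recovery tests therefore shows
the estimators are correct and calibrated under the stated generating
model, not that real arrays meet those assumptions.

A single integer seed drives everything; each operation derives a
deterministic substream from it, so partial re-runs and full pipelines are
bit-identical under a repeated seed.

## Numerical and design choices

- The CBS arc statistic uses a constant-variance standardization; the
  permutation reference makes the scale irrelevant and avoids unstable
  per-arc variance estimates on short segments. Permutation testing stops
  early once enough exceedances force the split to be rejected, which is
  what makes full-permutation CBS affordable at these profile sizes.
- The Cox screen is a vectorized score test with Breslow risk sets;
  simulated survival times are continuous, where Breslow and Efron
  coincide, and the test is cross-checked against `survival::coxph`'s
  score test. A Wald variant via `coxph` sits behind a flag.
- Folds of the survival LOOCV whose filter selects nothing fall back to
  the per-sample mean expression thresholded at the fold's percentile;
  classification folds fall back to the single smallest-p gene. Both
  fallbacks are counted and reported.
- Cross-validated risk thresholds are recomputed inside each fold rather
  than fixed on the full data; the alternative leaks the full-data index
  distribution. Both behaviours exist; per-fold is the default.
- The landmark time for the time-dependent AUC defaults to the median
  follow-up among censored samples and is otherwise a user input — it is
  a property of each dataset, not a constant of the method.
- Empirical p-values throughout use the add-one correction
  `(1 + #null ≥ obs)/(1 + B)`.
- Degenerate inputs are flagged, never silently imputed: genes covering
  no marker are missing (not zero), constant covariates are undefined in
  screens, and a zero MAD degrades calling with an explicit warning.

## Problem sizes used in the checks

The test-suite and the acceptance script run at desk scale, chosen so the
whole suite completes in minutes while each check retains power: CBS
breakpoint recovery uses 100 replicate 100-marker profiles (step +1.0,
noise SD 0.2); concurrency recovery uses the two-cohort design with
n = 31 and n = 345, 600 genes of which 100 carry a dosage effect sized
for ρ ≈ 0.6; the recurrent-region check injects a +0.8 gain into 60% of
50 samples over 31 of 400 markers with 1000 resamplings; the survival
model runs on a planted-signature cohort of n = 200 plus 100 null
replicates of n = 50; classification uses a 3-SD effect with 20 + 20
samples and 199 label permutations. On null data a single label
permutation's LOOCV accuracy is highly variable (the permutation may
partially align with planted structure), so calibration is asserted on
the mean over 30 permutations.

## Known limitations

- Segmentation is univariate per sample; no joint multi-sample
  segmentation or allele-specific copy number.
- The recurrent-region scan has no peel-off step, so one very strong
  region can shade the q-values of weaker ones.
- The IPCW AUC assumes censoring independent of the index; informative
  censoring biases it.
- Log-rank on cross-validated risk groups is known to be slightly
  anti-conservative when screening is aggressive relative to cohort size;
  the null-calibration test bounds this at the generator's conditions.
- Gene-symbol harmonization is by static maps supplied by the user; no
  live annotation services are consulted.
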