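---
title: "Quantifying intertumor radiomic heterogeneity with mirv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intertumor radiomic heterogeneity with mirv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirv)
```

## The problem

In metastatic cancer, different lesions within the same patient can carry
different phenotypes, and that *intertumor* heterogeneity plausibly drives
mixed treatment responses: one lesion shrinks while another grows. This
package quantifies intertumor heterogeneity from routinely acquired CT
imaging. It consumes a lesion-level table of radiomic features (as written
by any standard extractor) and produces a per-patient heterogeneity score,
response summaries, and the downstream association and survival analyses
used to evaluate the score as a biomarker.

## The score

For a patient with lesions $L_1, \dots, L_n$ represented by radiomic
feature vectors, the package evaluates every unordered pair and summarizes
the patient by the *most divergent* pair:

$$\mathrm{maxDistance} = \max_{i,j}\; d_{\mathrm{Euclidean}}(L_i, L_j),
\qquad
\mathrm{maxDissimilarity} = \max_{i,j}\; 1 - \cos(L_i, L_j).$$

Euclidean distance responds to both the magnitude and the pattern of
feature differences; cosine dissimilarity (range $[0, 2]$) responds only to
the pattern, being invariant to positive rescaling of either lesion. The
two are complementary: a pair of lesions with proportional but differently
scaled profiles has large distance and zero dissimilarity.

Both scores are undefined for single-lesion patients, which is why the
ingestion stage filters to patients with at least two contoured lesions.
Arg-max ties are broken by the lexicographically smallest lesion-id pair so
results are reproducible.

### Standardization

Radiomic features span wildly different numeric scales (shape volumes in
mm^3 next to texture entropies of order 1), so the package z-scores each
feature over all lesions in the cohort before computing either metric.
Without this, the largest-scale feature dominates the Euclidean metric and
contaminates the cosine angle. Standardization is a documented default, not
a hidden step: `cohort_mirv(..., standardize = FALSE)` accepts pre-scaled
input. Scoring a standardized matrix is invariant to jointly permuting
lesions and, for the cosine score, to positively rescaling any lesion
before standardization.

## Feature reduction

The score is computed on a reduced feature set produced by three filters
applied in a fixed order:

1. **Variance filter** — drop features with sample variance *strictly
   below* the median variance across features. The median is recomputed on
   whatever matrix the filter receives, so the filter always removes about
   half of a matrix with distinct variances; it is therefore *not*
   idempotent in general (on an equal-variance matrix it removes nothing).
2. **Volume filter** — drop features with absolute Spearman correlation
   with baseline lesion volume strictly above 0.1, pooling all lesions of
   all patients. This removes volume surrogates: many classical radiomic
   features predict outcomes only because they track tumor size.
3. **Redundancy filter** — scan features in column order and drop any
   feature whose absolute Spearman correlation with an already-retained
   earlier feature strictly exceeds 0.7. Greedy keep-first scanning is
   deterministic and order-stable; reorder columns to change priority. The
   retained set has all pairwise $|\rho| \le 0.7$, and reapplying the
   filter changes nothing.

Thresholds are strict inequalities by design, so features sitting exactly
at a cutoff are retained. Correlations use average ranks for ties. The
0.1 volume threshold is tight: on small cohorts (a few dozen lesions) the
sampling noise of the rank correlation is itself near 0.1, and
volume-independent features will be discarded at an appreciable rate. The
filters are faithful to their definitions at any size, but the reduced set
is only stable for cohorts of a few hundred lesions or more. If every
feature is removed, `reduce_features()` raises an explicit empty-set error
rather than returning a degenerate matrix.

## Response metrics

Per lesion, volumetric response is the percent change
$100\,(V_1 - V_0)/V_0$ between baseline and first follow-up volumes. Per
patient the package reports the *range* of lesion changes (max minus min; 0
for a single evaluable lesion) and the binary tumor-specific response
classification (TSRC). Lesions without a follow-up contour are dropped from
the response computation with a warning; a patient with no evaluable lesion
falls out of the volumetric-response subset. Baseline-volume controls
(range, sample SD, total, in mm^3) use all lesions.

The 33% TSRC rule can be read in two directions, and the package implements
both as an explicit, logged run parameter:

* `reduction` (default): a lesion responds iff it shrank by at least the
  threshold ($\Delta V \le -33\%$); Complete Tumor Response requires every
  lesion to respond.
* `growth`: a lesion fails iff it grew beyond the threshold
  ($\Delta V > +33\%$); Complete requires no failing lesion.

The two conventions differ exactly for patients whose lesions all stayed
within $(-33\%, +33\%]$. The default follows the reading in which Complete
means uniform shrinkage, which matches how the classification is used as a
response-consistency endpoint; choosing it silently would hide a genuine
ambiguity, which is why the convention is carried in the run manifest.

## Association analysis

All association tests are Spearman rank correlations (average ranks for
ties; binary variables enter as 0/1 codings, making the statistic a signed
rank-biserial). The two-sided p-value uses the standard large-sample t
approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n - 2$ degrees of
freedom. Each subset matrix (volumetric: scores, response range, TSRC,
baseline controls; liquid biopsy: scores, pre/post ctDNA, baseline
controls) forms one Benjamini–Hochberg FDR family, diagonal excluded;
cells with adjusted values above 0.05 are flagged as not-displayed,
mirroring the blank-cell convention of correlation heat matrices.
Undefined correlations (a constant input) are flagged and excluded from
the family rather than silently coerced.

## Survival analysis

The Cox proportional-hazards model enters the heterogeneity score
untransformed and continuous, adjusted for histology, age, performance
status, RECIST category and (when available) total baseline volume, with
an optional score-by-histology interaction. Ties use Efron's method.
Reference levels are histology "Other" and RECIST "SD"; both are
configurable and recorded. Non-convergence or separation (e.g. a sparse
covariate level) raises a diagnostic error rather than returning an
unstable fit — on small cohorts the remedy is to drop or merge sparse
covariates, not to trust a diverging coefficient.

Kaplan–Meier subgroup comparisons dichotomize the score at the
within-stratum median (ties to "low"; cutpoint logged) because no
principled external cutpoint exists for these scores yet. Subgroups below
20 patients (configurable) are skipped. Per-stratum log-rank p-values are
exploratory and unadjusted for the number of strata; the output says so.

## The synthetic cohort generator

Restricted trial data cannot ship with a package, so `generate_cohort()`
emulates the structure of a multi-metastatic soft-tissue sarcoma cohort
with fully known ground truth:

* **Lesion counts** from a truncated distribution on $\{2,\dots,6\}$ with
  probabilities $(0.55, 0.25, 0.12, 0.05, 0.03)$, giving median 2 and
  IQR $[2, 3]$ as in the trial population the defaults emulate.
* **Histology mixture** 41% leiomyosarcoma, 14% liposarcoma, 12% UPS, 33%
  other.
* **Heterogeneity**: each patient draws $\sigma_p \sim U(0.1, 2)$ and a
  phenotype center $\mu_p$; lesion signal vectors are
  $\mu_p + \sigma_p\,\varepsilon$ with standard-normal noise. Signal
  features are emitted at geometric scales ($3^{j-1}$) to mimic the scale
  spread of real radiomic features, and are independent of lesion volume
  by construction.
* **Nuisance features**: log- and square-root-volume proxies, a
  near-constant column, and verbatim duplicates of leading signal
  features — exactly the targets of the three reduction filters.
* **Response**: a lesion responds according to a steep logistic
  (intercept 4, slope 8) in its value on a response-sensitivity axis (the
  first signal coordinate). The between-patient center SD on that axis is
  deliberately small (0.2 vs 1 elsewhere): mixed response then arises from
  *within-patient* lesion dispersion — the heterogeneity of interest —
  rather than from between-patient baseline differences. A shallow slope
  or a large center SD makes lesion response an almost independent coin
  flip patient by patient and erases the heterogeneity–response link the
  generator exists to emulate. Responders shrink by $N(-50, 10)$ percent,
  non-responders change by $N(+10, 15)$ percent, so the 33% rule separates
  the classes cleanly.
* **ctDNA** positivity is logistic in centered log total tumor volume
  (burden) plus, post-treatment, $0.8\,\sigma_p$.
* **Survival** is exponential (baseline hazard 0.46/year, matching a
  median OS near 1.5 years) with the hazard multiplied by
  $\exp(0.8\,\sigma_p)$ *only* in leiomyosarcoma, plus independent
  exponential censoring (0.18/year) and a 6-year horizon — an observed
  event fraction near 72%.

All randomness flows from one seed through per-patient substreams, so the
same (config, seed) pair reproduces the tables bit-identically and adding
patients never perturbs earlier ones.

### What the generator does and does not emulate

It reproduces cohort structure (lesion counts, subtype mixture, censoring),
scale heterogeneity across features, volume-surrogate and redundant
features, heterogeneity-linked mixed response, and a subtype-confined
hazard effect. It does not emulate scanner or protocol batch effects,
spatially correlated texture features, non-monotone volume relationships,
or informative censoring. Tests passing on synthetic cohorts demonstrate
that the machinery recovers planted signals under the stated model; they do
not certify effect sizes on real imaging data.

### A caveat specific to max statistics

The maximum over $\binom{n}{2}$ pairs grows stochastically with the number
of lesions, and an all-lesion response conjunction (TSRC) becomes harder
with more lesions. Patient lesion count therefore confounds score–response
associations even when the generative link is switched off. This is a real
property of max-based heterogeneity scores, not an implementation artifact;
analyses on real cohorts should consider adjusting for lesion count. The
package's null-calibration checks hold lesion count fixed to isolate the
generative null.

## Numerical choices and problem sizes

Scores are computed on `dist()`/cross-product machinery and verified
against exhaustive pair scans to $10^{-10}$; cosine values are clamped to
$[0, 2]$ against floating-point drift. Zero-norm lesion vectors and
zero-variance columns are errors, not silent NaNs. The test suite works at
deliberately modest sizes — cohorts of 60–400 patients, 100-replicate null
studies, 500-replicate log-rank calibrations — chosen so the full suite
runs in about a minute while keeping every check at the scale where its
asymptotic approximations are already honest.

## Reproducibility

`run_pipeline()` writes every stage output as CSV plus a JSON manifest
recording all thresholds, conventions, tie-handling, reference levels and
the seed; rerunning an identical configuration reproduces every output
byte-for-byte. `scripts/acceptance.R` regenerates the package's headline
quantities (heterogeneity recovery, score–response association, subgroup
survival effect) from scratch at any seed.
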