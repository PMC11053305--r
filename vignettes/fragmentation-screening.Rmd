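---
title: "cfDNA fragmentation profiling for cancer screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cfDNA fragmentation profiling for cancer screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(fragscreen)
```

# The measurement

Plasma cfDNA is nucleosome-protected, so its fragment lengths peak near
167 nt. Tumour-derived cfDNA is systematically shorter, enriching the
100–167 nt range, and this enrichment varies regionally along the genome.
`fragscreen` quantifies it as the per-bin **short-fragment proportion**:
within each ~5-Mb analysis window, the number of fragments with length in
the inclusive window [100, 167] divided by the number of fragments of all
retained sizes. Because the statistic is a within-bin ratio, it absorbs
most of the coverage fluctuation of shallow (~1×) whole-genome sequencing;
no GC correction is applied, reflecting the low GC bias of shallow,
UMI-deduplicated libraries.

Assumptions worth keeping in view:

* a *fragment* is the outer span of a properly paired read pair; single-end
  data cannot be used;
* duplicate removal happened upstream (an optional coordinate-duplicate
  filter exists but is off by default);
* the 100-kb source-bin list already excludes low-mappability and
  blacklisted regions — the package consumes the bin list, it does not
  derive one. An optional exclusion BED drops source bins overlapped by
  more than half their width.

# Genome binning

Analysis windows are built from arm-annotated, non-overlapping 100-kb bins
on the non-acrocentric autosome arms. The merge rule is deterministic:
within each arm, consecutive source bins are grouped greedily into blocks
of `floor(targetSpan / sourceSpan)` bins (50 at the 5-Mb default); a
trailing block keeps its own window when it contains at least half that
many source bins and is otherwise absorbed into the previous window, so an
arm yields windows of 25–74 source bins and no window ever crosses an arm
boundary. Labels combine the arm with a single *global* sequential index
over the coordinate-sorted genome (`1q_1`, …), matching the published
labelling style; note that published labelling starts at `1q`, which
suggests an upstream arm-inclusion or ordering convention not derivable
from the bin list itself — the package simply follows genomic order of the
bins it is given, and reproducing a specific published 504-window layout
requires the corresponding upstream 100-kb list as input.

Fragments are assigned to windows by their midpoint,
`start + floor(length/2)` in 0-based coordinates, under the half-open
`[start, end)` convention. The midpoint rule makes boundary-spanning
fragments unambiguous; a midpoint exactly on a window start belongs to that
window.

# Profiling parameters

| parameter | default | meaning |
|---|---|---|
| `mapqMin` | 30 | minimum mapping quality; below it a fragment is dropped |
| `sizeLo`, `sizeHi` | 100, 167 nt | inclusive short-fragment window ("100–167 nt" read inclusively on both ends) |
| `lengthCap` | 1000 nt | fragments longer than this are treated as chimeric artifacts and excluded from both counts |
| `minFragments` | 5e6 | depth QC: samples with fewer retained fragments fail QC (scale down alongside simulated depths) |

Zero-coverage bins get a missing proportion; before centring or modeling
they are imputed with the sample's mean proportion, which is neutral under
row-centring and inert for the penalized fit. Row-centring (subtracting
each sample's mean proportion) is used for display and clustering;
the model consumes raw proportions by default (`centered = TRUE` is
available) because the penalized fit standardizes features internally and
published descriptions mention centring only for figures.

Clustering uses Euclidean distance with Ward ("ward.D2") linkage on
centred profiles — neither choice is dictated by the science, both are the
field's common defaults, and both are arguments of `clusterSamples()`.

# The detection model

`trainFragModel()` fits an L1-penalized logistic regression (glmnet) of
case status on the proportion matrix. Design choices, each configurable:

* **Score** — the predicted case probability, so scores live in [0, 1] and
  a probability-like cutoff is meaningful.
* **Penalty selection** — "5-fold cross-validation by resampling" is
  realized as repeated stratified 5-fold CV: `nRepeats` (default 5)
  independent fold assignments, the binomial-deviance CV curves averaged
  over repeats on a common lambda grid, and the minimum-deviance lambda
  selected. The minimum rule (not 1-SE) is used because the reference
  workflow reports an "optimal" penalty; ties go to the larger (sparser)
  lambda.
* **Determinism** — folds derive from `seed` after sorting samples by id,
  so training is invariant to input row order.
* **Importance** — bin *i* contributes
  `|beta_i * sd_i| / sum_j |beta_j * sd_j| * 100` percent, i.e. shares of
  the standardized coefficients. Published reports do not state their
  importance formula; this one is scale-free and sums to 100 by
  construction.
* **Cutoff** — by default the training-set Youden-optimal threshold, with
  candidate thresholds at midpoints between consecutive observed scores
  (so a cutoff inside a wide class gap lands mid-gap rather than on an
  extreme training score). For reproduction of a published operating
  point, pass the published constant (e.g. `cutoff = 0.494`) — the package
  treats such a value as a given, not something it re-derives.
  Classification uses the `>=` convention: a score equal to the cutoff is
  positive.

Subjects with several samples in one time-to-diagnosis window are
aggregated by the arithmetic mean of their sample scores *before*
classification, for cases and controls alike.

# Screening evaluation

Time windows in years before diagnosis are `(lower, upper]` intervals —
`0–1`, `1–2`, `2–3`, `3–4`, `>4` by default — so a sample exactly on a
boundary joins the narrower, closer-to-diagnosis window, and a sample
taken on the diagnosis date counts as `0–1y`.

Confidence intervals for sensitivities and specificities are
Clopper–Pearson exact intervals (computed from beta quantiles, which solve
the defining binomial tail equalities); the exact method is the default
because published interval endpoints for 44/50 (75.7–95.5%) match the
exact and not the Wilson interval, which is available as an option. AUC is
the Mann–Whitney concordance probability with ties counted 1/2, and its
interval uses the DeLong placement-value variance, truncated to [0, 1].

PPV and NPV follow Bayes' rule from (sensitivity, specificity,
prevalence), with the prevalence taken as the annual incidence rate — an
approximation of the 1-year risk that is excellent for rare outcomes
(at 382/100,000 the error is below 1%). Per-window PPV/NPV intervals are
obtained by pushing the sensitivity CI endpoints through the same formula
at fixed specificity and prevalence; they are labelled as
sensitivity-propagated, since the exact published method for such
intervals is not stated.

# Prognosis

Survival time runs from diagnosis to death, administratively censored at
36 months (`capFollowup`). Scores are dichotomized at the case median with
the `>=` convention, so an odd cohort splits (n+1)/2 high vs (n-1)/2 low.
Group comparisons use the two-sided Wilcoxon rank-sum test (exact for
groups of ≤ 20 without ties). The Kaplan–Meier median is the earliest time
with S(t) ≤ 0.5. The Cox fit uses the Efron tie correction (the data are
month-scale and tied; the reference analysis does not state its tie
method) and enters the score as the median-dichotomized group by default —
consistent with the stratified survival display — while a continuous score
column can be supplied instead via the `covariates` data frame.

# The synthetic cohort generator

The generator exists so that every stage — file readers included — can be
exercised end-to-end with data whose truth is known. It emulates:

* per-bin baseline short-fragment proportions `p0_b ~ N(0.2, 0.02)`
  (truncated to [0.01, 0.9]). Published work reports enrichment *ratios*
  but no absolute baseline; 0.2 is a realistic plasma value and is
  recorded per-cohort in the truth object;
* a set of tumour-affected bins with enrichment ratios drawn from the
  empirically observed 1.50–2.38 range (or set explicitly);
* tumour signal growth: a sample collected *t* months before diagnosis has
  effective tumour fraction `tau * 2^(-t / doublingTime)` with a
  4.6-month default doubling time — published as an interpretive argument
  for why only near-diagnosis samples are detectable, made an explicit,
  configurable assumption here. Affected-bin probabilities become
  `p0 * (1 + (r - 1) * tauEff)`, so the expected case/control ratio is `r`
  at full effective tumour fraction;
* counts: totals multinomial over bins, short counts binomial — i.e.
  sampling noise only, no overdispersion beyond the Gamma-Poisson draw of
  the per-sample total (CV 5% by default);
* fragment-level output: short-class lengths uniform on [100, 167], the
  remainder from the upper shoulder of the mononucleosome peak (normal,
  mean 167, sd 10, truncated to ≥ 168). The truncation at 168 rather than
  the peak's left flank is a deliberate idealization: it keeps the
  "long" class strictly outside the short window so that programmed counts
  are exactly recoverable from the emitted BED, which is what makes the
  round-trip test sharp. Decoy fragments with out-of-class lengths and
  sub-threshold MAPQ exercise the filters;
* survival linked to the latent signal: case subjects above the median
  subject-level tumour fraction form the high-burden group, whose
  exponential hazard is the baseline (median 30 months) times a hazard
  ratio of 2.41, then censored at 36 months. Covariates (age, sex, BCLC,
  AFP) are generated independent of survival so that adjusted hazard-ratio
  recovery has a known target.

What it does **not** emulate — and what passing tests therefore do not
show about real data: GC and mappability bias, copy-number alterations
(which in real tumours couple coverage and fragmentation), between-sample
batch effects, library-preparation variation in the size distribution,
correlated bins, or biologically realistic AFP/BCLC associations with the
score. Simulated recovery demonstrates the *pipeline's* correctness under
its own model, not clinical performance.

# Problem sizes and determinism

The test suite and the acceptance script run simulations at desk scale,
chosen as the smallest sizes at which the statistical claims are stable:
cohorts of 30–60 cases/controls with 50 bins and 1e5 fragments per sample
for model recovery; 200 case subjects sampled in five longitudinal windows
for the sensitivity trend; 100 replicate cohorts of 400 cases for
hazard-ratio recovery; brute-force oracle comparisons at n ≤ 200. The
depth-QC threshold is scaled with the simulated depths (5e4 at 1e5
fragments per sample), standing in for the 5e6 threshold used at
production depth. Every stochastic step is seeded: a `cohortConfig` seed
fixes the cohort bytes exactly, and the training seed fixes fold
assignment, so identical seeds reproduce cohorts, model JSON and reports
bit-for-bit.

# Known limitations

* The package consumes a pre-filtered 100-kb bin list; it cannot recreate
  a published 504-window layout without that upstream input.
* Scores are logistic-model probabilities; they are calibrated only as
  well as the training cohort represents the deployment population —
  cutoff transfer across cohorts is an assumption, not a guarantee.
* PPV/NPV treat sensitivity and specificity as known constants; only the
  sensitivity's sampling uncertainty is propagated into the reported
  intervals.
* The Wilcoxon exact path is skipped in the presence of ties (normal
  approximation with tie correction is used), as in standard R practice.
* No competing risks, time-varying covariates, or landmark survival
  analyses.

```{r example, eval = FALSE}
# a compact end-to-end run
cfg <- cohortConfig(seed = 1, nCases = 30, nControls = 30, nBins = 50,
                    nArms = 5, fragmentsPerSample = 1e5,
                    enrichment = 2, tumorFraction = 0.5)
cohort <- makeCohort(cfg)
model <- trainFragModel(proportionMatrix(cohort$profiles),
                        cohort$metadata$label, seed = 1)
scores <- scoreSamples(model, proportionMatrix(cohort$profiles))
rocAuc(scores, cohort$metadata$label)
```
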