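# fragscreen

Genome-wide cell-free DNA (cfDNA) fragmentation profiling for liver-cancer
screening in R.

## The problem

Tumours shed DNA into blood plasma with a characteristically shortened
fragment-size distribution: where healthy cfDNA peaks at the ~167 nt
mononucleosome length, tumour-derived fragments are enriched in the
100–167 nt range. Aggregated over megabase-scale genomic windows, the
**short-fragment proportion**

```
p_b = (# fragments of 100–167 nt in bin b) / (# fragments of all sizes in bin b)
```

becomes a coverage-robust, genome-wide fragmentomic feature that separates
hepatocellular carcinoma (HCC) patients from HBV-seropositive controls in
shallow whole-genome sequencing — and, because HCC grows with a tumour
volume doubling time of only a few months, carries detectable signal mainly
in samples drawn shortly before clinical diagnosis. `fragscreen` implements
the full analysis chain for this design, for analysts evaluating
fragmentomics-based screening in high-risk cohorts:

- **Genome binning** — merge arm-annotated 100-kb bins into ~5-Mb analysis
  windows that never cross an arm boundary, labelled `1q_1 … 22q_504`;
  assign fragments to windows by midpoint.
- **Profiling** — fragment extraction from paired-end BAM or fragment BED
  (MAPQ ≥ 30), per-bin short-fragment proportions, a ≥ 5-million-fragment
  depth QC, row-centred visualization matrices, per-bin case/control
  ratios, hierarchical clustering.
- **Detection model** — L1-penalized (lasso) logistic regression on the
  samples × bins proportion matrix, with the penalty chosen by repeated
  stratified 5-fold cross-validation; probability-scale scores in [0, 1],
  standardized-coefficient importances, cutoff classification, and
  subject-level mean-score aggregation per time-to-diagnosis window.
- **Screening evaluation** — sensitivity/specificity with exact
  (Clopper–Pearson) confidence intervals, Mann–Whitney AUC with DeLong
  intervals, incidence rates per 100,000 person-years, and incidence-based
  PPV/NPV via Bayes' rule.
- **Prognosis** — Wilcoxon score comparisons across clinical groups,
  median-score dichotomization, Kaplan–Meier curves, (stratified) log-rank
  tests, and Cox proportional-hazards fits adjusted for age, sex, BCLC
  stage and AFP status, with follow-up capped at 36 months.
- **Synthetic cohorts** — a generator that emulates the statistical
  structure of such a study (nucleosome-peaked fragment sizes, per-bin
  enrichment ratios in the observed 1.50–2.38 range, tumour signal decaying
  exponentially with time before diagnosis at a 4.6-month doubling time,
  survival linked to tumour burden with hazard ratio 2.41), so the whole
  pipeline is testable without access to patient data.

Central containers follow Bioconductor idiom: bins are a `BinSet`
(a `GRanges` subclass), profiles a `FragProfileSet`
(a `RangedSummarizedExperiment` with `short`/`total`/`proportion` assays),
and the trained classifier a `FragModel` S4 object with JSON serialization.

## Worked example

Simulate a small discovery cohort (30 cases / 30 controls, 50 bins, five
bins enriched two-fold at tumour fraction 0.5, ~100,000 fragments per
sample), train the model, and score it:

```r
library(fragscreen)

cfg <- cohortConfig(seed = 42, nCases = 30, nControls = 30, nBins = 50,
                    nArms = 5, fragmentsPerSample = 1e5,
                    enrichment = 2, tumorFraction = 0.5)
cohort <- makeCohort(cfg)
model <- trainFragModel(proportionMatrix(cohort$profiles),
                        cohort$metadata$label, seed = 42)
model
#> FragModel: lasso logistic, 4 of 50 bins selected
#>   lambda = 0.0003717  cutoff = 0.4961
#>   top bins: 5q_46, 5q_50, 3q_24, 5q_47

round(featureImportance(model), 1)
#> 5q_46 5q_50 3q_24 5q_47
#>  47.0  38.7  13.2   1.1
cohort$truth$affected_bins
#> [1] "1q_5"  "2q_18" "3q_24" "5q_46" "5q_50"

scores <- scoreSamples(model, proportionMatrix(cohort$profiles))
rocAuc(scores, cohort$metadata$label)$auc
#> [1] 1
```

Three of the four selected bins are truly enriched (the planted bins
`3q_24`, `5q_46`, `5q_50`; importances are the bins' shares of the model's
standardized coefficients and sum to 100%), and training-set discrimination
is complete — at this signal strength the case and control score
distributions do not overlap. Screening arithmetic at a published-style
operating point (sensitivity 36.4%, specificity 88%, annual incidence
382/100,000 used as the 1-year risk):

```r
pv <- ppvNpv(0.364, 0.88, 0.00382)
sprintf("PPV %.2f%%, NPV %.2f%%", 100 * pv$ppv, 100 * pv$npv)
#> [1] "PPV 1.15%, NPV 99.72%"
```

A positive screen in such a rare-disease population is right only ~1% of
the time even with a good model — the central caveat for cfDNA-based
screening — while a negative screen is almost always right.

## Vignette

`vignettes/fragmentation-screening.Rmd` documents the model and its
assumptions, every tunable parameter, what the synthetic generator does and
does not emulate, and the numerical conventions (boundary handling,
tie-breaks, degenerate inputs).
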