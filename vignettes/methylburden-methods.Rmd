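---
title: "Promoter methylation burden: models, conventions and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter methylation burden: models, conventions and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MethylBurden)
```

# The problem

Array-based DNA methylation studies summarize each CpG site as a
&beta; value — the methylated fraction of signal, between 0 (unmethylated)
and 1 (fully methylated). Clinical questions, however, are usually posed at
the level of genes and gene programs: is a functional gene set (here, the
DNA-repair genes) unusually hypomethylated in a tumor type, and does the
fraction of those genes that a given patient has methylated — the
repair-gene promoter methylation burden, RPMB — predict outcome after
post-operative treatment?

MethylBurden implements that pipeline end to end: probe-level &beta; values
are aggregated into gene-level promoter methylation, each sample is scored
for its burden over a designated gene set, the set itself is tested for
hypomethylation against resampled null sets, and the burden groups are
carried into baseline contingency statistics, Kaplan–Meier / log-rank
comparison, univariate Cox models and a median-split subgroup forest.

# Promoter profile

A gene's promoter is the closed, 1-based interval from 1,000 bp upstream
of the transcription start site to 300 bp downstream of it
(`promoterWindow()`, defaults `upstream = 1000`, `downstream = 300`).
"Upstream" is measured against the direction of transcription, so
minus-strand windows flip: a minus-strand TSS at 10,000 has the window
[9,700, 11,000]. Strand-aware windows are the biologically standard
reading; because some published analyses are strand-naive, the
`ignoreStrand` flag reproduces the plus-strand-only variant. Window starts
are clipped at coordinate 1, and both endpoints are included when probes
are assigned (a probe exactly at either boundary belongs to the window).

A probe inside two overlapping promoter windows counts for both genes; no
unique-assignment step is applied. The gene's methylation value per sample
is the mean &beta; of its mapped probes, with missing probe measurements
excluded from the mean rather than imputed; a gene whose probes are all
missing in a sample is missing there and propagates as non-evaluable
downstream. A single-probe promoter simply inherits that probe's &beta;.

# Burden scoring

Gene-level methylation is binarized at a &beta; threshold of 0.1: a gene is
*methylated* when its value strictly exceeds 0.1 and *unmethylated* at or
below it (`binarizeMethylation()`). A sample's RPMB is the number of set
genes called methylated divided by the number of set genes *evaluable*
(non-missing) in that sample. Using the per-sample evaluable count as the
denominator, rather than the nominal set size, prevents missingness from
deflating the burden; set genes absent from the profile are dropped from
the set size with a logged count, and samples with less than 90% of set
genes evaluable (`minEvaluableFraction = 0.9`) are left unscored rather
than scored on a thin denominator.

Samples are split into low/high burden at the median RPMB. Ties at the
median go to *low*, consistent with the binarization rule's
"at-the-threshold means the lower state" convention; the split value is
recorded in the result so the assignment is reproducible.

# Gene-set hypomethylation testing

Testing operates on one summary value per gene — by default the mean of
the gene's methylation across samples (the median is available via
`summarizeGenes(stat = "median")`). The unit of comparison is therefore a
*set of genes*, matching the resampling design: `resamplingComparison()`
repeatedly draws, without replacement, a random set of non-target genes of
the same size as the target's overlap with the universe and applies an
unpaired Welch (unequal-variance) *t*-test. Welch is preferred over the
pooled-variance test because nothing guarantees equal spread between a
curated functional set and random genes. `compareGoTerms()` applies the
same test against named comparison sets; genes in both the target and a
comparison set stay on both sides unless `excludeOverlap = TRUE`.

One subtlety matters for calibration. Within one dataset, all resampling
iterations share the same fixed target values, so the iteration-level
p-values are strongly dependent: conditional on a target whose mean
happens to sit near the universe mean, almost no iteration rejects, while
a target one or two standard errors off rejects far more than 5% of the
time. The *unconditional* level is still the nominal one, but the
single-dataset "fraction of iterations with p < 0.05" is over-dispersed
and is not a useful calibration statistic. `calibrateResamplingNull()`
therefore pools iterations across many independently generated null
datasets (200 datasets × 5 iterations by default), which restores
approximately binomial behaviour of the pooled fraction. This is the
calibration the acceptance checks use.

# Baseline statistics

`baselineTable()` cross-tabulates the low/high burden groups against each
clinical variable and applies Pearson's chi-square with the Yates
continuity correction when the table is exactly 2×2 and no correction
otherwise — the convention of standard statistical software and the one
that reproduces published baseline tables. Each variable is analysed on
its own complete cases (per-variable totals may differ), with category
order fixed by the variable definitions. Cohort selection is expressed as
independently toggleable conjunctive filters (`selectionCriteria()` /
`applySelectionFilters()`) with per-filter attrition counts, so the
selection can be audited step by step.

# Survival analysis

Kaplan–Meier curves use the product-limit estimator; the two-group
comparison is the log-rank test. The median survival is the earliest time
at which the curve drops to 0.5 or below, with a 95% confidence interval
from the complementary log-log transform of the curve; when the curve (or
its confidence band) never reaches 0.5 the corresponding bound is reported
as +&infin; rather than suppressed — heavily censored strata genuinely
have open-ended medians.

Cox models are univariate proportional-hazards fits with the Efron tie
approximation (the modern default). Hazard ratios carry Wald 95%
confidence intervals and Wald p-values; the log-rank p-value is reported
alongside Kaplan–Meier output, since applied papers quote both. A
covariate level with no events makes the contrast non-estimable
(monotone likelihood) and is flagged instead of reported as a divergent
estimate.

The subgroup forest (`subgroupForest()`) restricts the cohort to each
level of each stratification factor, re-assigns low/high burden *within*
the subgroup at the subgroup's own median RPMB, and fits high-vs-low Cox
models. Re-splitting per subgroup is the literal reading of the
median-split-within-subgroup design; because the alternative reading
(reusing the cohort-wide split) is also defensible, `globalSplit = TRUE`
provides it as a sensitivity analysis. Subgroups with fewer than
`minN = 30` patients are excluded with a reason rather than estimated.

# The synthetic cohort generator

The generator (`simulationConfig()`, `simulateMethylation()`,
`simulateClinical()`) emulates the statistical structure the analysis
assumes, not array chemistry:

* **&beta; values** are drawn from a Beta distribution parameterized by
  mean and concentration (default concentration 30). The mean is shifted
  on the logit scale by a per-gene effect (sd 0.25) and a per-sample
  burden shift (sd 0.3), giving sample-level burden heterogeneity with
  values that respect the [0, 1] support. Repair-gene promoters default to
  mean &beta; 0.12 and other promoters to 0.30 — a hypomethylated set
  sitting just above the 0.1 calling threshold, so per-sample burden is
  informative rather than saturated.
* **Geometry**: genes are laid out on four synthetic chromosomes with
  strand-alternating TSSs 10 kb apart; each promoter receives 1–8 probes
  placed uniformly inside its window. The repair-gene set and ten disjoint
  comparison term sets are emitted in GMT form.
* **Covariates** are drawn conditionally on the burden group with odds
  multipliers (defaults: 1.8 for age ≥ 70, 9.5 for female sex, 1.6 for
  oral-cavity site), reproducing the direction and rough magnitude of the
  imbalances seen in head-and-neck cohorts.
* **Survival** is exponential at 0.3 events/year with an independent
  exponential censoring time tuned to 30% censoring, and a hazard ratio
  for high-vs-low burden that applies only inside the designated
  adjuvant-chemoradiation / involved-margin stratum (default 2.5 there, 1
  elsewhere; half the cohort in the stratum). Death times extend
  recurrence times, so overall-survival events imply disease-free events.
* **Randomness** flows from a single seed: the methylation stage seeds
  with `cfg$seed`, the clinical stage with `cfg$seed + 1`, so either stage
  can be re-run alone.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data — includes type I/II probe chemistry and
its distributional artefacts, batch and plate effects, copy-number
contamination of &beta; values, correlated methylation across neighbouring
genes, non-exponential hazards, and informative censoring. The simulation
checks validate the machinery, not any clinical claim.

# Problem sizes and numerical checks

The simulation studies run at sizes chosen to estimate each operating
characteristic with useful precision while remaining quick on a laptop:
promoter aggregation is checked entry-for-entry against a double-loop
oracle on 50 random fixtures (up to 60 genes × 20 samples); resampling
power uses 500 genes × 100 samples with 1,000 iterations; null calibration
pools 1,000 iterations over 200 datasets; log-rank size uses 1,000
replicates at n = 200 with 30% censoring; Cox bias/coverage uses 200
replicates each at true ln-HR 0, 0.7 and 1.0 with n = 400; the subgroup
study uses 100 replicates of a 600-patient cohort with a hazard ratio of
2.5 confined to one half-cohort stratum. Deterministic components
(chi-square values, window arithmetic, the binarization boundary) are
checked exactly; stochastic rates are asserted within bands implied by
their binomial standard errors.

# Known limitations

* One TSS per gene symbol is required at input; transcript-level promoter
  choice is deliberately left to the data preparer.
* Only univariate Cox models are provided; no multivariable adjustment,
  time-dependent covariates or competing risks.
* The resampling comparison tests set-level location shift via Welch
  *t*-tests on per-gene summaries; it is not a gene-set enrichment method
  and inherits the t-test's insensitivity to shape differences.
* The burden score treats all set genes exchangeably; no weighting by
  probe count, expression or pathway position.
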