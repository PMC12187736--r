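# MethylBurden

Gene-set promoter methylation burden analysis for Illumina 450K-style
methylation arrays, with the downstream clinical statistics used in
biomarker studies of post-operative treatment.

## The problem and who this is for

Methylation arrays report each CpG probe as a β value — the methylated
fraction of signal, in [0, 1]. Translational studies often need to move
from probes to a patient-level score over a functional gene program: for
DNA-repair genes, the **repair-gene promoter methylation burden (RPMB)**
of a sample is the fraction of repair genes whose promoter methylation
exceeds a calling threshold,

    RPMB_s = #{ g in S : beta_g(s) > 0.1 } / #{ g in S evaluable in s }

where a gene's promoter methylation `beta_g(s)` is the mean β of the
probes falling in its promoter window — the closed interval from 1,000 bp
upstream of the TSS to 300 bp downstream, measured along the direction of
transcription. Patients are split into low/high burden at the median RPMB
and compared on clinical endpoints.

The package is for statisticians and computational biologists who need
this pipeline as tested, reusable components rather than a one-off
script:

* **IO** — strict readers/writers for β matrices, probe annotation, TSS
  tables, GMT gene sets and clinical tables (`readBetaMatrix()`,
  `readGmt()`, `readClinical()`, ...).
* **Promoter profile** — probe-to-promoter mapping and gene-level
  aggregation (`mapProbesToPromoters()`,
  `buildGeneMethylationProfile()`), built on GenomicRanges.
* **Burden scoring** — binarization at β > 0.1, per-sample RPMB and the
  median split (`binarizeMethylation()`, `computeRPMB()`,
  `splitByMedian()`).
* **Set comparison** — Welch t-tests of a target set against resampled
  size-matched null sets and against other named sets
  (`resamplingComparison()`, `compareGoTerms()`), plus a pooled null
  calibration (`calibrateResamplingNull()`).
* **Baseline statistics** — conjunctive cohort-selection filters with
  attrition, and burden-by-covariate contingency tables with Pearson
  chi-square (Yates-corrected for 2×2) (`applySelectionFilters()`,
  `baselineTable()`).
* **Survival** — Kaplan–Meier with log-rank and log-log median CIs,
  univariate Cox (Efron ties), and a median-re-split subgroup forest
  with a minimum-size exclusion rule (`kmLogrank()`, `coxUnivariate()`,
  `subgroupForest()`, `coxTable()`).
* **Synthetic cohorts** — a generator producing probe matrices,
  annotation, gene sets and burden-linked clinical/survival data with
  known truth (`simulationConfig()`, `simulateMethylation()`,
  `simulateClinical()`), so every stage is testable without external
  data.

See the methods vignette
(`vignettes/methylburden-methods.Rmd`) for the statistical conventions
and the generator's design.

## Worked example

A fully synthetic run — 400 genes, 120 samples, repair genes
hypomethylated (mean β 0.12 vs 0.30), a hazard-ratio-2.5 burden effect
confined to the adjuvant-chemoradiation stratum:

```r
library(MethylBurden)

cfg <- simulationConfig(nSamples = 120, nGenes = 400, seed = 42)
sim <- simulateMethylation(cfg)
mapping <- mapProbesToPromoters(sim$annotation, sim$tss)
profile <- buildGeneMethylationProfile(sim$betas, mapping)

burden <- splitByMedian(computeRPMB(binarizeMethylation(profile),
                                    geneSet(sim$sets, "DRG")))
burden
#> BurdenResult: 120 sample(s), 120 scored, 80 set gene(s)
#>   rpmb range: 0.062 - 0.988
#>   median split at 0.6687: 60 low, 60 high

resamplingComparison(summarizeGenes(profile), geneSet(sim$sets, "DRG"),
                     nIter = 1000, seed = 42)
#> ResamplingReport: 1000 iterations, 80 target genes
#>   target median: 0.1191
#>   fraction with p < 0.001: 1.000

clinical <- simulateClinical(burden, cfg)
kmLogrank(clinical$dfs_time, clinical$dfs_event,
          burdenGroups(burden)[clinical$patient_id])
#> Kaplan-Meier comparison of 2 groups
#>  group  n events   median    lower    upper
#>    low 60     40 2.557008 1.724486 3.579177
#>   high 60     47 1.648101 1.297560 2.811615
#>   log-rank chisq = 1.778 (df = 1), p = 0.1824

forest <- subgroupForest(clinical, burden, endpoint = "DFS",
                         factors = "stratum", minN = 30)
forest[, c("level", "n", "hr", "ci_lower", "ci_upper", "p.value")]
#>           level  n       hr  ci_lower ci_upper   p.value
#> 1 ACRT_MISM_ENE 55 1.592319 0.8390621 3.021801 0.1546850
#> 2         other 65 1.013237 0.5658979 1.814195 0.9647064
```

Reading the output: the repair-gene set's median promoter methylation
(0.119) sits far below the rest of the genome, and every one of the 1,000
resampled comparisons rejects at p < 0.001 — the hypomethylation signal
the score is built on. The burden median split does not separate
disease-free survival in the whole 120-patient cohort (log-rank
p = 0.18), but the subgroup forest shows why: the simulated hazard effect
lives only in the `ACRT_MISM_ENE` stratum (HR 1.59 there vs 1.01
elsewhere; at this small n the stratum CI still crosses 1).

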