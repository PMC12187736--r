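## Synthetic 450K-like cohort generator. Emulates the statistical
## structure the pipeline assumes: beta values in [0,1] with the
## repair-gene promoters systematically hypomethylated, multi-probe
## promoters, burden-correlated clinical covariates (older age, female
## sex, oral-cavity site enriched at high burden) and exponential
## survival whose hazard depends on burden group within a designated
## treatment stratum. All randomness flows from cfg$seed; the clinical
## stage re-seeds at cfg$seed + 1 so either stage can be re-run alone.

.goTermNames <- c("morphogenesis", "cell_death", "apoptosis",
                  "proliferation", "immune_response", "development",
                  "cell_migration", "angiogenesis", "cell_adhesion",
                  "secretion")

#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Beta values are drawn
#' from a Beta distribution parameterized by mean and concentration; the
#' mean is shifted on the logit scale by a per-gene effect
#' (\code{geneSd}) and a per-sample burden shift (\code{sampleBurdenSd}).
#' Defaults: repair-gene promoters at mean beta 0.12 vs 0.30 elsewhere
#' (just above/below the 0.1 calling threshold, so per-sample burden is
#' informative), 1-8 probes per promoter, covariate odds multipliers in
#' the direction seen in head-and-neck cohorts (high burden enriched for
#' age >= 70, female sex and oral-cavity site), exponential survival at
#' 0.3 events/year with a high-vs-low hazard ratio of 2.5 inside the
#' adjuvant-chemoradiation / involved-margin stratum and 1 elsewhere,
#' and 30% censoring.
#'
#' @param nSamples number of samples/patients.
#' @param nGenes number of genes.
#' @param drgFraction fraction of genes in the repair-gene set.
#' @param probesPerGeneRange integer length-2, min/max probes per
#'   promoter.
#' @param betaMeanDrg,betaMeanOther mean beta of repair-gene and other
#'   promoters.
#' @param concentration Beta-distribution concentration (a + b).
#' @param geneSd sd of the per-gene logit-scale effect.
#' @param sampleBurdenSd sd of the per-sample logit-scale shift.
#' @param covariateEffects named odds multipliers linking high burden to
#'   \code{age70}, \code{female}, \code{oral_cavity}.
#' @param baselineHazard event hazard, events/year.
#' @param trueHrByStratum named numeric: hazard ratio (high vs low
#'   burden) per stratum; strata not named get 1.
#' @param stratumFraction fraction of patients in the
#'   \code{ACRT_MISM_ENE} stratum (adjuvant chemoradiation for involved
#'   margins / extra-nodal extension).
#' @param censoringRate target fraction censored.
#' @param seed integer seed.
#' @return list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nSamples = 100L, nGenes = 500L,
                             drgFraction = 0.2,
                             probesPerGeneRange = c(1L, 8L),
                             betaMeanDrg = 0.12, betaMeanOther = 0.30,
                             concentration = 30,
                             geneSd = 0.25, sampleBurdenSd = 0.3,
                             covariateEffects = c(age70 = 1.8,
                                                  female = 9.5,
                                                  oral_cavity = 1.6),
                             baselineHazard = 0.3,
                             trueHrByStratum = c(ACRT_MISM_ENE = 2.5),
                             stratumFraction = 0.5,
                             censoringRate = 0.3,
                             seed = 1L) {
    stopifnot(nSamples >= 2, nGenes >= 10,
              drgFraction > 0, drgFraction < 1,
              length(probesPerGeneRange) == 2L,
              probesPerGeneRange[1L] >= 1L,
              probesPerGeneRange[2L] >= probesPerGeneRange[1L],
              betaMeanDrg > 0, betaMeanDrg < 1,
              betaMeanOther > 0, betaMeanOther < 1,
              concentration > 0, geneSd >= 0, sampleBurdenSd >= 0,
              all(covariateEffects > 0), baselineHazard > 0,
              all(trueHrByStratum > 0),
              stratumFraction > 0, stratumFraction < 1,
              censoringRate >= 0, censoringRate < 1)
    structure(as.list(environment()), class = "SimulationConfig")
}

#' Simulate a probe-level methylation dataset
#'
#' Places genes on synthetic chromosomes with strand-balanced TSSs,
#' drops 1-8 probes uniformly inside each promoter window, and draws
#' probe beta values from the gene-class Beta distribution with per-gene
#' and per-sample logit shifts. Emits the repair-gene set (\code{DRG})
#' and ten disjoint comparison term sets as a
#' \linkS4class{GeneSetCollection}. Deterministic for a given seed.
#'
#' @param cfg a [simulationConfig()].
#' @return list: \code{betas} (\linkS4class{ProbeBetaMatrix}),
#'   \code{annotation} (probe GRanges), \code{tss} (TSS GRanges),
#'   \code{sets} (\linkS4class{GeneSetCollection}), \code{truth} (list
#'   with \code{drgGenes}, per-gene class means and per-sample shifts).
#' @export
simulateMethylation <- function(cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    set.seed(cfg$seed)
    winLen <- 1000L + 300L + 1L
    if (cfg$probesPerGeneRange[2L] > winLen)
        stop("infeasible geometry: more probes than promoter positions")
    genes <- sprintf("G%04d", seq_len(cfg$nGenes))
    chrom <- paste0("chr", (seq_len(cfg$nGenes) - 1L) %% 4L + 1L)
    tssPos <- 5000L + 10000L * ((seq_len(cfg$nGenes) - 1L) %/% 4L)
    strand <- rep_len(c("+", "-"), cfg$nGenes)
    tss <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(tssPos, width = 1L),
                                  strand = strand)
    names(tss) <- genes

    nDrg <- max(2L, round(cfg$nGenes * cfg$drgFraction))
    drg <- sort(sample(genes, nDrg))
    isDrg <- genes %in% drg

    k <- sample(seq(cfg$probesPerGeneRange[1L],
                    cfg$probesPerGeneRange[2L]),
                cfg$nGenes, replace = TRUE)
    win <- promoterWindow(tssPos, strand)
    probePos <- unlist(lapply(seq_len(cfg$nGenes), function(i)
        sort(sample(seq(IRanges::start(win)[i], IRanges::end(win)[i]),
                    k[i]))))
    probeChrom <- rep(chrom, k)
    probeGene <- rep(seq_len(cfg$nGenes), k)
    probes <- sprintf("cg%06d", seq_along(probePos))
    ann <- GenomicRanges::GRanges(probeChrom,
                                  IRanges::IRanges(probePos, width = 1L))
    names(ann) <- probes

    classMean <- ifelse(isDrg, cfg$betaMeanDrg, cfg$betaMeanOther)
    geneEff <- stats::rnorm(cfg$nGenes, 0, cfg$geneSd)
    sampleShift <- stats::rnorm(cfg$nSamples, 0, cfg$sampleBurdenSd)
    logitMu <- stats::qlogis(classMean) + geneEff
    mu <- stats::plogis(outer(logitMu[probeGene], sampleShift, "+"))
    vals <- matrix(stats::rbeta(length(mu), mu * cfg$concentration,
                                (1 - mu) * cfg$concentration),
                   nrow = nrow(mu))
    dimnames(vals) <- list(probes,
                           sprintf("S%04d", seq_len(cfg$nSamples)))

    nonDrg <- setdiff(genes, drg)
    termSize <- min(length(nonDrg) %/% length(.goTermNames), nDrg)
    if (termSize >= 1L) {
        termPool <- sample(nonDrg, termSize * length(.goTermNames))
        terms <- split(termPool,
                       rep(.goTermNames, each = termSize))[.goTermNames]
        sets <- GeneSetCollection(
            c(list(DRG = drg), terms),
            c("synthetic repair-gene set",
              paste("synthetic term:", .goTermNames)))
    } else {
        # too few non-target genes to carve out comparison terms
        sets <- GeneSetCollection(list(DRG = drg),
                                  "synthetic repair-gene set")
    }

    list(betas = ProbeBetaMatrix(vals), annotation = ann, tss = tss,
         sets = sets,
         truth = list(drgGenes = drg, classMean = classMean,
                      geneEffect = geneEff, sampleShift = sampleShift))
}

#' Simulate a clinical table conditional on burden groups
#'
#' Draws covariates with the configured odds multipliers conditional on
#' the low/high burden group, assigns treatment flags so that
#' \code{stratumFraction} of patients form the adjuvant-chemoradiation /
#' involved-margin stratum (\code{ACRT_MISM_ENE}), and draws
#' disease-free survival from exponential hazards with the
#' stratum-specific hazard ratio for high burden, censored by an
#' independent exponential. Overall-survival times extend the
#' disease-free times (death follows recurrence), so a death implies
#' both events.
#'
#' @param burden a \linkS4class{BurdenResult} with groups assigned.
#' @param cfg a [simulationConfig()].
#' @param seed seed for this stage; defaults to \code{cfg$seed + 1}.
#' @return a cohort data.frame with a \code{stratum} column
#'   (\code{ACRT_MISM_ENE} / \code{other}).
#' @export
simulateClinical <- function(burden, cfg, seed = NULL) {
    stopifnot(is(burden, "BurdenResult"),
              inherits(cfg, "SimulationConfig"))
    grp <- burdenGroups(burden)
    if (all(is.na(grp)))
        stop("burden groups must be assigned (see splitByMedian)")
    if (is.null(seed)) seed <- cfg$seed + 1L
    set.seed(seed)
    n <- length(grp)
    high <- !is.na(grp) & grp == "high"

    condProb <- function(base, mult) {
        odds <- base / (1 - base)
        p <- ifelse(high, odds * mult / (1 + odds * mult), base)
        stats::rbinom(n, 1L, p) == 1L
    }
    eff <- cfg$covariateEffects
    old <- condProb(0.17, eff[["age70"]])
    female <- condProb(0.08, eff[["female"]])
    age <- ifelse(old, sample(70:85, n, TRUE), sample(40:69, n, TRUE))

    siteBase <- c(hypopharynx = 0.03, larynx = 0.28, oral_cavity = 0.44,
                  oropharynx = 0.20, lip = 0.02, other = 0.03)
    siteHigh <- siteBase
    siteHigh["oral_cavity"] <- siteHigh["oral_cavity"] *
        eff[["oral_cavity"]]
    siteHigh <- siteHigh / sum(siteHigh)
    site <- character(n)
    site[!high] <- sample(names(siteBase), sum(!high), TRUE, siteBase)
    site[high] <- sample(names(siteHigh), sum(high), TRUE, siteHigh)

    ethnicity <- sample(c("asian", "white", "black"), n, TRUE,
                        c(0.02, 0.88, 0.10))
    grade <- sample(c("G1", "G2", "G3-4"), n, TRUE, c(0.12, 0.62, 0.26))
    pT <- sample(c("T1-2", "T3", "T4"), n, TRUE, c(0.37, 0.27, 0.36))
    pN <- sample(c("N0", "N1", "N2-3"), n, TRUE, c(0.48, 0.17, 0.35))
    fineStage <- sample(c("I", "II", "III", "IVA", "IVB"), n, TRUE,
                        c(0.08, 0.15, 0.21, 0.51, 0.05))
    stage <- c(I = "I-II", II = "I-II", III = "III", IVA = "IV",
               IVB = "IV")[fineStage]
    naify <- function(x, frac) {
        x[sample.int(n, round(frac * n))] <- NA
        x
    }
    lvi <- naify(sample(c("no", "yes"), n, TRUE, c(0.6, 0.4)), 0.25)
    pni <- naify(sample(c("no", "yes"), n, TRUE, c(0.55, 0.45)), 0.25)

    inStratum <- stats::rbinom(n, 1L, cfg$stratumFraction) == 1L
    margin <- ifelse(inStratum,
                     sample(c("yes", "no"), n, TRUE, c(0.7, 0.3)), "no")
    ene <- ifelse(inStratum & margin == "no", "yes",
                  ifelse(inStratum, sample(c("yes", "no"), n, TRUE,
                                           c(0.4, 0.6)), "no"))
    adjuvantRt <- inStratum | stats::rbinom(n, 1L, 0.6) == 1L
    chemo <- inStratum
    stratum <- factor(ifelse(inStratum, "ACRT_MISM_ENE", "other"),
                      levels = c("ACRT_MISM_ENE", "other"))

    hrs <- rep(1, n)
    for (s in names(cfg$trueHrByStratum)) {
        inS <- stratum == s
        if (!any(inS) && cfg$trueHrByStratum[[s]] != 1)
            warning("stratum '", s, "' has no members but HR != 1")
        hrs[inS] <- cfg$trueHrByStratum[[s]]
    }
    hazard <- cfg$baselineHazard * ifelse(high, hrs, 1)
    tEvent <- stats::rexp(n, hazard)
    censHaz <- cfg$baselineHazard * cfg$censoringRate /
        max(1 - cfg$censoringRate, 1e-9)
    cens <- if (cfg$censoringRate > 0) stats::rexp(n, censHaz)
            else rep(Inf, n)
    dfsTime <- pmin(tEvent, cens)
    dfsEvent <- as.integer(tEvent <= cens)
    death <- tEvent + stats::rexp(n, 0.7)
    osTime <- pmin(death, cens)
    osEvent <- as.integer(death <= cens)

    data.frame(patient_id = sampleIds(burden),
               age_years = as.integer(age),
               sex = factor(ifelse(female, "female", "male"),
                            levels = c("male", "female")),
               ethnicity = factor(ethnicity,
                                  levels = .cohortEnums$ethnicity),
               site = factor(site, levels = .cohortEnums$site),
               grade = factor(grade, levels = .cohortEnums$grade),
               pT = factor(pT, levels = .cohortEnums$pT),
               pN = factor(pN, levels = .cohortEnums$pN),
               stage = factor(stage, levels = .cohortEnums$stage),
               fine_stage = factor(fineStage,
                                   levels = .cohortEnums$fine_stage),
               lymphovascular_invasion =
                   factor(lvi, levels = c("yes", "no")),
               perineural_invasion = factor(pni, levels = c("yes", "no")),
               mism = factor(margin, levels = c("yes", "no")),
               ene = factor(ene, levels = c("yes", "no")),
               neoadjuvant = stats::rbinom(n, 1L, 0.05) == 1L,
               radical_surgery = stats::rbinom(n, 1L, 0.95) == 1L,
               node_dissection = stats::rbinom(n, 1L, 0.9) == 1L,
               adjuvant_rt = adjuvantRt,
               concurrent_chemo = chemo,
               stratum = stratum,
               dfs_time = dfsTime, dfs_event = dfsEvent,
               os_time = osTime, os_event = osEvent,
               stringsAsFactors = FALSE)
}

#' Simulate two-group exponential survival data
#'
#' Minimal generator for calibration and parameter-recovery studies:
#' equal-sized low/high groups, exponential event times with hazard
#' ratio \code{hr} for the high group, independent exponential censoring
#' tuned to the target censoring fraction.
#'
#' @param n total sample size (split evenly).
#' @param hr true hazard ratio, high vs low.
#' @param baselineHazard events/year in the low group.
#' @param censoringRate target fraction censored.
#' @param seed optional seed.
#' @return data.frame: \code{time}, \code{event}, \code{group}.
#' @export
simulateSurvivalTwoGroup <- function(n, hr, baselineHazard = 0.3,
                                     censoringRate = 0.3, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    group <- factor(rep(c("low", "high"), length.out = n),
                    levels = c("low", "high"))
    hazard <- baselineHazard * ifelse(group == "high", hr, 1)
    tEvent <- stats::rexp(n, hazard)
    cens <- if (censoringRate > 0)
        stats::rexp(n, baselineHazard * censoringRate /
                        (1 - censoringRate))
    else rep(Inf, n)
    data.frame(time = pmin(tEvent, cens),
               event = as.integer(tEvent <= cens), group = group)
}

#' Null calibration of the resampling comparison
#'
#' Estimates the type-I behaviour of [resamplingComparison()] under the
#' null (no target-set methylation shift). Iterations on a single
#' dataset share the fixed target set and are therefore dependent, so
#' the significant fraction is pooled over many independently generated
#' null datasets with a few iterations each, which restores approximate
#' binomial behaviour of the pooled fraction.
#'
#' @param nDatasets number of independent null datasets.
#' @param nIterPerDataset resampling iterations per dataset.
#' @param alpha significance level to tally.
#' @param seed integer seed; dataset d uses \code{seed + d}.
#' @param nSamples,nGenes size of each null dataset.
#' @return list: \code{fraction} (pooled fraction of p < alpha),
#'   \code{nIterations}, \code{pValues}.
#' @export
calibrateResamplingNull <- function(nDatasets = 200L,
                                    nIterPerDataset = 5L,
                                    alpha = 0.05, seed = 1L,
                                    nSamples = 50L, nGenes = 500L) {
    ps <- numeric(0)
    for (d in seq_len(nDatasets)) {
        cfg <- simulationConfig(nSamples = nSamples, nGenes = nGenes,
                                drgFraction = 0.2,
                                probesPerGeneRange = c(1L, 2L),
                                betaMeanDrg = 0.30,   # null: no shift
                                betaMeanOther = 0.30,
                                seed = seed + d)
        sim <- simulateMethylation(cfg)
        mapping <- mapProbesToPromoters(sim$annotation, sim$tss)
        profile <- buildGeneMethylationProfile(sim$betas, mapping)
        rep <- resamplingComparison(summarizeGenes(profile),
                                    geneSet(sim$sets, "DRG"),
                                    nIter = nIterPerDataset,
                                    seed = seed + d, alpha = alpha)
        ps <- c(ps, rep$iterations$p.value)
    }
    list(fraction = mean(ps < alpha), nIterations = length(ps),
         pValues = ps)
}
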