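test_that("generator emits a coherent dataset, reproducibly", {
    cfg <- simulationConfig(nSamples = 20, nGenes = 10,
                            drgFraction = 0.5,
                            probesPerGeneRange = c(1L, 3L), seed = 3)
    sim <- simulateMethylation(cfg)
    expect_length(geneSet(sim$sets, "DRG"), 5)
    expect_s4_class(sim$betas, "ProbeBetaMatrix")
    expect_equal(ncol(betaValues(sim$betas)), 20)
    # every probe lies inside its gene's promoter window
    m <- mapProbesToPromoters(sim$annotation, sim$tss)
    expect_setequal(unlist(m), names(sim$annotation))
    # identical seed, identical output
    sim2 <- simulateMethylation(cfg)
    expect_identical(betaValues(sim2$betas), betaValues(sim$betas))
    expect_identical(geneSets(sim2$sets), geneSets(sim$sets))
    # comparison term sets are disjoint from the target and each other
    all <- geneSets(sim$sets)
    expect_equal(anyDuplicated(unlist(all)), 0)
})

test_that("target genes are hypomethylated by about the configured gap", {
    cfg <- simulationConfig(nSamples = 100, nGenes = 500, seed = 19)
    sim <- simulateMethylation(cfg)
    prof <- buildGeneMethylationProfile(
        sim$betas, mapProbesToPromoters(sim$annotation, sim$tss))
    s <- summarizeGenes(prof)
    drg <- intersect(geneSet(sim$sets, "DRG"), names(s))
    gap <- mean(s[setdiff(names(s), drg)]) - mean(s[drg])
    expect_gte(gap, (cfg$betaMeanOther - cfg$betaMeanDrg) / 2)
})

test_that("mean burden rises with the target-gene methylation mean", {
    burdens <- vapply(c(0.08, 0.15, 0.30), function(m) {
        cfg <- simulationConfig(nSamples = 30, nGenes = 100,
                                betaMeanDrg = m, seed = 23)
        sim <- simulateMethylation(cfg)
        prof <- buildGeneMethylationProfile(
            sim$betas, mapProbesToPromoters(sim$annotation, sim$tss))
        r <- computeRPMB(binarizeMethylation(prof),
                         geneSet(sim$sets, "DRG"))
        mean(rpmbValues(r))
    }, numeric(1))
    expect_true(all(diff(burdens) > 0))
})

test_that("clinical stage links covariates and hazards to burden", {
    cfg <- simulationConfig(nSamples = 400, nGenes = 50,
                            probesPerGeneRange = c(1L, 2L), seed = 29)
    ids <- sprintf("S%04d", seq_len(cfg$nSamples))
    b <- burdenWithGroups(ids, seq_len(400) / 400,
                          rep(c("low", "high"), each = 200))
    cl <- simulateClinical(b, cfg)
    expect_true(validateCohort(cl))
    expect_identical(cl$patient_id, ids)
    # covariates skew in the configured direction at high burden
    pf <- function(x, g) mean(x[b@group == g], na.rm = TRUE)
    expect_gt(pf(cl$sex == "female", "high"), pf(cl$sex == "female", "low"))
    expect_gt(pf(cl$age_years >= 70, "high"), pf(cl$age_years >= 70, "low"))
    # stratum members all carry margin/ENE involvement plus chemo-RT
    inS <- cl$stratum == "ACRT_MISM_ENE"
    expect_true(all(cl$mism[inS] == "yes" | cl$ene[inS] == "yes"))
    expect_true(all(cl$adjuvant_rt[inS] & cl$concurrent_chemo[inS]))
    expect_true(all(cl$concurrent_chemo[!inS] == FALSE))
    # death implies both endpoints observed, never before recurrence
    expect_true(all(cl$dfs_event[cl$os_event == 1] == 1))
    expect_true(all(cl$os_time >= cl$dfs_time - 1e-9))
    # deterministic given the seed
    cl2 <- simulateClinical(b, cfg)
    expect_identical(cl, cl2)
})

test_that("null covariate effects leave covariates independent of burden", {
    cfg <- simulationConfig(nSamples = 300, nGenes = 50,
                            covariateEffects = c(age70 = 1, female = 1,
                                                 oral_cavity = 1),
                            seed = 41)
    ids <- sprintf("S%04d", 1:300)
    b <- burdenWithGroups(ids, seq_len(300) / 300,
                          rep(c("low", "high"), 150))
    cl <- simulateClinical(b, cfg)
    bt <- baselineTable(cl, b, c("age", "sex"))
    expect_true(all(sapply(bt, function(e) e$test$p.value) > 0.001))
})

test_that("pipeline closes end-to-end over random configurations", {
    withr::local_seed(55)
    for (i in 1:6) {
        cfg <- simulationConfig(
            nSamples = sample(20:40, 1), nGenes = sample(40:120, 1),
            drgFraction = runif(1, 0.1, 0.4),
            probesPerGeneRange = sort(sample(1:6, 2)),
            seed = sample.int(1e6, 1))
        sim <- simulateMethylation(cfg)
        prof <- buildGeneMethylationProfile(
            sim$betas, mapProbesToPromoters(sim$annotation, sim$tss))
        r <- splitByMedian(computeRPMB(binarizeMethylation(prof),
                                       geneSet(sim$sets, "DRG")))
        cl <- simulateClinical(r, cfg)
        km <- kmLogrank(cl$dfs_time, cl$dfs_event,
                        burdenGroups(r)[cl$patient_id])
        expect_s3_class(km, "KMResult")
        expect_true(all(diff(km$curves$surv[
            km$curves$group == km$curves$group[1]]) <= 1e-12))
    }
})

test_that("baseline fixture reproduces its printed cross-tabulations", {
    fx <- makeFixtureTable1()
    bt <- baselineTable(fx$cohort, fx$burden, c("age", "sex", "pN"))
    expect_equal(as.vector(t(bt$age$table)), c(221, 45, 190, 71))
    expect_equal(as.vector(t(bt$sex$table)), c(245, 22, 141, 120))
    expect_equal(as.vector(t(bt$pN$table)), c(126, 44, 88, 123, 45, 88))
    expect_equal(nrow(fx$cohort), 528)
    expect_identical(as.character(unique(burdenGroups(fx$burden))),
                     c("low", "high"))
})
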