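# Shared fixture builders: everything is generated in code.

# random probe x sample beta matrix, optionally with missing cells
randomBetaMatrix <- function(nProbes, nSamples, naFrac = 0) {
    v <- matrix(stats::runif(nProbes * nSamples), nProbes, nSamples,
                dimnames = list(sprintf("cg%04d", seq_len(nProbes)),
                                sprintf("S%03d", seq_len(nSamples))))
    if (naFrac > 0)
        v[sample(length(v), round(naFrac * length(v)))] <- NA
    ProbeBetaMatrix(v)
}

# random gene -> probes mapping over the rows of a beta matrix; genes may
# share probes
randomMapping <- function(betas, nGenes) {
    probes <- rownames(betaValues(betas))
    m <- lapply(seq_len(nGenes), function(i)
        sample(probes, sample(1:4, 1L)))
    names(m) <- sprintf("G%03d", seq_len(nGenes))
    m
}

# independent double-loop oracle for promoter aggregation
naiveProfile <- function(betas, mapping) {
    v <- betaValues(betas)
    out <- matrix(NA_real_, length(mapping), ncol(v),
                  dimnames = list(names(mapping), colnames(v)))
    for (g in names(mapping)) {
        for (s in colnames(v)) {
            xs <- v[mapping[[g]], s]
            xs <- xs[!is.na(xs)]
            if (length(xs)) out[g, s] <- sum(xs) / length(xs)
        }
    }
    out
}

# minimal valid cohort around whatever columns a test needs
minimalCohort <- function(n, ...) {
    extra <- list(...)
    d <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                    dfs_time = rep(1, n), dfs_event = rep(0L, n),
                    os_time = rep(1, n), os_event = rep(0L, n),
                    stringsAsFactors = FALSE)
    for (nm in names(extra)) d[[nm]] <- extra[[nm]]
    d
}

# burden result with groups assigned directly
burdenWithGroups <- function(ids, rpmb, group) {
    MethylBurden:::BurdenResult(
        sampleIds = ids, rpmb = rpmb,
        nEvaluable = rep(100L, length(ids)), nSetGenes = 100L,
        group = factor(group, levels = c("low", "high")),
        splitValue = stats::median(rpmb))
}
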