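## Gene-set hypomethylation testing: per-gene summaries, Welch t-tests
## against resampled size-matched non-member sets, and comparisons
## against other named gene sets.

#' Per-gene methylation summary across samples
#'
#' Collapses a gene x sample profile to one value per gene (default the
#' mean across samples, missing excluded; optionally the median). Genes
#' missing in every sample are dropped with a warning.
#'
#' @param profile a \linkS4class{GeneMethylationMatrix}.
#' @param stat \code{"mean"} or \code{"median"}.
#' @return named numeric vector, one summary value in [0,1] per gene.
#' @export
summarizeGenes <- function(profile, stat = c("mean", "median")) {
    stopifnot(is(profile, "GeneMethylationMatrix"))
    stat <- match.arg(stat)
    v <- methValues(profile)
    out <- if (stat == "mean") rowMeans(v, na.rm = TRUE)
           else apply(v, 1L, stats::median, na.rm = TRUE)
    allMissing <- is.nan(out) | is.na(out)
    if (any(allMissing)) {
        warning(sum(allMissing), " gene(s) missing in every sample dropped")
        out <- out[!allMissing]
    }
    out
}

#' Welch two-sample t-test
#'
#' Unequal-variance (Welch) unpaired t-test with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value. The degenerate case of two
#' zero-variance samples with equal means returns \code{t = 0, p = 1}.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @export
welchT <- function(a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
        stop("welch t-test needs >= 2 non-missing values per group")
    if (stats::var(a) == 0 && stats::var(b) == 0) {
        if (mean(a) == mean(b))
            return(list(statistic = 0, df = NA_real_, p.value = 1))
        stop("both groups constant with different means: t is undefined")
    }
    ht <- stats::t.test(a, b, var.equal = FALSE)
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = ht$p.value)
}

#' Compare a gene set against resampled non-member sets
#'
#' Repeatedly draws, without replacement, a random set of non-target
#' genes of the same size as the target's overlap with the universe, and
#' Welch-tests the target's per-gene summaries against the random set's.
#' The report records every iteration's statistic and p-value, the
#' target's median summary, and the fraction of iterations significant
#' at \code{alpha}. The whole procedure is a pure function of
#' (\code{summary}, \code{target}, \code{nIter}, \code{seed}).
#'
#' @param summary named numeric vector from [summarizeGenes()]; its names
#'   are the gene universe.
#' @param target character vector of target-set gene symbols.
#' @param nIter number of resampling iterations (default 1000).
#' @param seed integer seed governing all draws.
#' @param alpha significance level for \code{fractionSignificant}
#'   (default 0.001).
#' @return list of class \code{"ResamplingReport"}: \code{iterations}
#'   (data.frame iteration/statistic/p.value), \code{targetMedian},
#'   \code{fractionSignificant}, \code{alpha}, \code{nIter}, \code{nTarget}.
#' @export
resamplingComparison <- function(summary, target, nIter = 1000L,
                                 seed = NULL, alpha = 0.001) {
    universe <- names(summary)
    tg <- intersect(target, universe)
    pool <- setdiff(universe, target)
    if (length(tg) < 2L)
        stop("fewer than 2 target genes present in the summary")
    if (length(pool) < length(tg))
        stop("universe minus target has fewer genes (", length(pool),
             ") than the target overlap (", length(tg), ")")
    if (!is.null(seed)) set.seed(seed)
    tv <- summary[tg]
    stat <- p <- numeric(nIter)
    for (i in seq_len(nIter)) {
        rv <- summary[sample(pool, length(tg))]
        ht <- welchT(tv, rv)
        stat[i] <- ht$statistic
        p[i] <- ht$p.value
    }
    structure(list(
        iterations = data.frame(iteration = seq_len(nIter),
                                statistic = stat, p.value = p),
        targetMedian = stats::median(tv),
        fractionSignificant = mean(p < alpha),
        alpha = alpha, nIter = nIter, nTarget = length(tg)),
        class = "ResamplingReport")
}

#' @export
print.ResamplingReport <- function(x, ...) {
    cat("ResamplingReport:", x$nIter, "iterations,", x$nTarget,
        "target genes\n")
    cat(sprintf("  target median: %.4f\n", x$targetMedian))
    cat(sprintf("  fraction with p < %g: %.3f\n", x$alpha,
                x$fractionSignificant))
    invisible(x)
}

#' Compare a gene set against other named gene sets
#'
#' One Welch test per comparison set: target per-gene summaries vs the
#' comparison set's. Genes belonging to both sets are kept on both sides
#' unless \code{excludeOverlap} removes them from the comparison set.
#' Sets with fewer than 2 genes in the universe are flagged
#' non-evaluable.
#'
#' @param summary named numeric vector from [summarizeGenes()].
#' @param target character vector of target-set gene symbols.
#' @param others a \linkS4class{GeneSetCollection} of comparison sets.
#' @param excludeOverlap drop target genes from each comparison set.
#' @return data.frame: \code{term}, \code{n_genes}, \code{statistic},
#'   \code{p.value}, \code{evaluable}.
#' @export
compareGoTerms <- function(summary, target, others,
                           excludeOverlap = FALSE) {
    stopifnot(is(others, "GeneSetCollection"))
    universe <- names(summary)
    tg <- intersect(target, universe)
    if (length(tg) < 2L)
        stop("fewer than 2 target genes present in the summary")
    tv <- summary[tg]
    rows <- lapply(names(others), function(nm) {
        genes <- intersect(geneSet(others, nm), universe)
        if (excludeOverlap) genes <- setdiff(genes, target)
        if (length(genes) < 2L)
            return(data.frame(term = nm, n_genes = length(genes),
                              statistic = NA_real_, p.value = NA_real_,
                              evaluable = FALSE))
        ht <- welchT(tv, summary[genes])
        data.frame(term = nm, n_genes = length(genes),
                   statistic = ht$statistic, p.value = ht$p.value,
                   evaluable = TRUE)
    })
    do.call(rbind, rows)
}
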