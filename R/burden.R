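## RPMB scoring: binarize gene-level methylation at a beta threshold,
## score each sample as the fraction of evaluable set genes called
## methylated, and split the cohort at the median burden.

#' Binarize a gene methylation profile
#'
#' A gene is called methylated (1) in a sample when its promoter
#' methylation exceeds the threshold, and unmethylated (0) when it is
#' less than or equal to it; missing values stay missing.
#'
#' @param profile a \linkS4class{GeneMethylationMatrix}.
#' @param threshold beta threshold in (0, 1); default 0.1.
#' @return integer gene x sample matrix of 0/1/\code{NA}.
#' @export
binarizeMethylation <- function(profile, threshold = 0.1) {
    stopifnot(is(profile, "GeneMethylationMatrix"))
    if (!(threshold > 0 && threshold < 1))
        stop("threshold must lie strictly between 0 and 1")
    v <- methValues(profile)
    out <- (v > threshold) * 1L
    storage.mode(out) <- "integer"
    out
}

#' Compute per-sample methylation burden over a gene set
#'
#' RPMB for a sample is the number of set genes called methylated divided
#' by the number of set genes evaluable (non-missing) in that sample. Set
#' genes absent from the matrix are dropped with a logged count; samples
#' whose evaluable fraction falls below \code{minEvaluableFraction}
#' receive no score (\code{NA}) with a logged reason.
#'
#' @param binary integer 0/1/\code{NA} gene x sample matrix from
#'   [binarizeMethylation()].
#' @param genes character vector of set gene symbols.
#' @param minEvaluableFraction minimum fraction of set genes that must be
#'   non-missing for a sample to be scored; default 0.9.
#' @return a \linkS4class{BurdenResult} (groups unset).
#' @export
computeRPMB <- function(binary, genes, minEvaluableFraction = 0.9) {
    stopifnot(is.matrix(binary))
    genes <- unique(as.character(genes))
    present <- intersect(genes, rownames(binary))
    if (!length(present))
        stop("no gene of the set is present in the methylation matrix")
    dropped <- length(genes) - length(present)
    if (dropped)
        message("compute_rpmb: ", dropped,
                " set gene(s) absent from the matrix dropped (",
                length(present), " used)")
    sub <- binary[present, , drop = FALSE]
    nEval <- colSums(!is.na(sub))
    meth <- colSums(sub == 1L, na.rm = TRUE)
    rpmb <- ifelse(nEval > 0L, meth / nEval, NA_real_)
    low <- nEval < minEvaluableFraction * length(present)
    if (any(low)) {
        message("compute_rpmb: ", sum(low), " sample(s) below the ",
                "evaluable-fraction floor (", minEvaluableFraction,
                ") left unscored")
        rpmb[low] <- NA_real_
    }
    BurdenResult(sampleIds = colnames(binary), rpmb = rpmb,
                 nEvaluable = nEval, nSetGenes = length(present))
}

#' Split samples into low/high burden at the median
#'
#' Samples with RPMB less than or equal to the median of the scored
#' samples go to \code{low}, those above it to \code{high}; the median
#' used is recorded in \code{splitValue()}. Unscored samples keep a
#' missing group.
#'
#' @param result a \linkS4class{BurdenResult} from [computeRPMB()].
#' @return the result with groups assigned.
#' @export
splitByMedian <- function(result) {
    stopifnot(is(result, "BurdenResult"))
    scored <- !is.na(result@rpmb)
    if (sum(scored) < 2L)
        stop("median split needs at least 2 scored samples")
    med <- stats::median(result@rpmb[scored])
    if (all(result@rpmb[scored] == med))
        stop("degenerate split: all scored samples share rpmb = ", med)
    grp <- rep(NA_character_, length(result@rpmb))
    grp[scored] <- ifelse(result@rpmb[scored] <= med, "low", "high")
    initialize(result, group = factor(grp, levels = c("low", "high")),
               splitValue = med)
}
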