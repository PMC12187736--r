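#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Probe-level beta-value matrix
#'
#' Container for probe x sample methylation beta values from a 450K-style
#' array. Extends \linkS4class{SummarizedExperiment} with a single assay
#' named \code{"beta"}. A beta value is the fraction of methylated signal at
#' a CpG site and lies in [0, 1]; missing measurements are \code{NA}.
#'
#' @slot ... see \linkS4class{SummarizedExperiment}.
#' @seealso [ProbeBetaMatrix()], [readBetaMatrix()], [betaValues()]
#' @export
setClass("ProbeBetaMatrix", contains = "SummarizedExperiment")

.validProbeBetaMatrix <- function(object) {
    msg <- character()
    if (!"beta" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'beta' is required")
    else {
        v <- SummarizedExperiment::assay(object, "beta")
        bad <- which(!is.na(v) & (v < 0 | v > 1))
        if (length(bad)) {
            idx <- arrayInd(bad[1L], dim(v))
            msg <- c(msg, sprintf(
                "beta value out of [0,1] at probe '%s', sample '%s' (%g)",
                rownames(v)[idx[1L]], colnames(v)[idx[2L]], v[bad[1L]]))
        }
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "probe ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    if (length(msg)) msg else TRUE
}
setValidity("ProbeBetaMatrix", .validProbeBetaMatrix)

#' Construct a ProbeBetaMatrix
#'
#' @param values numeric matrix of beta values (probes x samples) with
#'   probe ids as rownames and sample ids as colnames. \code{NA} marks a
#'   missing measurement.
#' @return a \linkS4class{ProbeBetaMatrix}.
#' @examples
#' m <- matrix(c(0.1, 0.9, 0, 1), 2, dimnames = list(c("cg1","cg2"),
#'                                                   c("s1","s2")))
#' ProbeBetaMatrix(m)
#' @export
ProbeBetaMatrix <- function(values) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    new("ProbeBetaMatrix",
        SummarizedExperiment(assays = list(beta = values)))
}

#' Gene-level promoter methylation matrix
#'
#' Gene x sample promoter methylation values (mean beta over the probes
#' falling in each gene's promoter window). Extends
#' \linkS4class{SummarizedExperiment} with assay \code{"meth"}; the number
#' of probes contributing to each gene is kept in \code{rowData()$nProbes}.
#'
#' @seealso [buildGeneMethylationProfile()], [methValues()],
#'   [probesPerGene()]
#' @export
setClass("GeneMethylationMatrix", contains = "SummarizedExperiment")

.validGeneMethylationMatrix <- function(object) {
    msg <- character()
    if (!"meth" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'meth' is required")
    else {
        v <- SummarizedExperiment::assay(object, "meth")
        if (any(!is.na(v) & (v < 0 | v > 1)))
            msg <- c(msg, "methylation values must lie in [0,1]")
    }
    np <- SummarizedExperiment::rowData(object)$nProbes
    if (is.null(np) || any(is.na(np)) || any(np < 1L))
        msg <- c(msg, "rowData()$nProbes must be >= 1 for every gene")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene symbols must be present and unique")
    if (length(msg)) msg else TRUE
}
setValidity("GeneMethylationMatrix", .validGeneMethylationMatrix)

#' Construct a GeneMethylationMatrix
#'
#' @param values numeric matrix (genes x samples) in [0,1] or \code{NA}.
#' @param nProbes integer vector, probes contributing per gene (>= 1).
#' @return a \linkS4class{GeneMethylationMatrix}.
#' @export
GeneMethylationMatrix <- function(values, nProbes) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    new("GeneMethylationMatrix",
        SummarizedExperiment(assays = list(meth = values),
                             rowData = DataFrame(nProbes = as.integer(nProbes))))
}

#' Named collection of gene sets
#'
#' Gene sets (e.g. a DNA-repair gene set and GO-term comparison sets) as
#' read from a GMT file: each set has a unique name, a free-text
#' description and a vector of unique gene symbols.
#'
#' @slot sets named list of character vectors of gene symbols.
#' @slot descriptions named character vector, one per set.
#' @seealso [readGmt()], [geneSet()], [geneSets()]
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", descriptions = "character"))

.validGeneSetCollection <- function(object) {
    msg <- character()
    nm <- names(object@sets)
    if (length(object@sets) && (is.null(nm) || anyDuplicated(nm) ||
                                any(!nzchar(nm))))
        msg <- c(msg, "set names must be present, non-empty and unique")
    if (any(vapply(object@sets, anyDuplicated, 0L) > 0L))
        msg <- c(msg, "gene symbols must be unique within each set")
    if (length(object@descriptions) != length(object@sets))
        msg <- c(msg, "one description per set is required")
    if (length(msg)) msg else TRUE
}
setValidity("GeneSetCollection", .validGeneSetCollection)

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene symbols.
#' @param descriptions character vector of descriptions, recycled from ""
#'   when omitted.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets = list(), descriptions = NULL) {
    sets <- lapply(sets, as.character)
    if (is.null(descriptions))
        descriptions <- rep("", length(sets))
    names(descriptions) <- names(sets)
    new("GeneSetCollection", sets = sets, descriptions = descriptions)
}

#' Per-sample methylation burden result
#'
#' Holds each sample's RPMB (repair-gene promoter methylation burden): the
#' fraction of evaluable set genes whose promoter methylation exceeds the
#' beta threshold. After [splitByMedian()] the low/high group assignment
#' and the median used for the split are recorded.
#'
#' @slot sampleIds character, sample identifiers.
#' @slot rpmb numeric in [0,1]; \code{NA} for unscored samples.
#' @slot nEvaluable integer, non-missing set genes per sample.
#' @slot nSetGenes integer scalar, set genes present in the profile.
#' @slot group factor with levels \code{low}, \code{high}; all \code{NA}
#'   until the median split is applied.
#' @slot splitValue numeric scalar, the median RPMB used for the split
#'   (\code{NA} before splitting).
#' @seealso [computeRPMB()], [splitByMedian()]
#' @export
setClass("BurdenResult",
         representation(sampleIds = "character", rpmb = "numeric",
                        nEvaluable = "integer", nSetGenes = "integer",
                        group = "factor", splitValue = "numeric"))

.validBurdenResult <- function(object) {
    msg <- character()
    n <- length(object@sampleIds)
    if (anyDuplicated(object@sampleIds))
        msg <- c(msg, "sample ids must be unique")
    if (length(object@rpmb) != n || length(object@nEvaluable) != n ||
        length(object@group) != n)
        msg <- c(msg, "rpmb, nEvaluable and group must match sampleIds")
    if (any(!is.na(object@rpmb) & (object@rpmb < 0 | object@rpmb > 1)))
        msg <- c(msg, "rpmb must lie in [0,1]")
    if (!identical(levels(object@group), c("low", "high")))
        msg <- c(msg, "group levels must be c('low','high')")
    if (length(object@nSetGenes) != 1L || length(object@splitValue) != 1L)
        msg <- c(msg, "nSetGenes and splitValue must be scalars")
    if (length(msg)) msg else TRUE
}
setValidity("BurdenResult", .validBurdenResult)

BurdenResult <- function(sampleIds, rpmb, nEvaluable, nSetGenes,
                         group = NULL, splitValue = NA_real_) {
    if (is.null(group))
        group <- factor(rep(NA_character_, length(sampleIds)),
                        levels = c("low", "high"))
    new("BurdenResult", sampleIds = as.character(sampleIds),
        rpmb = as.numeric(rpmb), nEvaluable = as.integer(nEvaluable),
        nSetGenes = as.integer(nSetGenes), group = group,
        splitValue = as.numeric(splitValue))
}
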