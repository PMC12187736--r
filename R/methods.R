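#' @rdname ProbeBetaMatrix-class
#' @export
setMethod("betaValues", "ProbeBetaMatrix",
          function(x) SummarizedExperiment::assay(x, "beta"))

#' @rdname GeneMethylationMatrix-class
#' @export
setMethod("methValues", "GeneMethylationMatrix",
          function(x) SummarizedExperiment::assay(x, "meth"))

#' @rdname GeneMethylationMatrix-class
#' @export
setMethod("probesPerGene", "GeneMethylationMatrix", function(x) {
    np <- SummarizedExperiment::rowData(x)$nProbes
    names(np) <- rownames(x)
    np
})

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSet", "GeneSetCollection", function(x, name) {
    if (!name %in% names(x@sets))
        stop("no gene set named '", name, "'")
    x@sets[[name]]
})

#' @rdname GeneSetCollection-class
#' @export
setMethod("setDescriptions", "GeneSetCollection", function(x) x@descriptions)

#' @rdname GeneSetCollection-class
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @rdname GeneSetCollection-class
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection with", length(object), "set(s)\n")
    n <- names(object)
    for (i in seq_len(min(length(object), 5L)))
        cat(sprintf("  %s (%d genes): %s\n", n[i],
                    length(object@sets[[i]]),
                    paste(utils::head(object@sets[[i]], 3L),
                          collapse = ", ")))
    if (length(object) > 5L) cat("  ...\n")
})

#' @rdname BurdenResult-class
#' @export
setMethod("rpmbValues", "BurdenResult", function(x) {
    v <- x@rpmb; names(v) <- x@sampleIds; v
})

#' @rdname BurdenResult-class
#' @export
setMethod("burdenGroups", "BurdenResult", function(x) {
    g <- x@group; names(g) <- x@sampleIds; g
})

#' @rdname BurdenResult-class
#' @export
setMethod("nEvaluable", "BurdenResult", function(x) {
    v <- x@nEvaluable; names(v) <- x@sampleIds; v
})

#' @rdname BurdenResult-class
#' @export
setMethod("nSetGenes", "BurdenResult", function(x) x@nSetGenes)

#' @rdname BurdenResult-class
#' @export
setMethod("splitValue", "BurdenResult", function(x) x@splitValue)

#' @rdname BurdenResult-class
#' @export
setMethod("sampleIds", "BurdenResult", function(x) x@sampleIds)

setMethod("show", "BurdenResult", function(object) {
    scored <- sum(!is.na(object@rpmb))
    cat("BurdenResult:", length(object@sampleIds), "sample(s),",
        scored, "scored,", object@nSetGenes, "set gene(s)\n")
    if (scored)
        cat(sprintf("  rpmb range: %.3f - %.3f\n",
                    min(object@rpmb, na.rm = TRUE),
                    max(object@rpmb, na.rm = TRUE)))
    if (!is.na(object@splitValue))
        cat(sprintf("  median split at %.4f: %d low, %d high\n",
                    object@splitValue,
                    sum(object@group == "low", na.rm = TRUE),
                    sum(object@group == "high", na.rm = TRUE)))
})

#' Convert a BurdenResult to a data.frame
#'
#' @param x a \linkS4class{BurdenResult}.
#' @param ... ignored.
#' @return data.frame with columns \code{sample_id}, \code{n_evaluable},
#'   \code{rpmb}, \code{group}.
#' @export
as.data.frame.BurdenResult <- function(x, ...) {
    data.frame(sample_id = x@sampleIds, n_evaluable = x@nEvaluable,
               rpmb = x@rpmb, group = as.character(x@group),
               stringsAsFactors = FALSE)
}
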