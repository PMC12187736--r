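#' @rdname ProbeBetaMatrix-class
#' @param x a \linkS4class{ProbeBetaMatrix}.
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname GeneMethylationMatrix-class
#' @param x a \linkS4class{GeneMethylationMatrix}.
#' @export
setGeneric("methValues", function(x) standardGeneric("methValues"))

#' @rdname GeneMethylationMatrix-class
#' @export
setGeneric("probesPerGene", function(x) standardGeneric("probesPerGene"))

#' @rdname GeneSetCollection-class
#' @param x a \linkS4class{GeneSetCollection}.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @param name set name.
#' @export
setGeneric("geneSet", function(x, name) standardGeneric("geneSet"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

#' @rdname BurdenResult-class
#' @param x a \linkS4class{BurdenResult}.
#' @export
setGeneric("rpmbValues", function(x) standardGeneric("rpmbValues"))

#' @rdname BurdenResult-class
#' @export
setGeneric("burdenGroups", function(x) standardGeneric("burdenGroups"))

#' @rdname BurdenResult-class
#' @export
setGeneric("nEvaluable", function(x) standardGeneric("nEvaluable"))

#' @rdname BurdenResult-class
#' @export
setGeneric("nSetGenes", function(x) standardGeneric("nSetGenes"))

#' @rdname BurdenResult-class
#' @export
setGeneric("splitValue", function(x) standardGeneric("splitValue"))

#' @rdname BurdenResult-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
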