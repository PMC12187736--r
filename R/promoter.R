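## Promoter windows and probe-to-gene aggregation. The promoter of a gene
## is the closed 1-based interval from `upstream` bp upstream of the TSS
## to `downstream` bp downstream (defaults 1000/300), measured along the
## direction of transcription, so minus-strand windows flip.

#' Promoter window around a TSS
#'
#' For a plus-strand gene the window is \code{[tss - upstream,
#' tss + downstream]}; for a minus-strand gene "upstream" points to larger
#' coordinates, giving \code{[tss - downstream, tss + upstream]}. Both
#' endpoints are included and the start is clipped at 1. With
#' \code{ignoreStrand = TRUE} every gene is treated as plus-strand.
#'
#' @param tss numeric vector of 1-based TSS coordinates.
#' @param strand character vector of \code{"+"}/\code{"-"} (recycled).
#' @param upstream,downstream window extents in bp (>= 0).
#' @param ignoreStrand if \code{TRUE}, use the plus-strand window for all.
#' @return an \link[IRanges]{IRanges} of windows, one per TSS.
#' @examples
#' promoterWindow(10000, "+")   # [9000, 10300]
#' promoterWindow(10000, "-")   # [9700, 11000]
#' @export
promoterWindow <- function(tss, strand, upstream = 1000L,
                           downstream = 300L, ignoreStrand = FALSE) {
    stopifnot(upstream >= 0, downstream >= 0)
    if (any(is.na(tss)) || any(tss < 1))
        stop("tss must be >= 1")
    if (!all(strand %in% c("+", "-")))
        stop("strand must be '+' or '-'")
    strand <- rep_len(strand, length(tss))
    plus <- ignoreStrand | strand == "+"
    start <- ifelse(plus, tss - upstream, tss - downstream)
    end <- ifelse(plus, tss + downstream, tss + upstream)
    IRanges::IRanges(start = pmax(start, 1), end = end)
}

#' Promoter windows for a TSS GRanges
#'
#' @param tx width-1 stranded \link[GenomicRanges]{GRanges} of TSSs named
#'   by gene symbol (as from [readTranscriptTable()]).
#' @inheritParams promoterWindow
#' @return a \link[GenomicRanges]{GRanges} of promoter windows named by
#'   gene symbol.
#' @export
promoterWindows <- function(tx, upstream = 1000L, downstream = 300L,
                            ignoreStrand = FALSE) {
    ir <- promoterWindow(GenomicRanges::start(tx),
                         as.character(GenomicRanges::strand(tx)),
                         upstream, downstream, ignoreStrand)
    gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(tx), ir,
                                 strand = GenomicRanges::strand(tx))
    names(gr) <- names(tx)
    gr
}

#' Map probes to gene promoters
#'
#' A probe is assigned to a gene when it lies on the same chromosome and
#' its position falls inside the gene's promoter window (both endpoints
#' included). A probe inside two overlapping promoters is assigned to both
#' genes; genes whose window contains no probe are absent from the result.
#'
#' @param ann width-1 \link[GenomicRanges]{GRanges} of probe positions
#'   named by probe id (as from [readProbeAnnotation()]).
#' @param tx width-1 stranded GRanges of TSSs named by gene symbol.
#' @inheritParams promoterWindow
#' @return named list: gene symbol -> character vector of probe ids.
#' @export
mapProbesToPromoters <- function(ann, tx, upstream = 1000L,
                                 downstream = 300L, ignoreStrand = FALSE) {
    prom <- promoterWindows(tx, upstream, downstream, ignoreStrand)
    hits <- GenomicRanges::findOverlaps(prom, ann, ignore.strand = TRUE)
    g <- names(prom)[S4Vectors::queryHits(hits)]
    p <- names(ann)[S4Vectors::subjectHits(hits)]
    # keep genes in transcript-table order, probes in annotation order
    mapping <- split(p, factor(g, levels = unique(names(prom))))
    mapping[lengths(mapping) > 0L]
}

#' Build the gene x sample promoter methylation profile
#'
#' For every gene and sample, the gene's methylation value is the mean of
#' the non-missing beta values of the probes mapped to its promoter. A
#' single-probe gene inherits that probe's beta; a gene whose probes are
#' all missing in a sample is missing there.
#'
#' @param betas a \linkS4class{ProbeBetaMatrix}.
#' @param mapping named list gene -> probe ids, as from
#'   [mapProbesToPromoters()].
#' @return a \linkS4class{GeneMethylationMatrix} with one row per mapped
#'   gene; \code{rowData()$nProbes} records the probes per gene.
#' @export
buildGeneMethylationProfile <- function(betas, mapping) {
    stopifnot(is(betas, "ProbeBetaMatrix"))
    if (!length(mapping))
        stop("empty probe-to-gene mapping")
    v <- betaValues(betas)
    probes <- unlist(mapping, use.names = FALSE)
    unknown <- setdiff(probes, rownames(v))
    if (length(unknown))
        stop("mapping refers to probe(s) absent from the beta matrix: ",
             paste(utils::head(unknown, 3L), collapse = ", "))
    gene <- factor(rep(names(mapping), lengths(mapping)),
                   levels = names(mapping))
    sub <- v[probes, , drop = FALSE]
    filled <- sub
    filled[is.na(filled)] <- 0
    sums <- rowsum(filled, gene)
    counts <- rowsum((!is.na(sub)) * 1L, gene)
    vals <- sums / counts        # 0/0 -> NaN where every probe is missing
    vals[counts == 0L] <- NA_real_
    GeneMethylationMatrix(vals, nProbes = lengths(mapping))
}
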