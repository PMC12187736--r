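## Readers/writers for the tabular formats the pipeline touches: TSV beta
## matrices, probe annotation, TSS tables, GMT gene sets and the clinical
## table. All coordinates are 1-based, fully closed intervals; the missing
## token is "NA" (TCGA convention) unless overridden.

#' Read a probe x sample beta-value matrix from TSV
#'
#' First column holds probe ids, header row holds sample ids; cells are
#' numeric beta values in [0, 1] or the missing token. Probe and sample
#' order in the file is preserved.
#'
#' @param path TSV file path.
#' @param missing character token marking a missing cell (default "NA").
#' @return a \linkS4class{ProbeBetaMatrix}.
#' @seealso [writeBetaMatrix()]
#' @export
readBetaMatrix <- function(path, missing = "NA") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            na.strings = missing, check.names = FALSE,
                            colClasses = "character")
    if (ncol(df) < 2L)
        stop("beta matrix must have a probe-id column and >=1 sample")
    probes <- df[[1L]]
    if (anyDuplicated(probes))
        stop("duplicate probe id: ",
             probes[anyDuplicated(probes)])
    vals <- suppressWarnings(
        vapply(df[-1L], as.numeric, numeric(nrow(df))))
    if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L,
                                       dimnames = list(NULL, names(df)[-1L]))
    nonnum <- !is.na(as.matrix(df[-1L])) & is.na(vals)
    if (any(nonnum)) {
        idx <- which(nonnum, arr.ind = TRUE)[1L, ]
        stop(sprintf("non-numeric beta value for probe '%s', sample '%s'",
                     probes[idx[1L]], colnames(vals)[idx[2L]]))
    }
    rownames(vals) <- probes
    ProbeBetaMatrix(vals)
}

#' Write a ProbeBetaMatrix to TSV
#'
#' @param x a \linkS4class{ProbeBetaMatrix}.
#' @param path output file path.
#' @param missing token written for missing cells.
#' @return invisibly, \code{path}.
#' @export
writeBetaMatrix <- function(x, path, missing = "NA") {
    stopifnot(is(x, "ProbeBetaMatrix"))
    v <- betaValues(x)
    df <- data.frame(probe_id = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = missing)
    invisible(path)
}

#' Read probe genomic annotation
#'
#' Expects columns \code{probe_id}, \code{chromosome}, \code{position}
#' (1-based bp).
#'
#' @param path TSV file path.
#' @return a width-1 \link[GenomicRanges]{GRanges} named by probe id.
#' @export
readProbeAnnotation <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    req <- c("probe_id", "chromosome", "position")
    if (!all(req %in% names(df)))
        stop("probe annotation needs columns: ", paste(req, collapse = ", "))
    if (anyDuplicated(df$probe_id))
        stop("duplicate probe id in annotation: ",
             df$probe_id[anyDuplicated(df$probe_id)])
    if (any(is.na(df$position)) || any(df$position < 1))
        stop("probe positions must be 1-based (>= 1)")
    gr <- GenomicRanges::GRanges(df$chromosome,
                                 IRanges::IRanges(df$position, width = 1L))
    names(gr) <- df$probe_id
    gr
}

#' Write probe annotation to TSV
#' @param gr width-1 GRanges named by probe id.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeProbeAnnotation <- function(gr, path) {
    df <- data.frame(probe_id = names(gr),
                     chromosome = as.character(GenomicRanges::seqnames(gr)),
                     position = GenomicRanges::start(gr))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a transcript/TSS table
#'
#' Expects columns \code{gene_symbol}, \code{chromosome}, \code{strand}
#' (\code{+}/\code{-}) and \code{tss} (1-based bp). Exactly one row per
#' gene symbol is required: collapsing multiple transcripts to a single
#' representative TSS is the data preparer's job, and duplicates are
#' rejected rather than silently resolved.
#'
#' @param path TSV file path.
#' @return a width-1 stranded \link[GenomicRanges]{GRanges} (the TSS)
#'   named by gene symbol.
#' @export
readTranscriptTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    req <- c("gene_symbol", "chromosome", "strand", "tss")
    if (!all(req %in% names(df)))
        stop("transcript table needs columns: ", paste(req, collapse = ", "))
    if (anyDuplicated(df$gene_symbol))
        stop("duplicate gene symbol in transcript table: ",
             df$gene_symbol[anyDuplicated(df$gene_symbol)])
    if (!all(df$strand %in% c("+", "-")))
        stop("strand must be '+' or '-'")
    if (any(is.na(df$tss)) || any(df$tss < 1))
        stop("tss must be 1-based (>= 1)")
    gr <- GenomicRanges::GRanges(df$chromosome,
                                 IRanges::IRanges(df$tss, width = 1L),
                                 strand = df$strand)
    names(gr) <- df$gene_symbol
    gr
}

#' Write a TSS table to TSV
#' @param gr width-1 stranded GRanges named by gene symbol.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeTranscriptTable <- function(gr, path) {
    df <- data.frame(gene_symbol = names(gr),
                     chromosome = as.character(GenomicRanges::seqnames(gr)),
                     strand = as.character(GenomicRanges::strand(gr)),
                     tss = GenomicRanges::start(gr))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}. Duplicate symbols
#' within a line are deduplicated with a warning; duplicate set names and
#' malformed lines are errors.
#'
#' @param path GMT file path.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- list(); desc <- character()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop("GMT line ", i, " has fewer than 3 tab-separated fields")
        nm <- f[1L]
        if (nm %in% names(sets))
            stop("duplicate gene set name '", nm, "' at line ", i)
        genes <- f[-c(1L, 2L)]
        genes <- genes[nzchar(genes)]
        if (anyDuplicated(genes)) {
            warning("GMT set '", nm, "': ",
                    sum(duplicated(genes)), " duplicate symbol(s) removed")
            genes <- unique(genes)
        }
        sets[[nm]] <- genes
        desc[nm] <- f[2L]
    }
    GeneSetCollection(sets, desc)
}

#' Write a GeneSetCollection to GMT
#' @param x a \linkS4class{GeneSetCollection}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeGmt <- function(x, path) {
    stopifnot(is(x, "GeneSetCollection"))
    lines <- vapply(names(x), function(nm) {
        paste(c(nm, x@descriptions[[nm]], x@sets[[nm]]), collapse = "\t")
    }, character(1L))
    writeLines(lines, path)
    invisible(path)
}

## Clinical table: column enumerations (lowercased for matching)
.cohortEnums <- list(
    sex = c("male", "female"),
    ethnicity = c("asian", "white", "black", "other"),
    site = c("hypopharynx", "larynx", "oral_cavity", "oropharynx",
             "lip", "other"),
    grade = c("G1", "G2", "G3-4"),
    pT = c("T1-2", "T3", "T4"),
    pN = c("N0", "N1", "N2-3"),
    stage = c("I-II", "III", "IV"),
    fine_stage = c("I", "II", "III", "IVA", "IVB", "IVC"),
    lymphovascular_invasion = c("yes", "no"),
    perineural_invasion = c("yes", "no"),
    mism = c("yes", "no"),
    ene = c("yes", "no"))

.cohortFlags <- c("neoadjuvant", "radical_surgery", "node_dissection",
                  "adjuvant_rt", "concurrent_chemo")

.cohortMandatory <- c("patient_id", "dfs_time", "dfs_event",
                      "os_time", "os_event")

.normEnum <- function(x, levels, column) {
    x <- trimws(as.character(x))
    x[!nzchar(x)] <- NA_character_
    m <- match(tolower(x), tolower(levels))
    out <- levels[m]
    nbad <- sum(!is.na(x) & is.na(out))
    if (nbad)
        message("read_clinical: ", nbad, " unparseable value(s) in '",
                column, "' set to missing")
    factor(out, levels = levels)
}

.normFlag <- function(x, column) {
    x <- tolower(trimws(as.character(x)))
    x[!nzchar(x)] <- NA_character_
    out <- rep(NA, length(x))
    out[x %in% c("1", "true", "yes", "y")] <- TRUE
    out[x %in% c("0", "false", "no", "n")] <- FALSE
    nbad <- sum(!is.na(x) & is.na(out))
    if (nbad)
        message("read_clinical: ", nbad, " unparseable value(s) in '",
                column, "' set to missing")
    out
}

#' Read and validate a clinical cohort table
#'
#' One row per patient. Mandatory columns: \code{patient_id},
#' \code{dfs_time}, \code{dfs_event}, \code{os_time}, \code{os_event}.
#' Recognised categorical columns are normalised case-insensitively to
#' their enumerations (\code{sex}, \code{ethnicity}, \code{site},
#' \code{grade}, \code{pT}, \code{pN}, \code{stage}, \code{fine_stage},
#' \code{lymphovascular_invasion}, \code{perineural_invasion},
#' \code{mism}, \code{ene}); treatment flags (\code{neoadjuvant},
#' \code{radical_surgery}, \code{node_dissection}, \code{adjuvant_rt},
#' \code{concurrent_chemo}) become logicals. Unparseable cells become
#' missing with a logged count; unknown columns are preserved untouched.
#' Survival times are in years and must be non-negative; events in
#' \{0,1\}.
#'
#' @param path TSV file path.
#' @param missing token marking a missing cell.
#' @return a validated cohort data.frame.
#' @seealso [validateCohort()], [writeClinical()]
#' @export
readClinical <- function(path, missing = "NA") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            na.strings = missing, check.names = FALSE,
                            colClasses = "character")
    miss <- setdiff(.cohortMandatory, names(df))
    if (length(miss))
        stop("clinical table is missing mandatory column(s): ",
             paste(miss, collapse = ", "))
    if ("age_years" %in% names(df))
        df$age_years <- suppressWarnings(as.integer(df$age_years))
    for (col in names(.cohortEnums))
        if (col %in% names(df))
            df[[col]] <- .normEnum(df[[col]], .cohortEnums[[col]], col)
    for (col in .cohortFlags)
        if (col %in% names(df))
            df[[col]] <- .normFlag(df[[col]], col)
    for (col in c("dfs_time", "os_time"))
        df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    for (col in c("dfs_event", "os_event"))
        df[[col]] <- suppressWarnings(as.integer(df[[col]]))
    validateCohort(df)
    df
}

#' Validate a cohort data.frame
#'
#' Checks the invariants of the clinical table: unique patient ids,
#' non-negative survival times, events in \{0,1\}, categorical columns
#' within their enumerations.
#'
#' @param cohort a cohort data.frame.
#' @return invisibly \code{TRUE}; errors describe the first violation.
#' @export
validateCohort <- function(cohort) {
    miss <- setdiff(.cohortMandatory, names(cohort))
    if (length(miss))
        stop("cohort is missing mandatory column(s): ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(cohort$patient_id))
        stop("duplicate patient_id: ",
             cohort$patient_id[anyDuplicated(cohort$patient_id)])
    for (col in c("dfs_time", "os_time")) {
        bad <- which(!is.na(cohort[[col]]) & cohort[[col]] < 0)
        if (length(bad))
            stop("negative ", col, " for patient '",
                 cohort$patient_id[bad[1L]], "'")
    }
    for (col in c("dfs_event", "os_event")) {
        bad <- which(!is.na(cohort[[col]]) & !cohort[[col]] %in% c(0L, 1L))
        if (length(bad))
            stop(col, " must be 0 or 1 (patient '",
                 cohort$patient_id[bad[1L]], "')")
    }
    for (col in names(.cohortEnums))
        if (col %in% names(cohort) && !is.factor(cohort[[col]])) {
            v <- cohort[[col]]
            bad <- !is.na(v) & !v %in% .cohortEnums[[col]]
            if (any(bad))
                stop("invalid value '", v[which(bad)[1L]], "' in '", col, "'")
        }
    invisible(TRUE)
}

#' Write a cohort table to TSV
#' @param cohort a cohort data.frame.
#' @param path output file path.
#' @param missing token written for missing cells.
#' @return invisibly, \code{path}.
#' @export
writeClinical <- function(cohort, path, missing = "NA") {
    out <- cohort
    for (col in .cohortFlags)
        if (col %in% names(out))
            out[[col]] <- as.integer(out[[col]])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = missing)
    invisible(path)
}
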