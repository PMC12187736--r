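## Deterministic 528-patient fixture whose per-variable cross-tabulations
## against burden group reproduce a published baseline-characteristics
## table exactly, missing values included, so the chi-square machinery
## can be checked against printed statistics. Entirely synthetic: the
## only real quantities are the marginal counts.

.table1Counts <- list(
    # per variable: list(low = c(category = count), high = ...); the
    # remainder of each group (267 low / 261 high) is filled with NA
    age = list(low = c("<70" = 221L, ">=70" = 45L),
               high = c("<70" = 190L, ">=70" = 71L)),
    sex = list(low = c(male = 245L, female = 22L),
               high = c(male = 141L, female = 120L)),
    ethnicity = list(low = c(asian = 4L, white = 221L, black = 31L),
                     high = c(asian = 7L, white = 231L, black = 17L)),
    site = list(low = c(hypopharynx = 5L, larynx = 74L,
                        oral_cavity = 109L, oropharynx = 42L),
                high = c(hypopharynx = 5L, larynx = 43L,
                         oral_cavity = 135L, oropharynx = 39L)),
    grade = list(low = c(G1 = 29L, G2 = 148L, "G3-4" = 76L),
                 high = c(G1 = 34L, G2 = 163L, "G3-4" = 56L)),
    pT = list(low = c("T1-2" = 95L, T3 = 62L, T4 = 101L),
              high = c("T1-2" = 94L, T3 = 79L, T4 = 83L)),
    pN = list(low = c(N0 = 126L, N1 = 44L, "N2-3" = 88L),
              high = c(N0 = 123L, N1 = 45L, "N2-3" = 88L)),
    lymphovascular_invasion = list(low = c(no = 115L, yes = 74L),
                                   high = c(no = 117L, yes = 50L)),
    perineural_invasion = list(low = c(no = 113L, yes = 80L),
                               high = c(no = 85L, yes = 92L)),
    stage = list(low = c("I-II" = 59L, III = 48L, IV = 151L),
                 high = c("I-II" = 61L, III = 59L, IV = 136L)))

.fillColumn <- function(counts, nLow, nHigh) {
    mk <- function(cnt, n) {
        v <- rep(names(cnt), cnt)
        c(v, rep(NA_character_, n - length(v)))
    }
    c(mk(counts$low, nLow), mk(counts$high, nHigh))
}

#' Baseline-table fixture cohort
#'
#' A deterministic 528-patient synthetic cohort (267 low burden, 261
#' high) whose cross-tabulation of each clinical variable against burden
#' group reproduces a published head-and-neck baseline table count for
#' count, with missing values inserted so the per-variable totals match.
#' Ages are concrete years (60 for the under-70 class, 75 otherwise) so
#' the age-class derivation is exercised. Survival columns are filled
#' with trivial constants: the fixture drives contingency tests only.
#'
#' @return list: \code{cohort} (data.frame) and \code{burden}
#'   (\linkS4class{BurdenResult} with groups and split value set).
#' @export
makeFixtureTable1 <- function() {
    nLow <- 267L; nHigh <- 261L
    n <- nLow + nHigh
    grp <- factor(rep(c("low", "high"), c(nLow, nHigh)),
                  levels = c("low", "high"))
    ageClass <- .fillColumn(.table1Counts$age, nLow, nHigh)
    cohort <- data.frame(
        patient_id = sprintf("P%03d", seq_len(n)),
        age_years = ifelse(is.na(ageClass), NA_integer_,
                           ifelse(ageClass == "<70", 60L, 75L)),
        stringsAsFactors = FALSE)
    for (v in setdiff(names(.table1Counts), "age")) {
        lev <- names(.table1Counts[[v]]$low)
        cohort[[v]] <- factor(.fillColumn(.table1Counts[[v]], nLow, nHigh),
                              levels = lev)
    }
    cohort$dfs_time <- 1; cohort$dfs_event <- 0L
    cohort$os_time <- 1; cohort$os_event <- 0L
    burden <- BurdenResult(sampleIds = cohort$patient_id,
                           rpmb = ifelse(grp == "low", 0.2, 0.4),
                           nEvaluable = rep(528L, n), nSetGenes = 528L,
                           group = grp, splitValue = 0.3)
    list(cohort = cohort, burden = burden)
}
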