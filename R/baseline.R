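## Cohort selection filters, contingency-table chi-square tests and the
## baseline-characteristics table (burden group x clinical variable).

#' Cohort selection criteria
#'
#' Conjunctive filters mirroring a typical post-operative selection:
#' local disease (fine stage I-IVB), radical surgery, no neoadjuvant
#' therapy, regional node dissection, documented anatomic site, lip
#' tumors excluded, a complete endpoint, and optionally adjuvant RT,
#' concurrent chemotherapy, involved margins / extra-nodal extension and
#' an age ceiling. Each flag can be toggled independently; filters are
#' applied in the order listed and attrition is reported per filter.
#'
#' @param require_local_stage_I_to_IVB fine stage within I..IVB.
#' @param require_radical_surgery,require_no_neoadjuvant,require_node_dissection,require_site_documented,exclude_lip,require_adjuvant_rt,require_concurrent_chemo,require_mism_or_ene logical flags.
#' @param require_endpoint \code{NA}, \code{"DFS"} or \code{"OS"}:
#'   require non-missing time and event for that endpoint.
#' @param max_age keep patients with age strictly below this (NA = off).
#' @return list of class \code{"SelectionCriteria"}.
#' @export
selectionCriteria <- function(require_local_stage_I_to_IVB = FALSE,
                              require_radical_surgery = FALSE,
                              require_no_neoadjuvant = FALSE,
                              require_node_dissection = FALSE,
                              require_site_documented = FALSE,
                              exclude_lip = FALSE,
                              require_endpoint = NA_character_,
                              require_adjuvant_rt = FALSE,
                              require_concurrent_chemo = FALSE,
                              require_mism_or_ene = FALSE,
                              max_age = NA_real_) {
    if (!is.na(require_endpoint))
        require_endpoint <- match.arg(toupper(require_endpoint),
                                      c("DFS", "OS"))
    structure(list(
        require_local_stage_I_to_IVB = require_local_stage_I_to_IVB,
        require_radical_surgery = require_radical_surgery,
        require_no_neoadjuvant = require_no_neoadjuvant,
        require_node_dissection = require_node_dissection,
        require_site_documented = require_site_documented,
        exclude_lip = exclude_lip,
        require_endpoint = require_endpoint,
        require_adjuvant_rt = require_adjuvant_rt,
        require_concurrent_chemo = require_concurrent_chemo,
        require_mism_or_ene = require_mism_or_ene,
        max_age = max_age), class = "SelectionCriteria")
}

.filterDefs <- list(
    require_local_stage_I_to_IVB = list(
        cols = "fine_stage",
        keep = function(d) !is.na(d$fine_stage) &
            d$fine_stage %in% c("I", "II", "III", "IVA", "IVB")),
    require_radical_surgery = list(
        cols = "radical_surgery",
        keep = function(d) !is.na(d$radical_surgery) & d$radical_surgery),
    require_no_neoadjuvant = list(
        cols = "neoadjuvant",
        keep = function(d) !is.na(d$neoadjuvant) & !d$neoadjuvant),
    require_node_dissection = list(
        cols = "node_dissection",
        keep = function(d) !is.na(d$node_dissection) & d$node_dissection),
    require_site_documented = list(
        cols = "site",
        keep = function(d) !is.na(d$site)),
    exclude_lip = list(
        cols = "site",
        keep = function(d) is.na(d$site) | d$site != "lip"),
    require_adjuvant_rt = list(
        cols = "adjuvant_rt",
        keep = function(d) !is.na(d$adjuvant_rt) & d$adjuvant_rt),
    require_concurrent_chemo = list(
        cols = "concurrent_chemo",
        keep = function(d) !is.na(d$concurrent_chemo) & d$concurrent_chemo),
    require_mism_or_ene = list(
        cols = c("mism", "ene"),
        keep = function(d) (!is.na(d$mism) & d$mism == "yes") |
            (!is.na(d$ene) & d$ene == "yes")))

#' Apply cohort selection filters
#'
#' Removes rows failing any active criterion, in the order the criteria
#' are defined, and reports per-filter attrition so the selection can be
#' laid out as a CONSORT-style diagram.
#'
#' @param cohort a cohort data.frame (see [readClinical()]).
#' @param criteria a [selectionCriteria()] object.
#' @return list with \code{cohort} (the filtered table) and
#'   \code{attrition} (data.frame criterion/removed/remaining).
#' @export
applySelectionFilters <- function(cohort, criteria) {
    stopifnot(inherits(criteria, "SelectionCriteria"))
    validateCohort(cohort)
    steps <- character(); removed <- integer(); remaining <- integer()
    note <- function(nm, before, d) {
        steps <<- c(steps, nm)
        removed <<- c(removed, before - nrow(d))
        remaining <<- c(remaining, nrow(d))
    }
    d <- cohort
    for (nm in names(.filterDefs)) {
        if (!isTRUE(criteria[[nm]])) next
        def <- .filterDefs[[nm]]
        missCols <- setdiff(def$cols, names(d))
        if (length(missCols))
            stop("criterion '", nm, "' needs column(s): ",
                 paste(missCols, collapse = ", "))
        before <- nrow(d)
        d <- d[def$keep(d), , drop = FALSE]
        note(nm, before, d)
    }
    if (!is.na(criteria$require_endpoint)) {
        pre <- if (criteria$require_endpoint == "DFS")
            c("dfs_time", "dfs_event") else c("os_time", "os_event")
        before <- nrow(d)
        d <- d[!is.na(d[[pre[1L]]]) & !is.na(d[[pre[2L]]]), , drop = FALSE]
        note(paste0("require_endpoint_", criteria$require_endpoint),
             before, d)
    }
    if (!is.na(criteria$max_age)) {
        if (!"age_years" %in% names(d))
            stop("criterion 'max_age' needs column: age_years")
        before <- nrow(d)
        d <- d[!is.na(d$age_years) & d$age_years < criteria$max_age, ,
               drop = FALSE]
        note("max_age", before, d)
    }
    list(cohort = d,
         attrition = data.frame(criterion = steps, removed = removed,
                                remaining = remaining))
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square with Yates continuity correction when the table
#' is exactly 2x2 and no correction otherwise (the convention needed to
#' reproduce published baseline tables); df = (r-1)(c-1). A zero row or
#' column marginal is an error; an expected count below 1 attaches a
#' warning flag to the result.
#'
#' @param tab integer matrix of counts, at least 2x2.
#' @return list with \code{statistic}, \code{df}, \code{p.value},
#'   \code{correction_applied}, \code{low_expected}.
#' @export
chiSquareTest <- function(tab) {
    tab <- as.matrix(tab)
    if (nrow(tab) < 2L || ncol(tab) < 2L)
        stop("contingency table must be at least 2x2")
    if (any(tab < 0)) stop("counts must be non-negative")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("zero marginal: a row or column has no observations")
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    res <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    list(statistic = unname(res$statistic),
         df = unname(res$parameter),
         p.value = res$p.value,
         correction_applied = nrow(tab) == 2L && ncol(tab) == 2L,
         low_expected = any(expected < 1))
}

## Baseline-table variable definitions: derivation + fixed category order
.baselineVars <- list(
    age = list(label = "Age (years)",
               derive = function(d) factor(
                   ifelse(is.na(d$age_years), NA_character_,
                          ifelse(d$age_years < 70, "<70", ">=70")),
                   levels = c("<70", ">=70"))),
    sex = list(label = "Gender",
               derive = function(d) factor(d$sex,
                   levels = c("male", "female"))),
    ethnicity = list(label = "Ethnicity",
                     derive = function(d) factor(as.character(d$ethnicity),
                         levels = c("asian", "white", "black"))),
    site = list(label = "Location",
                derive = function(d) factor(as.character(d$site),
                    levels = c("hypopharynx", "larynx", "oral_cavity",
                               "oropharynx"))),
    grade = list(label = "Grade",
                 derive = function(d) factor(d$grade,
                     levels = c("G1", "G2", "G3-4"))),
    pT = list(label = "pT",
              derive = function(d) factor(d$pT,
                  levels = c("T1-2", "T3", "T4"))),
    pN = list(label = "pN",
              derive = function(d) factor(d$pN,
                  levels = c("N0", "N1", "N2-3"))),
    lymphovascular_invasion = list(label = "Lymphovascular invasion",
        derive = function(d) factor(d$lymphovascular_invasion,
            levels = c("no", "yes"))),
    perineural_invasion = list(label = "Perineural invasion",
        derive = function(d) factor(d$perineural_invasion,
            levels = c("no", "yes"))),
    stage = list(label = "Stage",
                 derive = function(d) factor(d$stage,
                     levels = c("I-II", "III", "IV"))))

#' Baseline-characteristics table with chi-square tests
#'
#' Cross-tabulates the low/high burden groups against each requested
#' clinical variable and tests the association with [chiSquareTest()].
#' Each variable is analysed on its complete cases (rows missing that
#' variable are dropped for that variable only), with category order
#' fixed by the variable definition. Variables with a single observed
#' category are returned as non-evaluable.
#'
#' @param cohort a cohort data.frame.
#' @param burden a \linkS4class{BurdenResult} with groups assigned;
#'   \code{sampleIds(burden)} must match \code{cohort$patient_id}.
#' @param variables character vector drawn from \code{age}, \code{sex},
#'   \code{ethnicity}, \code{site}, \code{grade}, \code{pT}, \code{pN},
#'   \code{lymphovascular_invasion}, \code{perineural_invasion},
#'   \code{stage}.
#' @return named list, one entry per variable: \code{table} (counts,
#'   rows = low/high), \code{test} (chi-square result or \code{NULL}),
#'   \code{evaluable}.
#' @seealso [baselineDataFrame()] for a serializable form.
#' @export
baselineTable <- function(cohort, burden,
                          variables = names(.baselineVars)) {
    stopifnot(is(burden, "BurdenResult"))
    unknown <- setdiff(variables, names(.baselineVars))
    if (length(unknown))
        stop("unknown baseline variable(s): ",
             paste(unknown, collapse = ", "))
    grp <- burdenGroups(burden)[match(cohort$patient_id,
                                      sampleIds(burden))]
    if (all(is.na(grp)))
        stop("no cohort patient has a burden group assigned")
    out <- list()
    for (v in variables) {
        val <- .baselineVars[[v]]$derive(cohort)
        keep <- !is.na(val) & !is.na(grp)
        tab <- table(group = factor(grp[keep], levels = c("low", "high")),
                     value = val[keep])
        tab <- tab[, colSums(tab) > 0L, drop = FALSE]
        evaluable <- ncol(tab) >= 2L && all(rowSums(tab) > 0L)
        out[[v]] <- list(
            table = tab,
            test = if (evaluable) chiSquareTest(tab) else NULL,
            evaluable = evaluable)
    }
    out
}

#' Flatten a baseline table to a data.frame
#'
#' @param x result of [baselineTable()].
#' @return data.frame: \code{variable}, \code{category}, \code{low},
#'   \code{high}, \code{statistic}, \code{df}, \code{p.value} (test
#'   columns repeated on the variable's first row only).
#' @export
baselineDataFrame <- function(x) {
    rows <- lapply(names(x), function(v) {
        e <- x[[v]]
        k <- ncol(e$table)
        data.frame(variable = v,
                   category = colnames(e$table),
                   low = as.integer(e$table["low", ]),
                   high = as.integer(e$table["high", ]),
                   statistic = c(if (e$evaluable) e$test$statistic
                                 else NA_real_, rep(NA_real_, k - 1L)),
                   df = c(if (e$evaluable) e$test$df else NA_real_,
                          rep(NA_real_, k - 1L)),
                   p.value = c(if (e$evaluable) e$test$p.value
                               else NA_real_, rep(NA_real_, k - 1L)))
    })
    do.call(rbind, rows)
}
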