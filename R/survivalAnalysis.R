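## Kaplan-Meier / log-rank comparison, univariate Cox models (Efron
## ties), the median-split subgroup forest and the univariate Cox table.
## All survival times are in years.

#' @importFrom survival Surv survfit survdiff coxph
NULL

.endpointCols <- function(endpoint) {
    endpoint <- match.arg(toupper(endpoint), c("DFS", "OS"))
    if (endpoint == "DFS") c("dfs_time", "dfs_event")
    else c("os_time", "os_event")
}

#' Kaplan-Meier curves with log-rank test and median survival
#'
#' Product-limit estimate per group, two-group log-rank chi-square (1 df)
#' and p-value, and per-group median survival with a 95% confidence
#' interval from the complementary log-log transform of the curve. The
#' median is the earliest time at which the curve drops to 0.5 or below;
#' a CI bound (or the median itself) is \code{Inf} when the curve (or its
#' confidence band) never reaches 0.5.
#'
#' @param time numeric, survival times (years, >= 0).
#' @param event integer 0/1 event indicators.
#' @param group factor/character with the group of each observation.
#' @return list of class \code{"KMResult"}: \code{curves} (data.frame
#'   group/time/surv/lower/upper), \code{medians} (data.frame
#'   group/n/events/median/lower/upper), \code{chisq}, \code{df},
#'   \code{p.value} (\code{NA} with \code{zeroEvents = TRUE} when no
#'   event occurred).
#' @export
kmLogrank <- function(time, event, group) {
    stopifnot(length(time) == length(event),
              length(time) == length(group))
    if (any(is.na(time)) || any(time < 0))
        stop("times must be non-negative and non-missing")
    group <- droplevels(factor(group))
    if (nlevels(group) < 2L || any(table(group) == 0L))
        stop("kmLogrank needs >= 2 non-empty groups")
    fit <- survfit(Surv(time, event) ~ group, conf.type = "log-log")
    qt <- stats::quantile(fit, probs = 0.5)
    medians <- data.frame(
        group = sub("^group=", "", rownames(qt$quantile)),
        n = summary(fit)$table[, "records"],
        events = summary(fit)$table[, "events"],
        median = ifelse(is.na(qt$quantile[, 1L]), Inf, qt$quantile[, 1L]),
        lower = ifelse(is.na(qt$lower[, 1L]), Inf, qt$lower[, 1L]),
        upper = ifelse(is.na(qt$upper[, 1L]), Inf, qt$upper[, 1L]),
        row.names = NULL)
    curves <- data.frame(
        group = rep(sub("^group=", "", names(fit$strata)),
                    fit$strata),
        time = fit$time, surv = fit$surv,
        lower = fit$lower, upper = fit$upper)
    zeroEvents <- sum(event) == 0L
    if (zeroEvents) {
        chisq <- NA_real_; p <- NA_real_; df <- nlevels(group) - 1L
    } else {
        sd <- survdiff(Surv(time, event) ~ group)
        chisq <- sd$chisq
        df <- length(sd$n) - 1L
        p <- stats::pchisq(chisq, df, lower.tail = FALSE)
    }
    structure(list(curves = curves, medians = medians, chisq = chisq,
                   df = df, p.value = p, zeroEvents = zeroEvents),
              class = "KMResult")
}

#' @export
print.KMResult <- function(x, ...) {
    cat("Kaplan-Meier comparison of", nrow(x$medians), "groups\n")
    print(x$medians, row.names = FALSE)
    if (x$zeroEvents) cat("  no events: log-rank p undefined\n")
    else cat(sprintf("  log-rank chisq = %.3f (df = %d), p = %.4g\n",
                     x$chisq, x$df, x$p.value))
    invisible(x)
}

#' Univariate Cox proportional-hazards model
#'
#' Partial-likelihood fit with the Efron tie approximation. For each
#' non-reference level of the covariate the hazard ratio, Wald 95%
#' confidence interval and Wald p-value are reported. A level with zero
#' events (monotone likelihood) makes the contrast non-estimable and is
#' flagged rather than reported as a divergent estimate.
#'
#' @param time,event survival times and 0/1 event indicators.
#' @param covariate factor/character covariate (>= 2 observed levels).
#' @param reference reference level; default the covariate's first level.
#' @return data.frame, one row per non-reference level: \code{level},
#'   \code{reference}, \code{n}, \code{n_events}, \code{hr},
#'   \code{ci_lower}, \code{ci_upper}, \code{p.value}, \code{estimable}.
#' @export
coxUnivariate <- function(time, event, covariate, reference = NULL) {
    keep <- !is.na(time) & !is.na(event) & !is.na(covariate)
    time <- time[keep]; event <- event[keep]
    covariate <- droplevels(factor(covariate[keep]))
    if (nlevels(covariate) < 2L)
        stop("covariate has a single observed level: no contrast to fit")
    if (!is.null(reference))
        covariate <- stats::relevel(covariate, ref = reference)
    ref <- levels(covariate)[1L]
    eventsByLevel <- tapply(event, covariate, sum)
    estimable <- eventsByLevel > 0L
    lev <- levels(covariate)[-1L]
    out <- data.frame(level = lev, reference = ref,
                      n = as.integer(table(covariate)[lev]),
                      n_events = as.integer(eventsByLevel[lev]),
                      hr = NA_real_, ci_lower = NA_real_,
                      ci_upper = NA_real_, p.value = NA_real_,
                      estimable = estimable[lev] & estimable[[ref]])
    if (any(out$estimable)) {
        fit <- coxph(Surv(time, event) ~ covariate, ties = "efron")
        s <- summary(fit)
        cn <- paste0("covariate", lev)
        beta <- s$coefficients[cn, "coef"]
        se <- s$coefficients[cn, "se(coef)"]
        ok <- out$estimable
        out$hr[ok] <- exp(beta)[ok]
        out$ci_lower[ok] <- exp(beta - 1.96 * se)[ok]
        out$ci_upper[ok] <- exp(beta + 1.96 * se)[ok]
        out$p.value[ok] <- s$coefficients[cn, "Pr(>|z|)"][ok]
    }
    out
}

#' Subgroup forest analysis of burden effect
#'
#' For every level of every stratification factor, restricts the cohort
#' to that subgroup, re-assigns low/high burden at the subgroup's own
#' median RPMB (or reuses the cohort-wide split with
#' \code{globalSplit = TRUE}), and fits a univariate Cox model of high vs
#' low burden on the chosen endpoint. Subgroups with fewer than
#' \code{minN} patients are excluded (flagged, no estimate), as are
#' subgroups with a degenerate burden split or a non-estimable fit.
#'
#' @param cohort a cohort data.frame.
#' @param burden a \linkS4class{BurdenResult} scored on the same
#'   patients.
#' @param endpoint \code{"DFS"} or \code{"OS"}.
#' @param factors character vector of cohort column names (factor-like)
#'   defining the subgroups.
#' @param minN minimum subgroup size (default 30).
#' @param globalSplit reuse the cohort-wide median split instead of
#'   re-splitting within each subgroup.
#' @return data.frame of class \code{"ForestTable"}: \code{factor},
#'   \code{level}, \code{n}, \code{n_events}, \code{hr}, \code{ci_lower},
#'   \code{ci_upper}, \code{p.value}, \code{excluded}, \code{reason}.
#' @export
subgroupForest <- function(cohort, burden, endpoint = "DFS", factors,
                           minN = 30L, globalSplit = FALSE) {
    stopifnot(is(burden, "BurdenResult"))
    cols <- .endpointCols(endpoint)
    miss <- setdiff(factors, names(cohort))
    if (length(miss))
        stop("unknown factor column(s): ", paste(miss, collapse = ", "))
    rpmb <- rpmbValues(burden)[match(cohort$patient_id,
                                     sampleIds(burden))]
    globalGroup <- burdenGroups(burden)[match(cohort$patient_id,
                                              sampleIds(burden))]
    rows <- list()
    emit <- function(factor, level, n, nEvents = NA_integer_,
                     hr = NA_real_, lo = NA_real_, hi = NA_real_,
                     p = NA_real_, excluded = FALSE, reason = "") {
        rows[[length(rows) + 1L]] <<- data.frame(
            factor = factor, level = level, n = n, n_events = nEvents,
            hr = hr, ci_lower = lo, ci_upper = hi, p.value = p,
            excluded = excluded, reason = reason)
    }
    for (f in factors) {
        vals <- cohort[[f]]
        for (lev in levels(droplevels(factor(vals)))) {
            idx <- which(!is.na(vals) & vals == lev &
                         !is.na(cohort[[cols[1L]]]) &
                         !is.na(cohort[[cols[2L]]]) & !is.na(rpmb))
            n <- length(idx)
            if (n < minN) {
                emit(f, lev, n, excluded = TRUE,
                     reason = sprintf("n < %d", minN))
                next
            }
            grp <- if (globalSplit) {
                globalGroup[idx]
            } else {
                med <- stats::median(rpmb[idx])
                if (all(rpmb[idx] == med)) {
                    emit(f, lev, n, excluded = TRUE,
                         reason = "degenerate burden split")
                    next
                }
                factor(ifelse(rpmb[idx] <= med, "low", "high"),
                       levels = c("low", "high"))
            }
            if (any(table(grp) == 0L)) {
                emit(f, lev, n, excluded = TRUE,
                     reason = "single burden group")
                next
            }
            fit <- coxUnivariate(cohort[[cols[1L]]][idx],
                                 cohort[[cols[2L]]][idx], grp,
                                 reference = "low")
            if (!fit$estimable[1L]) {
                emit(f, lev, n, excluded = TRUE,
                     reason = "non-estimable (a group has no events)")
                next
            }
            emit(f, lev, n, sum(cohort[[cols[2L]]][idx]),
                 fit$hr[1L], fit$ci_lower[1L], fit$ci_upper[1L],
                 fit$p.value[1L])
        }
    }
    structure(do.call(rbind, rows), class = c("ForestTable",
                                              "data.frame"))
}

#' Univariate Cox table over several factors
#'
#' One univariate Cox fit per factor on the chosen endpoint, each level
#' contrasted against the factor's reference (first) level — the layout
#' of a published univariate-analysis table. The burden group can be
#' included by passing \code{burden}; it appears as factor
#' \code{"rpmb_group"} with reference \code{"low"}.
#'
#' @param cohort a cohort data.frame (typically after
#'   [applySelectionFilters()]).
#' @param factors character vector of cohort column names.
#' @param endpoint \code{"DFS"} or \code{"OS"}.
#' @param burden optional \linkS4class{BurdenResult} with groups.
#' @return data.frame: \code{factor}, \code{level}, \code{reference},
#'   \code{n}, \code{n_events}, \code{hr}, \code{ci_lower},
#'   \code{ci_upper}, \code{p.value}, \code{estimable}.
#' @export
coxTable <- function(cohort, factors, endpoint = "DFS", burden = NULL) {
    cols <- .endpointCols(endpoint)
    d <- cohort
    if (!is.null(burden)) {
        stopifnot(is(burden, "BurdenResult"))
        d$rpmb_group <- burdenGroups(burden)[match(d$patient_id,
                                                   sampleIds(burden))]
        factors <- c(factors, "rpmb_group")
    }
    miss <- setdiff(factors, names(d))
    if (length(miss))
        stop("unknown factor column(s): ", paste(miss, collapse = ", "))
    rows <- lapply(factors, function(f) {
        keep <- !is.na(d[[cols[1L]]]) & !is.na(d[[cols[2L]]]) &
            !is.na(d[[f]])
        v <- droplevels(factor(d[[f]][keep]))
        if (nlevels(v) < 2L)
            return(data.frame(factor = f, level = NA_character_,
                              reference = levels(v)[1L] %||% NA_character_,
                              n = sum(keep), n_events = NA_integer_,
                              hr = NA_real_, ci_lower = NA_real_,
                              ci_upper = NA_real_, p.value = NA_real_,
                              estimable = FALSE))
        fit <- coxUnivariate(d[[cols[1L]]][keep], d[[cols[2L]]][keep], v)
        cbind(factor = f, fit)
    })
    do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a
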