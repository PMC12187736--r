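# independent oracles: product-limit recomputation and the
# hypergeometric-sum log-rank statistic
plOracle <- function(time, event) {
    ts <- sort(unique(time[event == 1]))
    s <- 1
    vapply(ts, function(t) {
        d <- sum(time == t & event == 1)
        n <- sum(time >= t)
        s <<- s * (1 - d / n)
        s
    }, numeric(1))
}
logrankOracle <- function(time, event, group) {
    g1 <- levels(factor(group))[1]
    O <- 0; E <- 0; V <- 0
    for (t in sort(unique(time[event == 1]))) {
        atRisk <- time >= t
        n <- sum(atRisk); n1 <- sum(atRisk & group == g1)
        d <- sum(time == t & event == 1)
        d1 <- sum(time == t & event == 1 & group == g1)
        O <- O + d1
        E <- E + d * n1 / n
        if (n > 1)
            V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
}

test_that("KM curves equal the product-limit recomputation", {
    # worked case: times 1,2,3 all events -> S = 2/3, 1/3, 0 per group
    km <- kmLogrank(time = c(1, 2, 3, 1, 2, 3),
                    event = rep(1L, 6),
                    group = rep(c("low", "high"), each = 3))
    for (g in c("low", "high")) {
        cu <- km$curves[km$curves$group == g, ]
        expect_equal(cu$surv, c(2 / 3, 1 / 3, 0))
    }
    # identical groups: log-rank 0, p 1
    expect_equal(km$chisq, 0, tolerance = 1e-12)
    expect_equal(km$p.value, 1, tolerance = 1e-12)

    # random fixtures against the oracle
    withr::local_seed(44)
    for (i in 1:10) {
        n <- sample(10:50, 1)
        time <- round(rexp(n, 0.5), 2)
        event <- rbinom(n, 1, 0.7)
        group <- factor(sample(c("low", "high"), n, TRUE),
                        levels = c("low", "high"))
        if (sum(event) == 0 || any(table(group) == 0)) next
        km <- kmLogrank(time, event, group)
        for (g in levels(group)) {
            want <- plOracle(time[group == g], event[group == g])
            got <- km$curves$surv[km$curves$group == g &
                                  km$curves$time %in%
                                      time[group == g & event == 1]]
            expect_equal(got, want)
        }
        expect_equal(km$chisq, logrankOracle(time, event, group),
                     tolerance = 1e-8)
    }
})

test_that("six-patient worked set matches the hypergeometric oracle", {
    time <- c(1, 2, 3, 4, 5, 6)
    event <- rep(1L, 6)
    group <- rep(c("A", "B"), each = 3)
    km <- kmLogrank(time, event, group)
    expect_equal(km$chisq, logrankOracle(time, event, group),
                 tolerance = 1e-10)
    expect_equal(km$p.value, pchisq(km$chisq, 1, lower.tail = FALSE))
})

test_that("median survival and CI use the curve, with +Inf when open", {
    km <- kmLogrank(c(1, 2, 3, 1, 2, 3), rep(1L, 6),
                    rep(c("low", "high"), each = 3))
    expect_equal(km$medians$median, c(2, 2))  # first time with S <= 0.5
    # heavy censoring: the curve never reaches 0.5 -> open median and CI
    km2 <- kmLogrank(time = c(rep(5, 9), 1, rep(5, 9), 1),
                     event = c(rep(0L, 9), 1L, rep(0L, 9), 1L),
                     group = rep(c("low", "high"), each = 10))
    expect_true(all(is.infinite(km2$medians$median)))
    expect_true(all(is.infinite(km2$medians$upper)))
    # degenerate inputs
    expect_error(kmLogrank(1:3, rep(1L, 3), rep("low", 3)),
                 "2 non-empty groups")
    km0 <- kmLogrank(c(1, 2), c(0L, 0L), c("low", "high"))
    expect_true(km0$zeroEvents)
    expect_true(is.na(km0$p.value))
})

test_that("log-rank p agrees with the Cox score test on untied data", {
    withr::local_seed(9)
    time <- rexp(80); event <- rbinom(80, 1, 0.8)
    group <- factor(rep(c("low", "high"), 40), levels = c("low", "high"))
    km <- kmLogrank(time, event, group)
    fit <- survival::coxph(survival::Surv(time, event) ~ group)
    expect_equal(km$p.value, summary(fit)$sctest[["pvalue"]],
                 tolerance = 1e-6)
})

test_that("univariate Cox reports HR with Wald CI, flags degeneracy", {
    expect_error(coxUnivariate(1:4, c(1L, 1L, 0L, 1L),
                               rep("a", 4)), "single observed level")
    # relabelling the reference inverts the hazard ratio
    withr::local_seed(10)
    d <- simulateSurvivalTwoGroup(120, hr = 2, seed = 10)
    f1 <- coxUnivariate(d$time, d$event, d$group, reference = "low")
    f2 <- coxUnivariate(d$time, d$event, d$group, reference = "high")
    expect_equal(f1$hr, 1 / f2$hr)
    expect_equal(f1$p.value, f2$p.value, tolerance = 1e-9)
    expect_true(f1$ci_lower < f1$hr && f1$hr < f1$ci_upper)
    # a level with no events is non-estimable, not divergent
    time <- c(rexp(20), rep(2, 5))
    event <- c(rep(1L, 20), rep(0L, 5))
    grp <- rep(c("low", "high"), c(20, 5))
    fit <- coxUnivariate(time, event, grp, reference = "low")
    expect_false(fit$estimable)
    expect_true(is.na(fit$hr))
})

test_that("Cox recovers a known hazard ratio", {
    d <- simulateSurvivalTwoGroup(1000, hr = 2, censoringRate = 0,
                                  seed = 77)
    fit <- coxUnivariate(d$time, d$event, d$group, reference = "low")
    expect_gt(fit$hr, 1.7)
    expect_lt(fit$hr, 2.35)
})

test_that("subgroup forest re-splits, excludes small subgroups", {
    withr::local_seed(12)
    n <- 120
    ids <- sprintf("P%03d", 1:n)
    rpmb <- runif(n)
    b <- burdenWithGroups(ids, rpmb,
                          ifelse(rpmb <= median(rpmb), "low", "high"))
    cohort <- minimalCohort(
        n,
        sex = factor(sample(c("male", "female"), n, TRUE, c(0.9, 0.1)),
                     levels = c("male", "female")),
        whole = factor(rep("all", n)))
    cohort$dfs_time <- rexp(n)
    cohort$dfs_event <- rbinom(n, 1, 0.7)
    ft <- subgroupForest(cohort, b, "DFS", c("sex", "whole"), minN = 30)
    small <- ft[ft$factor == "sex" & ft$level == "female", ]
    expect_true(small$excluded)
    expect_true(is.na(small$hr))
    expect_match(small$reason, "n < 30")
    # a factor covering the whole cohort reproduces the overall fit
    overall <- coxUnivariate(cohort$dfs_time, cohort$dfs_event,
                             burdenGroups(b)[ids], reference = "low")
    row <- ft[ft$factor == "whole", ]
    expect_equal(row$hr, overall$hr)
    expect_equal(row$p.value, overall$p.value)
    # global-split mode reuses the cohort-wide assignment (here equal)
    ftg <- subgroupForest(cohort, b, "DFS", "whole", minN = 30,
                          globalSplit = TRUE)
    expect_equal(ftg$hr, overall$hr)
})

test_that("cox table rows match standalone univariate fits", {
    withr::local_seed(13)
    n <- 100
    cohort <- minimalCohort(
        n,
        sex = factor(sample(c("male", "female"), n, TRUE),
                     levels = c("male", "female")),
        grade = factor(sample(c("G1", "G2", "G3-4"), n, TRUE),
                       levels = c("G1", "G2", "G3-4")))
    cohort$dfs_time <- rexp(n)
    cohort$dfs_event <- rbinom(n, 1, 0.6)
    b <- burdenWithGroups(cohort$patient_id, runif(n),
                          sample(c("low", "high"), n, TRUE))
    tab <- coxTable(cohort, c("sex", "grade"), "DFS", burden = b)
    expect_identical(unique(tab$factor), c("sex", "grade", "rpmb_group"))
    expect_equal(nrow(tab), 1 + 2 + 1)  # binary + 3-level + burden
    alone <- coxUnivariate(cohort$dfs_time, cohort$dfs_event, cohort$sex)
    expect_equal(tab$hr[tab$factor == "sex"], alone$hr)
    expect_equal(tab$p.value[tab$factor == "sex"], alone$p.value)
    expect_identical(tab$reference[tab$factor == "rpmb_group"], "low")
    # a factor with only its reference level observed is flagged
    cohort$const <- factor(rep("x", n))
    tab2 <- coxTable(cohort, "const", "DFS")
    expect_false(tab2$estimable)
})
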