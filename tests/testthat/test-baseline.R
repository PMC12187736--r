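# independent Yates closed form: sum (|O-E| - 0.5)^2 / E
yatesOracle <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum(pmax(abs(tab - E) - 0.5, 0)^2 / E)
}

test_that("chi-square uses Yates on 2x2 and plain Pearson otherwise", {
    r <- chiSquareTest(matrix(c(221, 45, 190, 71), 2))
    expect_equal(r$statistic, 7.531, tolerance = 1e-3)
    expect_true(r$correction_applied)
    expect_equal(r$df, 1)

    flat <- chiSquareTest(matrix(c(10, 10, 10, 10), 2))
    expect_equal(flat$statistic, 0)
    expect_equal(flat$p.value, 1)

    r23 <- chiSquareTest(matrix(c(126, 44, 88, 123, 45, 88), 3))
    expect_lt(abs(r23$statistic - 0.040), 1e-3)
    expect_false(r23$correction_applied)
    expect_equal(r23$df, 2)

    expect_error(chiSquareTest(matrix(c(1, 2, 0, 0), 2)), "zero marginal")
    expect_true(chiSquareTest(matrix(c(1, 1, 1, 20), 2))$low_expected)
})

test_that("2x2 statistic equals the Yates closed form, rows swappable", {
    withr::local_seed(17)
    for (i in 1:20) {
        tab <- matrix(sample(5:200, 4), 2)
        r <- chiSquareTest(tab)
        expect_equal(r$statistic, yatesOracle(tab))
        expect_equal(chiSquareTest(tab[2:1, ])$statistic, r$statistic)
    }
})

test_that("selection filters remove rows conjunctively with attrition", {
    cohort <- minimalCohort(
        10,
        site = factor(c(rep("lip", 3), rep("larynx", 7)),
                      levels = MethylBurden:::.cohortEnums$site),
        neoadjuvant = c(rep(FALSE, 8), TRUE, TRUE),
        radical_surgery = rep(TRUE, 10))
    # empty criteria: identity
    out <- applySelectionFilters(cohort, selectionCriteria())
    expect_identical(out$cohort, cohort)
    expect_equal(nrow(out$attrition), 0)
    # lip exclusion removes exactly the lip rows
    out <- applySelectionFilters(cohort,
                                 selectionCriteria(exclude_lip = TRUE))
    expect_equal(nrow(out$cohort), 7)
    expect_equal(out$attrition$removed, 3)
    # conjunctive filters, attrition per filter in order
    crit <- selectionCriteria(require_no_neoadjuvant = TRUE,
                              exclude_lip = TRUE)
    out <- applySelectionFilters(cohort, crit)
    expect_equal(out$attrition$criterion,
                 c("require_no_neoadjuvant", "exclude_lip"))
    expect_equal(out$attrition$removed, c(2, 3))
    expect_equal(out$attrition$remaining, c(8, 5))
    expect_equal(nrow(out$cohort), 5)
    # referencing an absent column errors
    expect_error(applySelectionFilters(
        cohort, selectionCriteria(require_adjuvant_rt = TRUE)),
        "adjuvant_rt")
})

test_that("endpoint and age criteria filter on completeness and age", {
    cohort <- minimalCohort(6, age_years = c(50, 72, 68, 80, 55, 60))
    cohort$dfs_time[1] <- NA
    out <- applySelectionFilters(
        cohort, selectionCriteria(require_endpoint = "DFS"))
    expect_equal(nrow(out$cohort), 5)
    out <- applySelectionFilters(cohort, selectionCriteria(max_age = 70))
    expect_equal(nrow(out$cohort), 4)
})

test_that("baseline table is per-variable complete-case with fixed order", {
    fx <- makeFixtureTable1()
    bt <- baselineTable(fx$cohort, fx$burden,
                        c("age", "site", "lymphovascular_invasion"))
    # complete-case totals differ per variable
    expect_equal(sum(bt$age$table), 527)
    expect_equal(sum(bt$site$table), 452)
    expect_equal(sum(bt$lymphovascular_invasion$table), 356)
    expect_identical(colnames(bt$site$table),
                     c("hypopharynx", "larynx", "oral_cavity",
                       "oropharynx"))
    expect_identical(rownames(bt$age$table), c("low", "high"))
    # empty variable list -> empty result
    expect_length(baselineTable(fx$cohort, fx$burden, character(0)), 0)
    # single observed category -> non-evaluable
    cohort <- minimalCohort(6, sex = factor(rep("male", 6),
                                            levels = c("male", "female")))
    b <- burdenWithGroups(cohort$patient_id, seq(0.1, 0.6, 0.1),
                          rep(c("low", "high"), 3))
    bt1 <- baselineTable(cohort, b, "sex")
    expect_false(bt1$sex$evaluable)
    expect_null(bt1$sex$test)
    # serializable form carries counts and the test on the first row
    df <- baselineDataFrame(bt)
    expect_equal(df$low[df$variable == "age"], c(221, 45))
    expect_equal(df$statistic[df$variable == "age" &
                              df$category == "<70"],
                 7.531, tolerance = 1e-3)
})

test_that("balanced random categories stay non-significant", {
    # null calibration: with categories independent of burden, tests at
    # the 0.001 level should essentially never fire
    withr::local_seed(77)
    worst <- replicate(20, {
        n <- 500
        ids <- sprintf("P%03d", 1:n)
        b <- burdenWithGroups(ids, seq_len(n) / n,
                              rep(c("low", "high"), each = n / 2))
        cohort <- minimalCohort(
            n,
            sex = factor(sample(c("male", "female"), n, TRUE),
                         levels = c("male", "female")),
            grade = factor(sample(c("G1", "G2", "G3-4"), n, TRUE),
                           levels = c("G1", "G2", "G3-4")))
        bt <- baselineTable(cohort, b, c("sex", "grade"))
        min(sapply(bt, function(e) e$test$p.value))
    })
    expect_gte(mean(worst > 0.001), 0.95)
})
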