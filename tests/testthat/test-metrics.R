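# Performance metrics: predictive values, incidence, sweat-test accounting,
# contact-age summaries, report assembly and printed-count reproduction.

test_that("predictive values match their definitions and rounding", {
    expect_equal(ppv(57, 77)[["rounded"]], 74)
    expect_equal(ppv(57, 77)[["raw"]], 100 * 57 / 77)
    expect_equal(ppv(0, 10)[["rounded"]], 0)
    expect_equal(ppv(10, 34)[["rounded"]], 29)
    expect_equal(ppv(13, 34)[["rounded"]], 38)
    expect_error(ppv(1, 0), "undefined")
    expect_error(ppv(5, 3), "<=")

    expect_equal(npv(1151, 1151)[["rounded"]], 100)
    expect_equal(npv(1148, 1151)[["rounded"]], 99.7)
    expect_equal(npv(0, 5)[["rounded"]], 0)
    expect_error(npv(1, 0), "undefined")
})

test_that("ratio metrics agree with naive one-line oracles", {
    set.seed(37)
    for (i in 1:1000) {
        sp <- sample(1:500, 1)
        tp <- sample(0:sp, 1)
        expect_identical(ppv(tp, sp)[["raw"]], 100 * tp / sp)
        expect_identical(npv(tp, sp)[["raw"]], 100 * tp / sp)
        cases <- sample(1:sp, 1)
        expect_identical(falseNegativeRate(min(tp, cases), cases)[["raw"]],
                         100 * min(tp, cases) / cases)
    }
})

test_that("incidence denominators reproduce the published arithmetic", {
    expect_equal(incidenceDenominator(76, 401977), 5289L)
    expect_equal(incidenceDenominator(104, 401977), 3865L)
    expect_equal(incidenceDenominator(1, 1), 1L)
    expect_error(incidenceDenominator(0, 100), "undefined")
})

test_that("sweat-test accounting follows the stated formula", {
    expect_equal(sweatTestsAvoided(880, 115, 271), 1036)
    expect_equal(sweatTestsAvoided(0, 0, 0), 0)
    expect_equal(sweatTestsAvoided(10, 10, 5), 5)
    expect_error(sweatTestsAvoided(-1, 0, 0), "non-negative")
    expect_error(sweatTestsAvoided(5, 10, 0), "cannot exceed")
})

test_that("false-negative rates use the all-cases denominator", {
    expect_equal(falseNegativeRate(6, 76)[["rounded"]], 7.9)
    expect_equal(falseNegativeRate(9, 104)[["rounded"]], 8.7)
    expect_equal(falseNegativeRate(0, 76)[["rounded"]], 0)
    expect_error(falseNegativeRate(1, 0), "undefined")
})

test_that("contact-age summaries report both median conventions", {
    s <- summarizeContactAges(c(10, 22, 50))
    expect_equal(unname(s[c("median", "min", "max")]), c(22, 10, 50))
    s <- summarizeContactAges(c(12, 31, 31, 39))
    expect_equal(unname(s["median"]), 31)
    expect_equal(unname(s["median_low"]), 31)
    s <- summarizeContactAges(25)
    expect_equal(unname(s), c(25, 25, 25, 25))
    # lower-of-middle vs interpolated at even length
    s <- summarizeContactAges(c(10, 20, 30, 40))
    expect_equal(unname(s["median"]), 25)
    expect_equal(unname(s["median_low"]), 20)
    expect_error(summarizeContactAges(numeric()), "empty")

    byArm <- summarizeContactAges(c(10, 22, 50, 15, NA),
                                  c("a", "a", "a", "b", "b"))
    expect_equal(byArm$median[byArm$arm == "a"], 22)
    expect_equal(byArm$n[byArm$arm == "overall"], 4)
})

test_that("the one-mutation referral denominator is uniquely reconstructed", {
    expect_equal(reconstructReferralDenominator(10, 13, 29, 38), 34)
    # uniqueness over the scanned range is part of the contract
    expect_error(reconstructReferralDenominator(10, 13, 29, 38,
                                                candidates = 100:120),
                 "exactly one")
})

test_that("printed programme counts are reproduced from the fixture", {
    comparison <- reproducePrintedCounts()
    expect_true(attr(comparison, "all_pass"))
    expect_true(all(comparison$pass[!is.na(comparison$pass)]))
    get <- function(q) comparison$computed[comparison$quantity == q]
    expect_equal(get("ppv_two_mut_cf_pct"), 74)
    expect_equal(get("ppv_two_mut_all_pct"), 100)
    expect_equal(get("optional_sweat_uptake_pct"), 13)
    expect_equal(get("sweat_tests_avoided"), 1036)
    expect_equal(get("npv_day21_cf_pct"), 100)
    expect_equal(get("npv_day21_cfspid_pct"), 99.7)
    expect_equal(get("incidence_denominator_cf"), 5289)
    expect_equal(get("incidence_denominator_all"), 3865)
    expect_equal(get("total_cases_cf"), 76)
    expect_equal(get("total_cases_all"), 104)
    expect_equal(get("true_positive_cf_sum"), 70)
    expect_equal(get("true_positive_all_sum"), 95)

    broken <- printedCounts()
    broken$carriers_normal_irt2 <- NULL
    expect_error(reproducePrintedCounts(broken), "carriers_normal_irt2")
})

test_that("report assembly checks partitions and assembles all metrics", {
    pop <- defaultPopulation()
    co <- generateCohort(100000, pop, seed = 41)
    res <- runProgram(co, bundledPanels()$panel130, config = pop, seed = 41)
    lab <- labelCohort(co, res, pop)
    rep <- buildReport(lab)
    expect_s4_class(rep, "PerformanceReport")
    expect_equal(rep@nScreened, 100000)
    expect_equal(sum(rep@armCounts$count), 100000)

    # two-mutation arm PPV for CF between 50% and 100% at defaults
    ppv2 <- rep@ppvByArm$ppv_cf[rep@ppvByArm$arm == "positive_two_mutations"]
    expect_gte(ppv2, 50)
    expect_lte(ppv2, 100)
    expect_equal(rep@ppvByArm$ppv_all[rep@ppvByArm$arm ==
                                      "positive_two_mutations"], 100)

    # sensitivity and false-negative rate are complementary
    expect_equal(rep@sensitivity[["cf"]],
                 100 - rep@falseNegativeRate[["cf"]])
    expect_equal(rep@sensitivity[["all"]],
                 100 - rep@falseNegativeRate[["all"]])

    # a case with a missing channel violates the partition
    bad <- lab
    bad$detection_channel[which(bad$true_status == "cf")[1]] <- NA
    expect_error(buildReport(bad), "partition violation")

    # all-zero-case cohort still yields a report with flagged undefined PPVs
    pop0 <- tinyPopulation(pCfOn = 0, pVu = 0, pCfOff = 0, batch = 50L)
    co0 <- generateCohort(500, pop0, seed = 2)
    lab0 <- labelCohort(co0, runProgram(co0, tinyPanel(), config = pop0),
                        pop0)
    rep0 <- buildReport(lab0)
    expect_true(any(grepl("zero CF cases", rep0@checks)))
    expect_true(is.na(rep0@incidenceDenominator[["cf"]]))
})

test_that("sweat tests avoided decrease as optional uptake rises", {
    pop <- defaultPopulation()
    co <- generateCohort(30000, pop, seed = 43)
    panel <- bundledPanels()$panel130
    avoided <- vapply(c(0, 0.13, 0.5, 1), function(u) {
        th <- algorithmThresholds(optionalSweatUptake = u)
        res <- runProgram(co, panel, th, pop, seed = 43)
        sweatTestsAvoided(
            sum(res$arm %in% c("low_risk_optional_sweat",
                               "optional_sweat_done")),
            sum(res$arm == "optional_sweat_done"),
            sum(res$arm == "negative" & res$failsafe_flagged))
    }, numeric(1))
    expect_true(all(diff(avoided) <= 0))
})
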