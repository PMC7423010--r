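# Screening engine: daily rank triage, panel detection, routing, the full
# programme run and the IRT-DNA comparator.

test_that("top-fraction flagging matches the brute-force sort oracle", {
    # distinct values: exactly the 3 largest of 100
    set.seed(21)
    v <- sample(seq(1, 300, by = 3), 100)
    f <- flagTopFraction(v, 0.03)
    expect_length(f, 3)
    expect_setequal(f, order(v, decreasing = TRUE)[1:3])

    # ceiling rule forces one flag even for a single sample
    expect_equal(flagTopFraction(42, 0.03), 1L)

    # 4-way tie straddling the boundary: earlier index wins
    tied <- c(5, 9, 7, 7, 7, 7, 3, 1, 2, 0)
    expect_equal(flagTopFraction(tied, 0.3), bruteTopFraction(tied, 0.3))
    expect_equal(flagTopFraction(tied, 0.3), c(2L, 3L, 4L))

    # random batches, some with heavy ties, against the oracle
    for (i in 1:40) {
        set.seed(i)
        n <- sample(1:200, 1)
        vals <- sample(round(rlnorm(n, 3, 0.5), sample(0:2, 1)))
        frac <- runif(1, 0.005, 0.5)
        expect_equal(flagTopFraction(vals, frac),
                     bruteTopFraction(vals, frac))
    }

    expect_error(flagTopFraction(numeric(), 0.03), "empty")
    expect_error(flagTopFraction(1:5, 1.2), "fraction")
})

test_that("mutation detection counts panel members only", {
    pop <- tinyPopulation()
    panel <- tinyPanel()
    expect_equal(detectMutations("CFA", "CFA", panel, pop), 2L)
    expect_equal(detectMutations("CFA", "OFFC", panel, pop), 1L)
    expect_equal(detectMutations("OFFC", "OFFC", panel, pop), 0L)
    # benign alleles never count even though ".none" is not a panel member
    expect_equal(detectMutations("CFA", ".none", panel, pop), 1L)
    expect_equal(detectMutations(".none", ".none", panel, pop), 0L)
    expect_error(detectMutations("NOPE", ".none", panel, pop),
                 "not in the configured allele table")
})

test_that("routing follows the three-tier decision tree", {
    pop <- tinyPopulation()
    th <- defaultThresholds()

    r <- routeInfant(makeRecord(alleleA = "CFA", alleleB = "CFA",
                                sweat = 90, pop = pop),
                     TRUE, FALSE, 2, th)
    expect_equal(as.character(r$arm), "positive_two_mutations")
    expect_true(r$referred_for_sweat && r$sweat_performed)

    # carrier, normal day-21 IRT, family declines the optional sweat
    r <- routeInfant(makeRecord(alleleA = "CFA", irt2 = 35, uptake = 0.5,
                                pop = pop), TRUE, FALSE, 1, th)
    expect_equal(as.character(r$arm), "low_risk_optional_sweat")
    expect_false(r$referred_for_sweat)
    expect_false(r$sweat_performed)

    # carrier, day-21 IRT just above the cutoff: referred
    r <- routeInfant(makeRecord(alleleA = "CFA", irt2 = 41, pop = pop),
                     TRUE, FALSE, 1, th)
    expect_equal(as.character(r$arm), "referred_high_irt2")
    expect_true(r$sweat_performed)

    # the comparison is strict: exactly at the cutoff does not refer
    r <- routeInfant(makeRecord(alleleA = "CFA", irt2 = 40, uptake = 0.9,
                                pop = pop), TRUE, FALSE, 1, th)
    expect_equal(as.character(r$arm), "low_risk_optional_sweat")

    # optional sweat taken when the uptake draw is under the probability
    r <- routeInfant(makeRecord(alleleA = "CFA", irt2 = 35, uptake = 0.05,
                                pop = pop), TRUE, FALSE, 1, th)
    expect_equal(as.character(r$arm), "optional_sweat_done")
    expect_false(r$referred_for_sweat)
    expect_true(r$sweat_performed)

    # fail-safe: referral only on a high repeat IRT, else negative close-out
    r <- routeInfant(makeRecord(alleleA = "OFFC", alleleB = "OFFC",
                                irt1 = 150, irt2 = 55, pop = pop),
                     TRUE, TRUE, 0, th)
    expect_equal(as.character(r$arm), "failsafe_irt2")
    r <- routeInfant(makeRecord(alleleA = "OFFC", alleleB = "OFFC",
                                irt1 = 150, irt2 = 30, pop = pop),
                     TRUE, TRUE, 0, th)
    expect_equal(as.character(r$arm), "negative")

    # meconium ileus bypasses the algorithm entirely
    r <- routeInfant(makeRecord(alleleA = "CFA", alleleB = "CFA", mi = TRUE,
                                irt1 = 5, pop = pop), FALSE, FALSE, 0, th)
    expect_equal(as.character(r$arm), "prior_mi_referral")

    expect_error(routeInfant(makeRecord(pop = pop), FALSE, TRUE, 0, th),
                 "inconsistent flags")
})

test_that("the programme run partitions the cohort and is reproducible", {
    pop <- defaultPopulation()
    panel <- bundledPanels()$panel130
    expect_equal(nrow(runProgram(generateCohort(0, pop), panel,
                                 config = pop)), 0L)

    co <- generateCohort(20000, pop, seed = 8)
    r1 <- runProgram(co, panel, config = pop, seed = 8)
    r2 <- runProgram(co, panel, config = pop, seed = 8)
    expect_identical(r1, r2)
    expect_equal(sum(table(r1$arm)), nrow(co))
    expect_true(all(r1$sweat_performed[r1$referred_for_sweat]))
    expect_true(all(!is.na(r1$contact_age_days[r1$referred_for_sweat])))
    expect_true(all(is.na(r1$contact_age_days[r1$arm == "negative"])))

    expect_error(runProgram(rbind(co[1, ], co[1, ]), panel, config = pop),
                 "distinct")
})

test_that("with no pathogenic alleles every infant screens negative", {
    pop <- tinyPopulation(pCfOn = 0, pVu = 0, pCfOff = 0, batch = 100L)
    co <- generateCohort(3000, pop, seed = 2)
    res <- runProgram(co, tinyPanel(), config = pop, seed = 2)
    expect_true(all(res$arm %in% c("negative", "failsafe_irt2")))
    expect_equal(sum(res$arm == "positive_two_mutations"), 0L)
})

test_that("the DNA-tier fraction equals the per-batch ceiling-sum oracle", {
    pop <- defaultPopulation()
    co <- generateCohort(100000, pop, seed = 31)
    res <- runProgram(co, bundledPanels()$panel130, config = pop, seed = 31)
    expectedFlags <- sum(vapply(split(co$irt1, co$birth_day),
                                function(b) ceiling(0.03 * length(b) - 1e-9),
                                numeric(1)))
    expect_equal(sum(res$irt1_flagged), expectedFlags)
    # with 123-infant batches the ceiling rule forces 4/123 = 3.25% per day
    expect_equal(sum(res$irt1_flagged[co$birth_day == 1]), 4)
})

test_that("a panel superset never loses detections or positives", {
    pop <- defaultPopulation()
    co <- generateCohort(50000, pop, seed = 13)
    panels <- bundledPanels()
    expect_true(all(panelMembers(panels$panel24) %in%
                    panelMembers(panels$panel38)))
    expect_true(all(panelMembers(panels$panel38) %in%
                    panelMembers(panels$panel130)))
    prev <- NULL
    prevPos <- -1L
    for (p in panels) {
        det <- detectMutations(co$allele_a, co$allele_b, p, pop)
        if (!is.null(prev)) expect_true(all(det >= prev))
        res <- runProgram(co, p, config = pop, seed = 13)
        pos <- sum(res$arm == "positive_two_mutations")
        expect_gte(pos, prevPos)
        prev <- det
        prevPos <- pos
    }
})

test_that("raising the day-21 cutoff never adds repeat-IRT referrals", {
    pop <- defaultPopulation()
    co <- generateCohort(50000, pop, seed = 17)
    panel <- bundledPanels()$panel130
    counts <- vapply(c(30, 40, 50, 70), function(cut) {
        th <- algorithmThresholds(irt2Cutoff = cut)
        sum(runProgram(co, panel, th, pop, seed = 17)$arm ==
            "referred_high_irt2")
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("the IRT-DNA comparator only adds sweat tests", {
    pop <- defaultPopulation()
    co <- generateCohort(50000, pop, seed = 19)
    panel <- bundledPanels()$panel130
    three <- runProgram(co, panel, config = pop, seed = 19)
    comp <- runComparatorIrtDna(co, panel, config = pop, seed = 19)
    expect_gte(sum(comp$sweat_performed), sum(three$sweat_performed))

    # a single low-IRT2 carrier: the comparator refers, the three-tier
    # algorithm does not
    rec <- makeRecord(alleleA = "CFA", irt1 = 100, irt2 = 10, uptake = 0.9)
    tiny <- tinyPopulation(batch = 1L)
    r3 <- runProgram(rec, tinyPanel(), config = tiny)
    rc <- runComparatorIrtDna(rec, tinyPanel(), config = tiny)
    expect_false(r3$referred_for_sweat)
    expect_true(rc$referred_for_sweat)

    # with no carriers the two programmes differ only on fail-safe routing
    pop0 <- tinyPopulation(pCfOn = 0, pVu = 0, pCfOff = 0.01, batch = 50L)
    co0 <- generateCohort(2000, pop0, seed = 23)
    t0 <- runProgram(co0, tinyPanel(), config = pop0, seed = 23)
    c0 <- runComparatorIrtDna(co0, tinyPanel(), config = pop0, seed = 23)
    fs <- t0$failsafe_flagged
    expect_identical(t0$arm[!fs], c0$arm[!fs])
    expect_true(all(c0$arm[fs] == "direct_referral"))
})
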