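## Programme-performance metrics: predictive values, false-negative rate,
## birth incidence, sweat tests avoided, contact-age summaries, the
## assembled PerformanceReport, and recomputation of the bundled published
## counts.

## round-half-up, so 5288.5 -> 5289 and 99.75 -> 99.8 (base round() is
## half-even, which never matches printed screening-report rounding).
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    floor(x * p + 0.5) / p
}

#' Positive predictive value
#'
#' @param truePositive number of true cases among referrals.
#' @param screenPositive number of screen-positive referrals (> 0).
#' @return Named numeric of length 2: `raw` (unrounded percent) and
#'   `rounded` (nearest integer percent).
#' @examples
#' ppv(57, 77)  # 74% for the two-mutation arm
#' @export
ppv <- function(truePositive, screenPositive) {
    stopifnot(length(truePositive) == 1L, length(screenPositive) == 1L)
    if (screenPositive == 0)
        stop("PPV is undefined: no screen positives")
    if (truePositive < 0 || truePositive > screenPositive)
        stop("need 0 <= truePositive <= screenPositive")
    raw <- 100 * truePositive / screenPositive
    c(raw = raw, rounded = roundHalfUp(raw))
}

#' Negative predictive value
#'
#' @param trueNegative number of true non-cases among screen negatives.
#' @param screenNegative number of screen negatives (> 0).
#' @return Named numeric: `raw` and `rounded` (one decimal).
#' @examples
#' npv(1148, 1151)  # 99.7% for CFSPID after a normal day-21 IRT
#' @export
npv <- function(trueNegative, screenNegative) {
    stopifnot(length(trueNegative) == 1L, length(screenNegative) == 1L)
    if (screenNegative == 0)
        stop("NPV is undefined: no screen negatives")
    if (trueNegative < 0 || trueNegative > screenNegative)
        stop("need 0 <= trueNegative <= screenNegative")
    raw <- 100 * trueNegative / screenNegative
    c(raw = raw, rounded = roundHalfUp(raw, 1))
}

#' Birth-incidence denominator
#'
#' The N of "1 in N": `screened / cases` rounded to the nearest integer.
#'
#' @param cases number of cases (>= 1).
#' @param screened number screened (>= cases).
#' @return Integer denominator.
#' @examples
#' incidenceDenominator(76, 401977)   # 5289
#' incidenceDenominator(104, 401977)  # 3865
#' @export
incidenceDenominator <- function(cases, screened) {
    if (cases == 0)
        stop("incidence is undefined with zero cases")
    stopifnot(cases >= 1, screened >= cases)
    as.integer(roundHalfUp(screened / cases))
}

#' Sweat tests avoided by the day-21 IRT tier
#'
#' Carriers with a normal repeat IRT who declined the optional sweat test,
#' plus fail-safe infants closed out by a normal repeat IRT:
#' `carriersNormalIrt2 - optionalSweatsDone + failsafeNormalIrt2`.
#'
#' @param carriersNormalIrt2 carriers with a normal day-21 IRT.
#' @param optionalSweatsDone optional sweat tests actually performed
#'   (<= `carriersNormalIrt2`).
#' @param failsafeNormalIrt2 fail-safe infants with a normal day-21 IRT.
#' @return Count of sweat tests avoided.
#' @examples
#' sweatTestsAvoided(880, 115, 271)  # 1036
#' @export
sweatTestsAvoided <- function(carriersNormalIrt2, optionalSweatsDone,
                              failsafeNormalIrt2) {
    if (any(c(carriersNormalIrt2, optionalSweatsDone,
              failsafeNormalIrt2) < 0))
        stop("counts must be non-negative")
    if (optionalSweatsDone > carriersNormalIrt2)
        stop("optionalSweatsDone cannot exceed carriersNormalIrt2")
    carriersNormalIrt2 - optionalSweatsDone + failsafeNormalIrt2
}

#' False-negative rate
#'
#' `100 * falseNegatives / totalCases`, with the denominator defined as all
#' ascertained cases (screen-detected true positives plus false negatives).
#'
#' @param falseNegatives number of missed cases.
#' @param totalCases total ascertained cases (> 0).
#' @return Named numeric: `raw` and `rounded` (one decimal).
#' @examples
#' falseNegativeRate(6, 76)   # 7.9% for CF
#' falseNegativeRate(9, 104)  # 8.7% for CF + CFSPID
#' @export
falseNegativeRate <- function(falseNegatives, totalCases) {
    if (totalCases == 0)
        stop("false-negative rate is undefined with zero cases")
    stopifnot(falseNegatives >= 0, falseNegatives <= totalCases)
    raw <- 100 * falseNegatives / totalCases
    c(raw = raw, rounded = roundHalfUp(raw, 1))
}

#' Summarize ages at first CF clinic contact
#'
#' Median and range, optionally split by routing arm with an overall row.
#' Because the median convention of printed programme tables is usually
#' unstated, both the interpolated median and the lower-of-the-two-middle
#' order statistic are reported (they coincide at odd lengths).
#'
#' @param ages numeric vector of ages in days (non-empty).
#' @param arm optional factor/character of arms aligned with `ages`.
#' @return For `arm = NULL`, a named numeric with `median`, `median_low`,
#'   `min`, `max`; otherwise a data.frame with one row per arm plus
#'   `"overall"`.
#' @examples
#' summarizeContactAges(c(10, 22, 50))
#' @export
summarizeContactAges <- function(ages, arm = NULL) {
    if (is.null(arm)) {
        ages <- ages[!is.na(ages)]
        if (length(ages) == 0L)
            stop("cannot summarize an empty set of contact ages")
        s <- sort(ages)
        n <- length(s)
        return(c(median = stats::median(s),
                 median_low = s[floor((n + 1) / 2)],
                 min = s[1L], max = s[n]))
    }
    keep <- !is.na(ages)
    ages <- ages[keep]; arm <- as.character(arm)[keep]
    if (length(ages) == 0L)
        stop("cannot summarize an empty set of contact ages")
    groups <- c(split(ages, arm), list(overall = ages))
    out <- do.call(rbind, lapply(names(groups), function(g) {
        s <- summarizeContactAges(groups[[g]])
        data.frame(arm = g, n = length(groups[[g]]),
                   median = s[["median"]], median_low = s[["median_low"]],
                   min = s[["min"]], max = s[["max"]],
                   stringsAsFactors = FALSE)
    }))
    out
}

## Safe PPV as a plain percent (NA when the arm is empty).
.ppvOrNA <- function(tp, sp) if (sp > 0) 100 * tp / sp else NA_real_

#' Assemble the programme performance report
#'
#' Computes every reported metric from a labelled results table (the output
#' of [labelCohort()]): per-arm referral counts and PPVs, the NPV of a
#' normal day-21 IRT, sensitivity and false-negative rate (denominator: all
#' ascertained cases), birth-incidence denominators, sweat tests avoided,
#' and per-arm contact-age summaries. Partition consistency (arms sum to n;
#' detection channels sum to total cases) is re-checked and a violation is
#' an error naming the failing sum.
#'
#' @param labelled data.frame from [labelCohort()].
#' @return A [PerformanceReport-class] object.
#' @export
buildReport <- function(labelled) {
    need <- c("arm", "true_status", "diagnostic_label", "detection_channel",
              "failsafe_flagged", "contact_age_days")
    if (!all(need %in% names(labelled)))
        stop("labelled results must come from labelCohort()")
    n <- nrow(labelled)
    armTab <- table(factor(labelled$arm, levels = armLevels()))
    if (sum(armTab) != n)
        stop("partition violation: arm counts sum to ", sum(armTab),
             ", not n = ", n)
    isCase <- labelled$true_status %in% c("cf", "cfspid_type")
    isCf <- labelled$true_status == "cf"
    chTab <- table(labelled$detection_channel[isCase])
    if (sum(chTab) != sum(isCase))
        stop("partition violation: channel counts sum to ", sum(chTab),
             ", not total cases = ", sum(isCase))
    checks <- c(sprintf("arms partition n (%d)", n),
                sprintf("channels partition cases (%d)", sum(isCase)))

    detected <- isCase &
        labelled$detection_channel %in% tpChannels() &
        labelled$diagnostic_label != "cf_excluded"
    fn <- isCase & !detected

    refArms <- c("positive_two_mutations", "referred_high_irt2",
                 "optional_sweat_done", "failsafe_irt2")
    ppvByArm <- do.call(rbind, lapply(refArms, function(a) {
        inArm <- labelled$arm == a
        data.frame(arm = a, referred = sum(inArm),
                   cases_cf = sum(inArm & detected &
                                  labelled$diagnostic_label == "cf"),
                   cases_all = sum(inArm & detected),
                   ppv_cf = .ppvOrNA(sum(inArm & detected &
                                         labelled$diagnostic_label == "cf"),
                                     sum(inArm)),
                   ppv_all = .ppvOrNA(sum(inArm & detected), sum(inArm)),
                   stringsAsFactors = FALSE)
    }))

    ## the normal-day-21 group: carriers not referred on IRT2, plus
    ## fail-safe cases closed out by a normal repeat IRT
    normal21 <- labelled$arm %in% c("low_risk_optional_sweat",
                                    "optional_sweat_done") |
        (labelled$arm == "negative" & labelled$failsafe_flagged)
    n21 <- sum(normal21)
    npvDay21 <- c(cf = if (n21 > 0) 100 * (n21 - sum(normal21 & isCf)) / n21
                       else NA_real_,
                  all = if (n21 > 0) 100 * (n21 - sum(normal21 & isCase)) / n21
                        else NA_real_)
    attr(npvDay21, "n") <- n21

    totCf <- sum(isCf); totAll <- sum(isCase)
    fnr <- c(cf = if (totCf > 0) 100 * sum(fn & isCf) / totCf else NA_real_,
             all = if (totAll > 0) 100 * sum(fn) / totAll else NA_real_)
    sens <- 100 - fnr
    if (totCf == 0)
        checks <- c(checks, "zero CF cases: PPV/FNR/incidence undefined")
    inc <- c(cf = if (totCf > 0) incidenceDenominator(totCf, n) else NA_real_,
             all = if (totAll > 0) incidenceDenominator(totAll, n)
                   else NA_real_)

    avoided <- sweatTestsAvoided(
        sum(labelled$arm %in% c("low_risk_optional_sweat",
                                "optional_sweat_done")),
        sum(labelled$arm == "optional_sweat_done"),
        sum(labelled$arm == "negative" & labelled$failsafe_flagged))

    ages <- labelled$contact_age_days
    caSummary <- if (any(!is.na(ages)))
        summarizeContactAges(ages, labelled$arm)
    else data.frame(arm = character(), n = integer(), median = numeric(),
                    median_low = numeric(), min = numeric(), max = numeric())

    new("PerformanceReport",
        nScreened = as.numeric(n),
        armCounts = data.frame(arm = names(armTab),
                               count = as.integer(armTab),
                               stringsAsFactors = FALSE),
        channelCounts = data.frame(channel = names(chTab),
                                   count = as.integer(chTab),
                                   stringsAsFactors = FALSE),
        ppvByArm = ppvByArm,
        npvDay21 = npvDay21,
        sensitivity = sens,
        falseNegativeRate = fnr,
        incidenceDenominator = inc,
        sweatTestsAvoided = as.numeric(avoided),
        contactAgeSummary = caSummary,
        checks = checks)
}

#' Reconstruct the one-mutation referral denominator
#'
#' The referral count behind a pair of printed PPV percentages is recovered
#' by exhaustive scan: the unique integer denominator in `candidates`
#' consistent with both printed integer percents for the given case counts.
#'
#' @param cfDetected CF cases detected in the arm.
#' @param allDetected CF+CFSPID cases detected in the arm.
#' @param ppvCfPct,ppvAllPct printed integer percents.
#' @param candidates integer denominators to scan.
#' @return The unique consistent denominator (error if none or several).
#' @examples
#' reconstructReferralDenominator(10, 13, 29, 38)  # 34
#' @export
reconstructReferralDenominator <- function(cfDetected, allDetected,
                                           ppvCfPct, ppvAllPct,
                                           candidates = 25:45) {
    ok <- vapply(candidates, function(d) {
        roundHalfUp(100 * cfDetected / d) == ppvCfPct &&
            roundHalfUp(100 * allDetected / d) == ppvAllPct
    }, logical(1))
    hits <- candidates[ok]
    if (length(hits) != 1L)
        stop("expected exactly one consistent denominator, found ",
             length(hits))
    hits
}

#' Recompute the bundled published programme counts
#'
#' Recomputes every derived performance number from the bundled fixture of
#' published counts (arm-level case counts of a nine-year, 401,977-infant
#' programme) and compares each against its printed value: the two-mutation
#' arm PPVs, the reconstructed one-mutation-arm PPVs, optional sweat-test
#' uptake, sweat tests avoided, the day-21 NPVs, the birth-incidence
#' denominators, and the true-positive / false-negative / total-case sums.
#'
#' @param fixture named list of printed counts, by default loaded from the
#'   bundled fixture via [printedCounts()].
#' @return data.frame with columns `quantity`, `computed`, `printed`,
#'   `pass`; the attribute `all_pass` is `TRUE` when every comparison with
#'   a printed value passes.
#' @examples
#' rep <- reproducePrintedCounts()
#' attr(rep, "all_pass")
#' @export
reproducePrintedCounts <- function(fixture = printedCounts()) {
    need <- c("n_screened", "cf_total", "cfspid_total",
              "true_positive_cf", "true_positive_all",
              "false_negative_cf", "false_negative_all",
              "meconium_ileus_cases", "two_mutation_referrals",
              "two_mutation_cf", "one_mut_high_irt2_cf",
              "one_mut_high_irt2_all", "carriers_normal_irt2",
              "optional_sweats_done", "failsafe_normal_irt2",
              "optional_sweat_cfspid", "optional_sweat_cf",
              "failsafe_detected", "fn_normal_irt1_cf", "fn_normal_irt1_all",
              "fn_no_mutation", "fn_no_sweat_cfspid",
              "fn_high_irt2_normal_sweat_cfspid",
              "ppv_two_mut_cf_printed", "ppv_two_mut_all_printed",
              "ppv_one_mut_cf_printed", "ppv_one_mut_all_printed",
              "uptake_pct_printed", "sweat_tests_avoided_printed",
              "npv_day21_cf_printed", "npv_day21_cfspid_printed",
              "incidence_cf_printed", "incidence_all_printed",
              "cases_all_printed")
    miss <- setdiff(need, names(fixture))
    if (length(miss))
        stop("printed-count fixture is missing key(s): ",
             paste(miss, collapse = ", "))
    f <- fixture
    day21Group <- f$carriers_normal_irt2 + f$failsafe_normal_irt2
    day21MissedCfspid <- f$optional_sweat_cfspid + f$fn_no_sweat_cfspid
    oneMutDen <- reconstructReferralDenominator(
        f$one_mut_high_irt2_cf, f$one_mut_high_irt2_all,
        f$ppv_one_mut_cf_printed, f$ppv_one_mut_all_printed)
    row <- function(quantity, computed, printed = NA_real_)
        data.frame(quantity = quantity, computed = computed,
                   printed = printed,
                   pass = if (is.na(printed)) NA else computed == printed,
                   stringsAsFactors = FALSE)
    out <- rbind(
        row("ppv_two_mut_cf_pct",
            ppv(f$two_mutation_cf, f$two_mutation_referrals)[["rounded"]],
            f$ppv_two_mut_cf_printed),
        row("ppv_two_mut_all_pct",
            ppv(f$true_positive_all - f$meconium_ileus_cases -
                f$one_mut_high_irt2_all - f$optional_sweat_cfspid -
                f$failsafe_detected,
                f$two_mutation_referrals)[["rounded"]],
            f$ppv_two_mut_all_printed),
        row("one_mut_referrals_reconstructed", oneMutDen),
        row("ppv_one_mut_cf_pct",
            ppv(f$one_mut_high_irt2_cf, oneMutDen)[["rounded"]],
            f$ppv_one_mut_cf_printed),
        row("ppv_one_mut_all_pct",
            ppv(f$one_mut_high_irt2_all, oneMutDen)[["rounded"]],
            f$ppv_one_mut_all_printed),
        row("optional_sweat_uptake_pct",
            roundHalfUp(100 * f$optional_sweats_done /
                        f$carriers_normal_irt2),
            f$uptake_pct_printed),
        row("sweat_tests_avoided",
            sweatTestsAvoided(f$carriers_normal_irt2,
                              f$optional_sweats_done,
                              f$failsafe_normal_irt2),
            f$sweat_tests_avoided_printed),
        row("npv_day21_cf_pct",
            npv(day21Group - 0, day21Group)[["rounded"]],
            f$npv_day21_cf_printed),
        row("npv_day21_cfspid_pct",
            npv(day21Group - day21MissedCfspid, day21Group)[["rounded"]],
            f$npv_day21_cfspid_printed),
        row("incidence_denominator_cf",
            incidenceDenominator(f$cf_total, f$n_screened),
            f$incidence_cf_printed),
        row("incidence_denominator_all",
            incidenceDenominator(f$cf_total + f$cfspid_total, f$n_screened),
            f$incidence_all_printed),
        row("true_positive_cf_sum",
            f$meconium_ileus_cases + f$two_mutation_cf +
            f$one_mut_high_irt2_cf + f$optional_sweat_cf +
            f$failsafe_detected,
            f$true_positive_cf),
        row("true_positive_all_sum",
            f$meconium_ileus_cases + f$two_mutation_referrals +
            f$one_mut_high_irt2_all + f$optional_sweat_cfspid +
            f$failsafe_detected,
            f$true_positive_all),
        row("false_negative_cf_sum",
            f$fn_normal_irt1_cf + f$fn_no_mutation,
            f$false_negative_cf),
        row("false_negative_all_sum",
            f$fn_normal_irt1_all + f$fn_no_mutation + f$fn_no_sweat_cfspid +
            f$fn_high_irt2_normal_sweat_cfspid,
            f$false_negative_all),
        row("total_cases_cf",
            f$true_positive_cf + f$false_negative_cf, f$cf_total),
        row("total_cases_all",
            f$true_positive_all + f$false_negative_all,
            f$cases_all_printed))
    attr(out, "all_pass") <- all(out$pass[!is.na(out$pass)])
    out
}
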