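## The screening decision engine: daily rank-based IRT triage, CFTR panel
## detection, and the three-tier routing tree (with an IRT-DNA comparator
## that skips the day-21 repeat IRT).

#' Flag the top fraction of a daily IRT batch
#'
#' Flags exactly `ceiling(fraction * n)` indices holding the largest values
#' of the batch. Ties at the boundary are broken by input order (the earlier
#' index wins), making the rule deterministic and oracle-checkable.
#'
#' @param values numeric vector of IRT values (ng/mL) for one daily batch.
#' @param fraction fraction in (0, 1) of the batch to flag.
#' @return Sorted integer vector of flagged indices.
#' @examples
#' flagTopFraction(c(5, 9, 1, 9, 2), 0.4)  # the two largest; tie -> index 2
#' @export
flagTopFraction <- function(values, fraction) {
    if (length(values) == 0L)
        stop("cannot flag the top fraction of an empty batch")
    if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
        stop("fraction must be in (0, 1)")
    n <- length(values)
    ## epsilon guards against 0.03 * n landing an ulp above an integer
    k <- as.integer(ceiling(fraction * n - 1e-9))
    k <- max(k, 1L)
    ord <- order(-values, seq_len(n))
    sort(ord[seq_len(k)])
}

#' Count panel-detectable mutations of a genotype
#'
#' The number of non-benign alleles of the genotype whose id is a member of
#' the panel: benign alleles never count, and pathogenic alleles absent from
#' the panel are invisible (homozygotes for off-panel rare alleles screen as
#' zero-mutation).
#'
#' @param alleleA,alleleB character vectors of allele ids (vectorised).
#' @param panel a [MutationPanel-class].
#' @param config a [PopulationConfig-class] supplying the allele functional
#'   classes.
#' @return Integer vector of counts in 0..2.
#' @export
detectMutations <- function(alleleA, alleleB, panel,
                            config = defaultPopulation()) {
    stopifnot(is(panel, "MutationPanel"), length(alleleA) == length(alleleB))
    cls <- alleleClasses(config)
    unknown <- setdiff(c(alleleA, alleleB), names(cls))
    if (length(unknown))
        stop("allele id(s) not in the configured allele table: ",
             paste(unknown, collapse = ", "))
    hit <- function(a) (cls[a] != "benign_or_none") & (a %in% panel@members)
    as.integer(hit(alleleA)) + as.integer(hit(alleleB))
}

## Vectorised routing core shared by the three-tier programme and the
## comparator. Returns a results data.frame without contact ages.
.routeCore <- function(cohort, irt1Flagged, failsafeFlagged, detected,
                       thresholds, comparator = FALSE) {
    n <- nrow(cohort)
    stopifnot(length(irt1Flagged) == n, length(failsafeFlagged) == n,
              length(detected) == n)
    if (any(failsafeFlagged & !irt1Flagged))
        stop("inconsistent flags: the fail-safe flag requires the initial IRT flag")
    arm <- rep("negative", n)
    referred <- logical(n)
    sweatDone <- logical(n)

    mi <- cohort$meconium_ileus
    arm[mi] <- "prior_mi_referral"
    referred[mi] <- TRUE

    eligible <- !mi & irt1Flagged
    two <- eligible & detected == 2L
    arm[two] <- "positive_two_mutations"
    referred[two] <- TRUE

    one <- eligible & detected == 1L
    if (comparator) {
        ## IRT-DNA: every one-mutation infant (and fail-safe case) is
        ## referred for sweat directly, with no day-21 IRT tier.
        direct <- one | (eligible & detected == 0L & failsafeFlagged)
        arm[direct] <- "direct_referral"
        referred[direct] <- TRUE
    } else {
        high <- one & cohort$irt2 > thresholds@irt2Cutoff
        arm[high] <- "referred_high_irt2"
        referred[high] <- TRUE
        low <- one & !high
        taken <- low & cohort$uptake_draw < thresholds@optionalSweatUptake
        arm[taken] <- "optional_sweat_done"
        arm[low & !taken] <- "low_risk_optional_sweat"
        sweatDone[taken] <- TRUE

        fsHigh <- eligible & detected == 0L & failsafeFlagged &
            cohort$irt2 > thresholds@irt2Cutoff
        arm[fsHigh] <- "failsafe_irt2"
        referred[fsHigh] <- TRUE
        ## fail-safe cases with a normal repeat IRT close out screen-negative
        ## (no optional sweat offer on the fail-safe side).
    }
    sweatDone <- sweatDone | referred
    data.frame(infant_id = cohort$infant_id,
               detected_mutations = as.integer(detected),
               arm = factor(arm, levels = armLevels()),
               referred_for_sweat = referred,
               sweat_performed = sweatDone,
               contact_age_days = rep(NA_real_, n),
               irt1_flagged = irt1Flagged,
               failsafe_flagged = failsafeFlagged,
               stringsAsFactors = FALSE)
}

#' Route a single newborn record through the decision tree
#'
#' Single-record form of the routing rule: meconium ileus bypasses the
#' algorithm as a prior referral; an unflagged initial IRT screens negative;
#' two detected mutations are screen-positive; one detected mutation goes to
#' the day-21 repeat IRT (referral if strictly above the cutoff, otherwise
#' the low-risk optional-sweat offer); zero mutations refer only through the
#' fail-safe arm.
#'
#' @param record one-row cohort data.frame (see [generateCohort()]).
#' @param irt1Flagged was the initial IRT in the flagged daily top fraction?
#' @param failsafeFlagged was it in the fail-safe top fraction? (implies
#'   `irt1Flagged`).
#' @param detected detected mutation count 0..2.
#' @param thresholds an [AlgorithmThresholds-class].
#' @return One-row results data.frame (without a contact age).
#' @export
routeInfant <- function(record, irt1Flagged, failsafeFlagged, detected,
                        thresholds = defaultThresholds()) {
    stopifnot(nrow(record) == 1L)
    .routeCore(record, irt1Flagged, failsafeFlagged, as.integer(detected),
               thresholds)
}

## Per-batch daily flags plus calibrated fail-safe flags.
.computeFlags <- function(cohort, thresholds, config) {
    n <- nrow(cohort)
    flagged <- logical(n)
    for (idx in split(seq_len(n), cohort$birth_day)) {
        f <- flagTopFraction(cohort$irt1[idx], thresholds@irt1TopFraction)
        flagged[idx[f]] <- TRUE
    }
    ## "top 0.1%" as an absolute cutoff: the (1 - fraction) quantile of the
    ## configured unaffected IRT1 distribution (a daily rank of 0.1% is
    ## ill-defined on a ~123-infant batch).
    p <- .irtParamsFor("unaffected", "first", config)
    fsCut <- stats::qlnorm(1 - thresholds@failsafeTopFraction,
                           meanlog = p$meanlog, sdlog = p$sdlog)
    list(irt1 = flagged, failsafe = flagged & cohort$irt1 > fsCut,
         failsafeCutoff = fsCut)
}

## Sample contact ages for clinic-contact rows, one sub-stream, fixed arm
## order so results are reproducible.
.assignContactAges <- function(results, config, seed) {
    withSubstream(seed, fieldStreams()[["contact"]], {
        for (a in intersect(armLevels(), config@contactAgeParams$arm)) {
            rows <- which(results$arm == a &
                          (results$referred_for_sweat | results$sweat_performed))
            if (length(rows))
                results$contact_age_days[rows] <-
                    sampleContactAge(a, config, length(rows))
        }
        results
    })
}

#' Run the three-tier screening programme over a cohort
#'
#' Computes daily top-fraction IRT flags per birth-day batch, fail-safe
#' flags from the calibrated absolute cutoff, panel mutation counts, routes
#' every infant, and samples ages at first CF clinic contact for infants
#' who reach the clinic.
#'
#' @param cohort a cohort data.frame from [generateCohort()] (or
#'   [readCohort()]); infant ids must be distinct.
#' @param panel a [MutationPanel-class].
#' @param thresholds an [AlgorithmThresholds-class].
#' @param config the [PopulationConfig-class] used to generate the cohort
#'   (supplies allele classes, the fail-safe calibration and contact-age
#'   parameters).
#' @param seed master seed for the contact-age draws.
#' @return data.frame with one row per infant: `infant_id`,
#'   `detected_mutations`, `arm`, `referred_for_sweat`, `sweat_performed`,
#'   `contact_age_days`, `irt1_flagged`, `failsafe_flagged`.
#' @examples
#' cohort <- generateCohort(2000, seed = 7)
#' res <- runProgram(cohort, bundledPanels()$panel130, seed = 7)
#' table(res$arm)
#' @export
runProgram <- function(cohort, panel, thresholds = defaultThresholds(),
                       config = defaultPopulation(), seed = 1L) {
    if (anyDuplicated(cohort$infant_id))
        stop("cohort infant ids must be distinct")
    if (nrow(cohort) == 0L)
        return(.routeCore(cohort, logical(), logical(), integer(),
                          thresholds))
    flags <- .computeFlags(cohort, thresholds, config)
    detected <- detectMutations(cohort$allele_a, cohort$allele_b, panel,
                                config)
    results <- .routeCore(cohort, flags$irt1, flags$failsafe, detected,
                          thresholds)
    .assignContactAges(results, config, seed)
}

#' Run the IRT-DNA comparator over a cohort
#'
#' Identical to [runProgram()] except that the day-21 IRT tier is removed:
#' every one-mutation infant (and every fail-safe case) is referred for
#' sweat testing directly. Running both on the same cohort quantifies the
#' sweat-test burden saved by the repeat-IRT tier.
#'
#' @inheritParams runProgram
#' @return Results data.frame as for [runProgram()]; direct referrals carry
#'   the arm `direct_referral`.
#' @export
runComparatorIrtDna <- function(cohort, panel,
                                thresholds = defaultThresholds(),
                                config = defaultPopulation(), seed = 1L) {
    if (anyDuplicated(cohort$infant_id))
        stop("cohort infant ids must be distinct")
    if (nrow(cohort) == 0L)
        return(.routeCore(cohort, logical(), logical(), integer(),
                          thresholds, comparator = TRUE))
    flags <- .computeFlags(cohort, thresholds, config)
    detected <- detectMutations(cohort$allele_a, cohort$allele_b, panel,
                                config)
    results <- .routeCore(cohort, flags$irt1, flags$failsafe, detected,
                          thresholds, comparator = TRUE)
    .assignContactAges(results, config, seed)
}
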