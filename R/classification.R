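## Consensus CF / CFSPID case classification from genotype class counts and
## sweat chloride, and per-infant detection-channel labelling of a screened
## cohort.

#' Classify a case as CF, CFSPID, or CF-excluded
#'
#' Consensus-style rules: CF requires at least one CF-causing mutation and a
#' sweat chloride in the diagnostic range (>= 60 mmol/L by default; the
#' cutoff is inclusive so the real line is partitioned, the intermediate
#' band being `[30, 60)`). CFSPID requires a positive screen and either
#' (1) sweat below the intermediate band with two identified mutations of
#' which at least one has unclear consequence, or (2) an intermediate sweat
#' value with at most one CF-causing mutation. Everything else is
#' CF-excluded.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param cfCausingCount number of CF-causing mutations (0, 1 or 2).
#' @param hasUnclearAllele does the genotype carry a variant of unclear
#'   consequence?
#' @param sweatChloride sweat chloride in mmol/L.
#' @param screenPositive was the infant screen-positive (or, for clinically
#'   ascertained cases, under diagnostic work-up)?
#' @param totalIdentifiedMutations total identified mutations (0, 1 or 2);
#'   must be >= `cfCausingCount`.
#' @param thresholds an [AlgorithmThresholds-class] supplying the sweat
#'   bands.
#' @return Factor with levels `cf`, `cfspid`, `cf_excluded`.
#' @examples
#' classifyCase(2, FALSE, 80, TRUE, 2)   # cf
#' classifyCase(1, TRUE, 20, TRUE, 2)    # cfspid (normal sweat, 2 mutations)
#' classifyCase(1, FALSE, 45, TRUE, 1)   # cfspid (intermediate sweat)
#' @export
classifyCase <- function(cfCausingCount, hasUnclearAllele, sweatChloride,
                         screenPositive, totalIdentifiedMutations,
                         thresholds = defaultThresholds()) {
    n <- max(length(cfCausingCount), length(hasUnclearAllele),
             length(sweatChloride), length(screenPositive),
             length(totalIdentifiedMutations))
    cfc <- rep_len(as.integer(cfCausingCount), n)
    unc <- rep_len(as.logical(hasUnclearAllele), n)
    sw <- rep_len(as.numeric(sweatChloride), n)
    pos <- rep_len(as.logical(screenPositive), n)
    tot <- rep_len(as.integer(totalIdentifiedMutations), n)
    if (any(cfc > tot))
        stop("cfCausingCount cannot exceed totalIdentifiedMutations")
    if (any(sw < 0))
        stop("sweat chloride must be non-negative")
    lowBand <- thresholds@sweatIntermediateLow
    cfCut <- thresholds@sweatCfCutoff
    isCf <- cfc >= 1L & sw >= cfCut
    inBand <- sw >= lowBand & sw < cfCut
    isCfspid <- !isCf & pos &
        ((sw < lowBand & tot == 2L & unc) | (inBand & cfc <= 1L))
    out <- rep("cf_excluded", n)
    out[isCfspid] <- "cfspid"
    out[isCf] <- "cf"
    factor(out, levels = diagnosticLabelLevels())
}

## Detection channel for one true case given its routing and final label.
.caseChannels <- function(arm, irt1Flagged, failsafeFlagged, detected,
                          excluded) {
    ch <- rep(NA_character_, length(arm))
    arm <- as.character(arm)
    ch[arm == "prior_mi_referral"] <- "Meconium Ileus"
    ch[arm == "positive_two_mutations"] <-
        ifelse(excluded[arm == "positive_two_mutations"],
               "2 Mutations (Normal Sweat)", "2 Mutations")
    ch[arm == "referred_high_irt2"] <-
        ifelse(excluded[arm == "referred_high_irt2"],
               "1 Mutation and High IRT2 (Normal Sweat)",
               "1 Mutation and High IRT2")
    ch[arm == "optional_sweat_done"] <-
        ifelse(excluded[arm == "optional_sweat_done"],
               "1 Mutation and Normal IRT2 (optional sweat, not diagnostic)",
               "1 Mutation and Normal IRT2 (optional sweat test)")
    ch[arm == "failsafe_irt2"] <-
        ifelse(excluded[arm == "failsafe_irt2"],
               "No Mutations and High IRT2 (Normal Sweat)",
               "No Mutations and Top 0.1% IRT1 and High IRT2")
    ch[arm == "low_risk_optional_sweat"] <-
        "1 Mutation and Normal IRT2 (no sweat)"
    neg <- arm == "negative"
    ch[neg & !irt1Flagged] <- "Normal IRT1"
    ch[neg & irt1Flagged & !failsafeFlagged] <-
        "No Mutations and IRT1 NOT Top 0.1%"
    ch[neg & failsafeFlagged] <- "No Mutations and Normal IRT2 (fail-safe)"
    ch
}

#' Label a screened cohort with diagnoses and detection channels
#'
#' Joins the cohort's ground truth with the screening results, classifies
#' every infant who had a sweat test (or is a true case, under the
#' assumption of complete eventual clinical ascertainment), and assigns each
#' true case a detection channel mirroring the programme's case-accounting
#' rows: the true-positive channels (meconium ileus, two mutations, one
#' mutation with high repeat IRT, optional sweat, fail-safe) and the
#' false-negative channels (normal initial IRT, no panel mutations, normal
#' repeat IRT without sweat, normal sweat after referral).
#'
#' @param cohort cohort data.frame from [generateCohort()].
#' @param results results data.frame from [runProgram()]; must cover the
#'   same infant ids.
#' @param config the [PopulationConfig-class] supplying allele classes.
#' @param thresholds an [AlgorithmThresholds-class].
#' @return The results table (in cohort order) with columns `true_status`,
#'   `diagnostic_label` and `detection_channel` appended; the channel is
#'   `NA` for infants who are not true cases.
#' @export
labelCohort <- function(cohort, results, config = defaultPopulation(),
                        thresholds = defaultThresholds()) {
    if (!setequal(cohort$infant_id, results$infant_id) ||
        nrow(cohort) != nrow(results))
        stop("cohort and results must cover the same infant ids")
    res <- results[match(cohort$infant_id, results$infant_id), ,
                   drop = FALSE]
    rownames(res) <- NULL
    cls <- alleleClasses(config)
    ca <- cls[cohort$allele_a]
    cb <- cls[cohort$allele_b]
    cfCount <- as.integer(ca == "cf_causing") + as.integer(cb == "cf_causing")
    hasUnclear <- ca == "varying_or_unclear" | cb == "varying_or_unclear"
    totalNonBenign <- as.integer(ca != "benign_or_none") +
        as.integer(cb != "benign_or_none")
    isCase <- cohort$true_status %in% c("cf", "cfspid_type")
    ## sweat-tested infants are classified from their measured sweat; missed
    ## true cases are classified as if fully worked up (perfect eventual
    ## clinical ascertainment), the clinical work-up standing in for the
    ## positive screen.
    label <- classifyCase(cfCount, hasUnclear, cohort$sweat_chloride,
                          res$sweat_performed | isCase, totalNonBenign,
                          thresholds)
    label[!res$sweat_performed & !isCase] <- "cf_excluded"
    channel <- rep(NA_character_, nrow(cohort))
    channel[isCase] <- .caseChannels(res$arm[isCase],
                                     res$irt1_flagged[isCase],
                                     res$failsafe_flagged[isCase],
                                     res$detected_mutations[isCase],
                                     (label == "cf_excluded")[isCase])
    res$true_status <- cohort$true_status
    res$diagnostic_label <- label
    res$detection_channel <- factor(channel,
                                    levels = detectionChannelLevels())
    res
}
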