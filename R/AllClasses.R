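#' @import methods
NULL

#' Enumeration helpers
#'
#' Fixed level sets used throughout the package: ground-truth infant status,
#' routing arms of the decision tree, CFTR allele functional classes,
#' diagnostic labels, and detection channels.
#'
#' @return A character vector of levels.
#' @name enumerations
NULL

#' @rdname enumerations
#' @export
statusLevels <- function() c("cf", "cfspid_type", "carrier", "unaffected")

#' @rdname enumerations
#' @export
armLevels <- function() {
    c("negative", "failsafe_irt2", "carrier_irt2", "positive_two_mutations",
      "referred_high_irt2", "low_risk_optional_sweat", "optional_sweat_done",
      "prior_mi_referral", "direct_referral")
}

#' @rdname enumerations
#' @export
alleleClassLevels <- function() {
    c("cf_causing", "varying_or_unclear", "benign_or_none")
}

#' @rdname enumerations
#' @export
diagnosticLabelLevels <- function() c("cf", "cfspid", "cf_excluded")

## Detection channels mirror the rows of the program's case-accounting table:
## true-positive channels first, then the false-negative channels.
tpChannels <- function() {
    c("Meconium Ileus",
      "2 Mutations",
      "1 Mutation and High IRT2",
      "1 Mutation and Normal IRT2 (optional sweat test)",
      "No Mutations and Top 0.1% IRT1 and High IRT2")
}

fnChannels <- function() {
    c("Normal IRT1",
      "No Mutations and IRT1 NOT Top 0.1%",
      "No Mutations and Normal IRT2 (fail-safe)",
      "1 Mutation and Normal IRT2 (no sweat)",
      "1 Mutation and Normal IRT2 (optional sweat, not diagnostic)",
      "1 Mutation and High IRT2 (Normal Sweat)",
      "2 Mutations (Normal Sweat)",
      "No Mutations and High IRT2 (Normal Sweat)")
}

#' @rdname enumerations
#' @export
detectionChannelLevels <- function() c(tpChannels(), fnChannels())

## ---------------------------------------------------------------------------
## MutationPanel

#' MutationPanel: a named set of detectable CFTR alleles
#'
#' A mutation panel is the set of CFTR allele identifiers a genotyping assay
#' can detect. Alleles of a genotype that are absent from the panel are
#' invisible to the screening programme (the source of "no mutation" and
#' "apparent carrier" misses).
#'
#' @slot name single character, the panel's name.
#' @slot members character vector of unique allele identifiers.
#'
#' @seealso [bundledPanels()] for the three nested presets of sizes 24, 38
#'   and 130 that mirror the assay succession of a long-running programme.
#' @export
setClass("MutationPanel",
         representation(name = "character", members = "character"),
         validity = function(object) {
             msg <- character()
             if (length(object@name) != 1L || is.na(object@name) ||
                 !nzchar(object@name))
                 msg <- c(msg, "name must be a single non-empty string")
             if (anyDuplicated(object@members))
                 msg <- c(msg, "members must be unique allele ids")
             if (length(msg)) msg else TRUE
         })

#' Construct a mutation panel
#'
#' @param name panel name.
#' @param members character vector of allele identifiers the assay detects.
#' @return A [MutationPanel-class] object.
#' @examples
#' p <- mutationPanel("demo", c("CF001", "CF002"))
#' panelSize(p)
#' @export
mutationPanel <- function(name, members) {
    new("MutationPanel", name = as.character(name),
        members = as.character(members))
}

#' @describeIn mutationPanel Panel name accessor.
#' @param x a `MutationPanel`.
#' @export
panelName <- function(x) x@name

#' @describeIn mutationPanel Member allele ids accessor.
#' @export
panelMembers <- function(x) x@members

#' @describeIn mutationPanel Number of member alleles.
#' @export
panelSize <- function(x) length(x@members)

setMethod("show", "MutationPanel", function(object) {
    cat("MutationPanel \"", object@name, "\" with ", length(object@members),
        " alleles\n", sep = "")
    head_ids <- utils::head(object@members, 6L)
    cat("  members: ", paste(head_ids, collapse = ", "),
        if (length(object@members) > 6L) ", ..." else "", "\n", sep = "")
})

## ---------------------------------------------------------------------------
## AlgorithmThresholds

#' AlgorithmThresholds: every decision cutoff of the screening tree
#'
#' Holds the cutoffs of the three-tier algorithm: the daily IRT percentile
#' fraction sent for CFTR analysis, the fail-safe top fraction, the day-21
#' repeat-IRT referral cutoff, the diagnostic and intermediate sweat-chloride
#' bounds, and the optional sweat-test uptake probability.
#'
#' @slot irt1TopFraction fraction of each daily batch sent for CFTR analysis
#'   (default 0.03).
#' @slot failsafeTopFraction fraction defining the fail-safe arm
#'   (default 0.001); operationalised as an absolute IRT1 cutoff at the
#'   corresponding quantile of the unaffected IRT1 distribution.
#' @slot irt2Cutoff day-21 IRT referral cutoff in ng/mL (default 40); a
#'   repeat IRT strictly above this refers the infant.
#' @slot sweatCfCutoff sweat chloride diagnostic cutoff in mmol/L
#'   (default 60, inclusive).
#' @slot sweatIntermediateLow lower bound of the intermediate sweat band in
#'   mmol/L (default 30); the intermediate band is `[low, cf_cutoff)`.
#' @slot optionalSweatUptake Bernoulli probability that a family offered the
#'   optional sweat test takes it (default 0.13).
#' @export
setClass("AlgorithmThresholds",
         representation(irt1TopFraction = "numeric",
                        failsafeTopFraction = "numeric",
                        irt2Cutoff = "numeric",
                        sweatCfCutoff = "numeric",
                        sweatIntermediateLow = "numeric",
                        optionalSweatUptake = "numeric"),
         validity = function(object) {
             msg <- character()
             one <- function(x) length(x) == 1L && is.finite(x)
             if (!one(object@irt1TopFraction) ||
                 object@irt1TopFraction <= 0 || object@irt1TopFraction >= 1)
                 msg <- c(msg, "irt1_top_fraction must be in (0, 1)")
             if (!one(object@failsafeTopFraction) ||
                 object@failsafeTopFraction <= 0)
                 msg <- c(msg, "failsafe_top_fraction must be positive")
             if (one(object@failsafeTopFraction) && one(object@irt1TopFraction) &&
                 object@failsafeTopFraction >= object@irt1TopFraction)
                 msg <- c(msg,
                          "failsafe_top_fraction must be below irt1_top_fraction")
             if (!one(object@irt2Cutoff) || object@irt2Cutoff <= 0)
                 msg <- c(msg, "irt2_cutoff must be positive")
             if (!one(object@sweatCfCutoff) || !one(object@sweatIntermediateLow) ||
                 object@sweatIntermediateLow >= object@sweatCfCutoff)
                 msg <- c(msg,
                          "sweat_intermediate_low must be below sweat_cf_cutoff")
             if (!one(object@optionalSweatUptake) ||
                 object@optionalSweatUptake < 0 || object@optionalSweatUptake > 1)
                 msg <- c(msg, "optional_sweat_uptake must be in [0, 1]")
             if (length(msg)) msg else TRUE
         })

#' Construct the algorithm thresholds
#'
#' Defaults are the programme's published operating points: daily top 3% to
#' CFTR analysis, top 0.1% fail-safe, day-21 IRT referral above 40 ng/mL,
#' sweat chloride diagnostic at 60 mmol/L with the intermediate band starting
#' at 30 mmol/L, and 13% optional sweat-test uptake.
#'
#' @param irt1TopFraction,failsafeTopFraction,irt2Cutoff,sweatCfCutoff,sweatIntermediateLow,optionalSweatUptake
#'   see [AlgorithmThresholds-class].
#' @return An [AlgorithmThresholds-class] object.
#' @examples
#' algorithmThresholds()
#' @export
algorithmThresholds <- function(irt1TopFraction = 0.03,
                                failsafeTopFraction = 0.001,
                                irt2Cutoff = 40,
                                sweatCfCutoff = 60,
                                sweatIntermediateLow = 30,
                                optionalSweatUptake = 0.13) {
    new("AlgorithmThresholds",
        irt1TopFraction = as.numeric(irt1TopFraction),
        failsafeTopFraction = as.numeric(failsafeTopFraction),
        irt2Cutoff = as.numeric(irt2Cutoff),
        sweatCfCutoff = as.numeric(sweatCfCutoff),
        sweatIntermediateLow = as.numeric(sweatIntermediateLow),
        optionalSweatUptake = as.numeric(optionalSweatUptake))
}

#' @rdname algorithmThresholds
#' @export
defaultThresholds <- function() algorithmThresholds()

setMethod("show", "AlgorithmThresholds", function(object) {
    cat("AlgorithmThresholds\n")
    cat(sprintf("  IRT1 daily top fraction : %.3f\n", object@irt1TopFraction))
    cat(sprintf("  fail-safe top fraction  : %.4f\n", object@failsafeTopFraction))
    cat(sprintf("  IRT2 referral cutoff    : %g ng/mL (strict >)\n",
                object@irt2Cutoff))
    cat(sprintf("  sweat CF cutoff         : %g mmol/L (inclusive >=)\n",
                object@sweatCfCutoff))
    cat(sprintf("  sweat intermediate band : [%g, %g) mmol/L\n",
                object@sweatIntermediateLow, object@sweatCfCutoff))
    cat(sprintf("  optional sweat uptake   : %.2f\n", object@optionalSweatUptake))
})

## ---------------------------------------------------------------------------
## PopulationConfig

#' PopulationConfig: population and distribution parameters for the generator
#'
#' Everything the synthetic birth-cohort generator needs: the CFTR allele
#' table with functional classes and population frequencies, per-status
#' log-normal IRT parameters at both collection timepoints, per-status
#' truncated-normal sweat-chloride parameters, the meconium-ileus probability
#' given CF, the optional sweat-test uptake probability, per-arm triangular
#' contact-age parameters, and the daily batch size.
#'
#' @slot alleles data.frame with columns `allele_id`, `functional_class`,
#'   `frequency`; the benign remainder allele is implicit (frequency
#'   `1 - sum`).
#' @slot irtParams data.frame with columns `status`, `timepoint`
#'   (`"first"` or `"day21"`), `meanlog`, `sdlog` (log ng/mL scale).
#' @slot sweatParams data.frame with columns `status`, `mean`, `sd`
#'   (mmol/L); draws are truncated at zero.
#' @slot miProbGivenCf probability of meconium ileus given true CF.
#' @slot optionalSweatUptake probability a low-risk family takes the optional
#'   sweat test.
#' @slot contactAgeParams data.frame with columns `arm`, `min`, `median`,
#'   `max` (days) for arms that reach the CF clinic.
#' @slot dailyBatchSize number of infants per birth-day batch.
#' @export
setClass("PopulationConfig",
         representation(alleles = "data.frame",
                        irtParams = "data.frame",
                        sweatParams = "data.frame",
                        miProbGivenCf = "numeric",
                        optionalSweatUptake = "numeric",
                        contactAgeParams = "data.frame",
                        dailyBatchSize = "integer"),
         validity = function(object) {
             msg <- character()
             al <- object@alleles
             need <- c("allele_id", "functional_class", "frequency")
             if (!all(need %in% names(al))) {
                 msg <- c(msg, paste("alleles must have columns",
                                     paste(need, collapse = ", ")))
             } else {
                 if (anyDuplicated(al$allele_id))
                     msg <- c(msg, "alleles: allele_id must be unique")
                 if (!all(al$functional_class %in% alleleClassLevels()))
                     msg <- c(msg, "alleles: unknown functional_class value")
                 if (any(al$frequency < 0) ||
                     sum(al$frequency) > 1 + 1e-12)
                     msg <- c(msg,
                              "alleles: frequencies must be >= 0 and sum to <= 1")
             }
             ip <- object@irtParams
             needIp <- c("status", "timepoint", "meanlog", "sdlog")
             if (!all(needIp %in% names(ip))) {
                 msg <- c(msg, paste("irt params must have columns",
                                     paste(needIp, collapse = ", ")))
             } else {
                 if (!all(ip$status %in% statusLevels()) ||
                     !all(ip$timepoint %in% c("first", "day21")))
                     msg <- c(msg, "irt params: unknown status or timepoint")
                 if (any(!is.finite(ip$meanlog)) || any(ip$sdlog < 0))
                     msg <- c(msg, "irt params: sdlog must be >= 0")
             }
             sp <- object@sweatParams
             if (!all(c("status", "mean", "sd") %in% names(sp))) {
                 msg <- c(msg, "sweat params must have columns status, mean, sd")
             } else if (any(sp$mean < 0) || any(sp$sd < 0)) {
                 msg <- c(msg, "sweat params: mean and sd must be >= 0")
             }
             for (p in c(object@miProbGivenCf, object@optionalSweatUptake))
                 if (!is.finite(p) || p < 0 || p > 1)
                     msg <- c(msg, "probabilities must be in [0, 1]")
             ca <- object@contactAgeParams
             if (!all(c("arm", "min", "median", "max") %in% names(ca))) {
                 msg <- c(msg,
                          "contact age params must have columns arm, min, median, max")
             } else if (nrow(ca)) {
                 bad <- ca$min > ca$median | ca$median > ca$max | ca$min < 0
                 if (any(bad))
                     msg <- c(msg, paste("contact_age: need 0 <= min <= median <= max for arm",
                                         paste(ca$arm[bad], collapse = ", ")))
             }
             if (length(object@dailyBatchSize) != 1L ||
                 is.na(object@dailyBatchSize) || object@dailyBatchSize < 1L)
                 msg <- c(msg, "daily_batch_size must be a positive integer")
             if (length(msg)) msg else TRUE
         })

setMethod("show", "PopulationConfig", function(object) {
    al <- object@alleles
    cat("PopulationConfig\n")
    cat(sprintf("  alleles        : %d (%d cf_causing, %d varying_or_unclear); pathogenic allele mass %.5f\n",
                nrow(al), sum(al$functional_class == "cf_causing"),
                sum(al$functional_class == "varying_or_unclear"),
                sum(al$frequency[al$functional_class != "benign_or_none"])))
    cat(sprintf("  IRT params     : %d (status x timepoint) log-normal rows\n",
                nrow(object@irtParams)))
    cat(sprintf("  sweat params   : %d truncated-normal rows\n",
                nrow(object@sweatParams)))
    cat(sprintf("  P(MI | CF)     : %.4f\n", object@miProbGivenCf))
    cat(sprintf("  optional uptake: %.2f\n", object@optionalSweatUptake))
    cat(sprintf("  daily batch    : %d infants/day\n", object@dailyBatchSize))
})

## ---------------------------------------------------------------------------
## PerformanceReport

#' PerformanceReport: programme performance metrics
#'
#' Assembled by [buildReport()] from a labelled simulated cohort. All
#' percentages are on the 0--100 scale; unrounded values are stored and
#' rounding (integer percents for PPV, one decimal for NPV and rates) is
#' applied only for display.
#'
#' @slot nScreened number of infants screened.
#' @slot armCounts data.frame of routing-arm counts.
#' @slot channelCounts data.frame of detection-channel counts for true cases.
#' @slot ppvByArm data.frame with per-arm referral counts and PPV (CF and
#'   CF+CFSPID).
#' @slot npvDay21 named numeric, NPV of a normal day-21 IRT for CF and for
#'   CF+CFSPID, with the group size as attribute.
#' @slot sensitivity named numeric (percent), CF and CF+CFSPID.
#' @slot falseNegativeRate named numeric (percent), CF and CF+CFSPID.
#' @slot incidenceDenominator named numeric, the N of "1 in N" for CF and
#'   CF+CFSPID.
#' @slot sweatTestsAvoided single number.
#' @slot contactAgeSummary data.frame of per-arm contact-age medians/ranges.
#' @slot checks character vector of partition-consistency check messages.
#' @export
setClass("PerformanceReport",
         representation(nScreened = "numeric",
                        armCounts = "data.frame",
                        channelCounts = "data.frame",
                        ppvByArm = "data.frame",
                        npvDay21 = "numeric",
                        sensitivity = "numeric",
                        falseNegativeRate = "numeric",
                        incidenceDenominator = "numeric",
                        sweatTestsAvoided = "numeric",
                        contactAgeSummary = "data.frame",
                        checks = "character"))

setMethod("show", "PerformanceReport", function(object) {
    cat("PerformanceReport:", format(object@nScreened, big.mark = ","),
        "infants screened\n")
    cat("\nDetection channels (true cases):\n")
    print(object@channelCounts, row.names = FALSE)
    cat("\nPPV by referral arm:\n")
    print(object@ppvByArm, row.names = FALSE, digits = 3)
    npv <- object@npvDay21
    cat(sprintf("\nNPV of normal day-21 IRT (n = %d): CF %.1f%%, CF+CFSPID %.1f%%\n",
                attr(npv, "n"), npv[["cf"]], npv[["all"]]))
    cat(sprintf("Sensitivity: CF %.1f%%, CF+CFSPID %.1f%%\n",
                object@sensitivity[["cf"]], object@sensitivity[["all"]]))
    cat(sprintf("False-negative rate: CF %.1f%%, CF+CFSPID %.1f%%\n",
                object@falseNegativeRate[["cf"]],
                object@falseNegativeRate[["all"]]))
    inc <- object@incidenceDenominator
    cat(sprintf("Birth incidence: CF 1/%d, CF+CFSPID 1/%d\n",
                round(inc[["cf"]]), round(inc[["all"]])))
    cat(sprintf("Sweat tests avoided: %d\n", round(object@sweatTestsAvoided)))
    if (nrow(object@contactAgeSummary)) {
        cat("\nTime to first CF clinic contact (days):\n")
        print(object@contactAgeSummary, row.names = FALSE)
    }
    if (length(object@checks))
        cat("\nChecks:", paste(object@checks, collapse = "; "), "\n")
})

## ---------------------------------------------------------------------------
## RunConfig

#' RunConfig: a fully resolved pipeline run configuration
#'
#' @slot population a [PopulationConfig-class].
#' @slot thresholds an [AlgorithmThresholds-class].
#' @slot panelName name of the mutation panel to use (one of the bundled
#'   presets or a user-supplied panel).
#' @slot nInfants cohort size for simulation runs.
#' @slot outputPrefix path prefix for output files.
#' @slot seed master seed for all randomness of the run.
#' @export
setClass("RunConfig",
         representation(population = "PopulationConfig",
                        thresholds = "AlgorithmThresholds",
                        panelName = "character",
                        nInfants = "numeric",
                        outputPrefix = "character",
                        seed = "numeric"),
         validity = function(object) {
             msg <- character()
             if (length(object@nInfants) != 1L || is.na(object@nInfants) ||
                 object@nInfants < 0)
                 msg <- c(msg, "n_infants must be >= 0")
             if (length(object@panelName) != 1L || !nzchar(object@panelName))
                 msg <- c(msg, "panel must be a single panel name")
             if (length(msg)) msg else TRUE
         })

setMethod("show", "RunConfig", function(object) {
    cat("RunConfig\n")
    cat(sprintf("  panel   : %s\n", object@panelName))
    cat(sprintf("  n       : %s infants\n",
                format(object@nInfants, big.mark = ",")))
    cat(sprintf("  seed    : %d\n", as.integer(object@seed)))
    cat(sprintf("  output  : %s\n", object@outputPrefix))
})
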