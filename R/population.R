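## Default synthetic population: CFTR allele table, status-conditional
## biomarker distributions, contact-age parameters. All values are package
## defaults chosen to emulate the operating conditions of a large
## single-centre IRT-DNA-IRT programme; every one is overridable through
## PopulationConfig / the YAML run configuration.

## Geometric-decay weights summing to `total` over `k` alleles.
.decayWeights <- function(k, total, ratio = 0.85) {
    if (k == 0L) return(numeric())
    w <- ratio^(seq_len(k) - 1L)
    w / sum(w) * total
}

#' Default synthetic CFTR allele table
#'
#' Builds a synthetic allele catalogue under Hardy-Weinberg sampling:
#' 150 CF-causing alleles (`CF001`..`CF150`) and six alleles of varying or
#' unclear consequence (`VU001`..`VU006`), with the benign/none remainder
#' implicit. Total pathogenic-allele frequencies are solved so the CF
#' genotype probability is `cfGenotypeProb` and the CFSPID-type genotype
#' probability is `cfspidGenotypeProb`.
#'
#' The within-class frequency profile is block-structured so the bundled
#' nested panels (24/38/130 alleles) cover roughly 83/86/90% of CF-causing
#' allele mass: one dominant allele (70%, an F508del-like major allele),
#' a decaying common block, two rarer blocks, and a 9.6% off-panel tail.
#'
#' @param cfGenotypeProb probability that a newborn has a CF genotype
#'   (two CF-causing alleles); default 1/5289.
#' @param cfspidGenotypeProb probability of a CFSPID-type genotype (two
#'   non-benign alleles, not both CF-causing); default 28/401977.
#' @return data.frame with columns `allele_id`, `functional_class`,
#'   `frequency`.
#' @export
defaultAlleleTable <- function(cfGenotypeProb = 1 / 5289,
                               cfspidGenotypeProb = 28 / 401977) {
    stopifnot(cfGenotypeProb >= 0, cfspidGenotypeProb >= 0,
              cfGenotypeProb + cfspidGenotypeProb < 1)
    pCf <- sqrt(cfGenotypeProb)
    ## (pCf + pVu)^2 - pCf^2 = cfspidGenotypeProb
    pVu <- sqrt(pCf^2 + cfspidGenotypeProb) - pCf
    cfWeights <- c(0.70,
                   .decayWeights(21L, 0.127),   # CF002-CF022 (panel24 block)
                   .decayWeights(12L, 0.034),   # CF023-CF034 (panel38 block)
                   .decayWeights(90L, 0.043),   # CF035-CF124 (panel130 block)
                   .decayWeights(26L, 0.096))   # CF125-CF150 off-panel tail
    vuWeights <- .decayWeights(6L, 1, ratio = 0.6)
    data.frame(
        allele_id = c(sprintf("CF%03d", seq_len(150L)),
                      sprintf("VU%03d", seq_len(6L))),
        functional_class = c(rep("cf_causing", 150L),
                             rep("varying_or_unclear", 6L)),
        frequency = c(cfWeights * pCf, vuWeights * pVu),
        stringsAsFactors = FALSE)
}

#' Default population configuration
#'
#' The generator's default operating conditions:
#' \itemize{
#'   \item CF genotype probability 1/5289 and CFSPID-type probability
#'     28/401977 via Hardy-Weinberg allele frequencies
#'     ([defaultAlleleTable()]).
#'   \item Log-normal IRT distributions per status and timepoint. The
#'     unaffected day-21 distribution is calibrated so its 90th percentile
#'     is 40 ng/mL ([calibrateDay21Params()]); the CF first-draw
#'     distribution leaves about 4-5% of CF cases below the daily top-3%
#'     cutoff; the carrier day-21 tail above 40 ng/mL is about 3.7%.
#'   \item Truncated-at-zero normal sweat chloride: CF 95/15, CFSPID-type
#'     40/7, carrier and unaffected 15/6 (mmol/L), placing >= 99% of CF
#'     draws above 60 and >= 90% of CFSPID-type draws in [30, 60).
#'   \item Meconium ileus probability 3/76 given CF; optional sweat uptake
#'     0.13; daily batch 123 infants (~45,000 births/year).
#'   \item Triangular contact-age distributions per referral arm with
#'     (min, median, max) of (10, 22, 50) days for two-mutation referrals
#'     and (12, 31, 39) days for day-21 IRT referrals.
#' }
#'
#' @param cfGenotypeProb,cfspidGenotypeProb passed to
#'   [defaultAlleleTable()].
#' @return A [PopulationConfig-class] object.
#' @examples
#' cfg <- defaultPopulation()
#' cfg
#' @export
defaultPopulation <- function(cfGenotypeProb = 1 / 5289,
                              cfspidGenotypeProb = 28 / 401977) {
    irt <- rbind(
        data.frame(status = c("unaffected", "carrier", "cfspid_type", "cf"),
                   timepoint = "first",
                   meanlog = c(log(18), log(22), log(60), log(100)),
                   sdlog = c(0.45, 0.45, 0.50, 0.50)),
        data.frame(status = c("unaffected", "carrier", "cfspid_type", "cf"),
                   timepoint = "day21",
                   meanlog = c(calibrateDay21Params(40, 0.90, 0.35),
                               calibrateDay21Params(40, 1 - 0.0372, 0.25),
                               log(40), log(120)),
                   sdlog = c(0.35, 0.25, 0.45, 0.50)))
    sweat <- data.frame(status = c("cf", "cfspid_type", "carrier", "unaffected"),
                        mean = c(95, 40, 15, 15),
                        sd = c(15, 7, 6, 6))
    contact <- data.frame(
        arm = c("positive_two_mutations", "referred_high_irt2",
                "failsafe_irt2", "optional_sweat_done", "prior_mi_referral",
                "direct_referral"),
        min = c(10, 12, 12, 60, 1, 10),
        median = c(22, 31, 31, 110, 5, 22),
        max = c(50, 39, 39, 160, 14, 50))
    new("PopulationConfig",
        alleles = defaultAlleleTable(cfGenotypeProb, cfspidGenotypeProb),
        irtParams = irt,
        sweatParams = sweat,
        miProbGivenCf = 3 / 76,
        optionalSweatUptake = 0.13,
        contactAgeParams = contact,
        dailyBatchSize = 123L)
}

#' Bundled synthetic mutation panels
#'
#' Three nested synthetic panel presets of sizes 24, 38 and 130 mirroring a
#' programme's assay succession. Each panel is a superset of the previous
#' one. Members are drawn from the default allele table: the 24-allele panel
#' carries the 22 most common CF-causing alleles plus two varying/unclear
#' alleles; the supersets add the next CF-causing blocks and further
#' varying/unclear alleles. Alleles `CF125`..`CF150` are on no panel (the
#' "rare mutation" tail responsible for panel misses).
#'
#' @return Named list of three [MutationPanel-class] objects
#'   (`panel24`, `panel38`, `panel130`).
#' @examples
#' vapply(bundledPanels(), panelSize, integer(1))
#' @export
bundledPanels <- function() {
    p24 <- c(sprintf("CF%03d", 1:22), sprintf("VU%03d", 1:2))
    p38 <- c(p24, sprintf("CF%03d", 23:34), sprintf("VU%03d", 3:4))
    p130 <- c(p38, sprintf("CF%03d", 35:124), sprintf("VU%03d", 5:6))
    list(panel24 = mutationPanel("panel24", p24),
         panel38 = mutationPanel("panel38", p38),
         panel130 = mutationPanel("panel130", p130))
}

## Named vector mapping allele_id -> functional class, including the
## implicit benign remainder allele ".none".
alleleClasses <- function(config) {
    al <- config@alleles
    stats::setNames(c(al$functional_class, "benign_or_none"),
                    c(al$allele_id, ".none"))
}
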