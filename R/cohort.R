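## Synthetic birth-cohort generation: Hardy-Weinberg CFTR genotypes,
## status-conditional log-normal IRT draws at both collection timepoints,
## truncated-normal sweat chloride, meconium ileus, and the pre-drawn
## optional-sweat uniform.

#' Derive ground-truth status from a pair of allele functional classes
#'
#' Two CF-causing alleles give `cf`; two non-benign alleles not both
#' CF-causing give `cfspid_type`; exactly one non-benign allele gives
#' `carrier`; otherwise `unaffected`. The pair is unordered.
#'
#' @param classA,classB character vectors of functional classes (see
#'   [alleleClassLevels()]).
#' @return Character vector of statuses.
#' @export
trueStatusFromClasses <- function(classA, classB) {
    stopifnot(all(classA %in% alleleClassLevels()),
              all(classB %in% alleleClassLevels()))
    aPath <- classA != "benign_or_none"
    bPath <- classB != "benign_or_none"
    cf <- classA == "cf_causing" & classB == "cf_causing"
    both <- aPath & bPath
    out <- rep("unaffected", length(cf))
    out[aPath != bPath] <- "carrier"
    out[both] <- "cfspid_type"
    out[cf] <- "cf"
    out
}

#' Sample CFTR genotypes under Hardy-Weinberg equilibrium
#'
#' Draws two independent alleles per genotype from the configured allele
#' frequencies, with the benign remainder allele (id `".none"`) taking the
#' leftover probability mass. Uses the caller's RNG state.
#'
#' @param config a [PopulationConfig-class].
#' @param n number of genotypes to draw.
#' @return data.frame with columns `allele_a`, `allele_b`, `true_status`.
#' @examples
#' set.seed(1)
#' sampleGenotype(defaultPopulation(), 5)
#' @export
sampleGenotype <- function(config, n = 1L) {
    stopifnot(is(config, "PopulationConfig"), n >= 0)
    al <- config@alleles
    rest <- 1 - sum(al$frequency)
    if (rest < -1e-12)
        stop("allele frequencies sum above 1")
    ids <- c(al$allele_id, ".none")
    freqs <- c(al$frequency, max(rest, 0))
    idx <- sample.int(length(ids), 2L * n, replace = TRUE, prob = freqs)
    a <- ids[idx[seq_len(n)]]
    b <- ids[idx[n + seq_len(n)]]
    cls <- alleleClasses(config)
    data.frame(allele_a = a, allele_b = b,
               true_status = trueStatusFromClasses(cls[a], cls[b]),
               stringsAsFactors = FALSE)
}

## Look up (status, timepoint) log-normal parameter rows; error names the
## missing pair. Returns list(meanlog, sdlog) aligned with `status`.
.irtParamsFor <- function(status, timepoint, config) {
    ip <- config@irtParams[config@irtParams$timepoint == timepoint, ]
    m <- match(status, ip$status)
    if (anyNA(m))
        stop("no IRT parameters for status '",
             status[which(is.na(m))[1L]], "' at timepoint '", timepoint, "'")
    list(meanlog = ip$meanlog[m], sdlog = ip$sdlog[m])
}

#' Sample IRT values for a given status and timepoint
#'
#' IRT (ng/mL) is drawn from the configured log-normal distribution for the
#' (status, timepoint) pair; a zero spread gives the degenerate point mass
#' at `exp(meanlog)`. Uses the caller's RNG state.
#'
#' @param status one of [statusLevels()] (scalar or vector; recycled
#'   against `n` when scalar).
#' @param timepoint `"first"` (collection at 24-48 h) or `"day21"`.
#' @param config a [PopulationConfig-class].
#' @param n number of draws (ignored when `status` has length > 1).
#' @return Numeric vector of non-negative IRT values in ng/mL.
#' @export
sampleIrt <- function(status, timepoint = c("first", "day21"), config,
                      n = 1L) {
    timepoint <- match.arg(timepoint)
    if (length(status) == 1L) status <- rep(status, n)
    p <- .irtParamsFor(status, timepoint, config)
    u <- stats::runif(length(status))
    stats::qlnorm(u, meanlog = p$meanlog, sdlog = p$sdlog)
}

#' Calibrate the day-21 log-normal location to a target quantile
#'
#' Returns the `meanlog` for which the log-normal distribution with spread
#' `sdlog` has its `targetQuantile` quantile exactly at
#' `targetQuantileValue`. With the defaults this pins the unaffected day-21
#' IRT 90th percentile at the 40 ng/mL referral cutoff.
#'
#' @param targetQuantileValue the quantile value in ng/mL (default 40).
#' @param targetQuantile the quantile level in (0, 1) (default 0.90).
#' @param sdlog log-scale spread (>= 0).
#' @return The `meanlog` location parameter.
#' @examples
#' m <- calibrateDay21Params(40, 0.9, 0.35)
#' qlnorm(0.9, m, 0.35)  # 40
#' @export
calibrateDay21Params <- function(targetQuantileValue = 40,
                                 targetQuantile = 0.90, sdlog = 0.35) {
    if (!is.finite(targetQuantileValue) || targetQuantileValue <= 0)
        stop("targetQuantileValue must be positive")
    if (!is.finite(targetQuantile) || targetQuantile <= 0 ||
        targetQuantile >= 1)
        stop("targetQuantile must be in (0, 1)")
    if (!is.finite(sdlog) || sdlog < 0)
        stop("sdlog must be >= 0")
    log(targetQuantileValue) - stats::qnorm(targetQuantile) * sdlog
}

#' Sample sweat chloride for a given status
#'
#' Sweat chloride (mmol/L) is drawn from the configured normal distribution
#' truncated at zero. With the defaults, at least 99% of CF draws fall above
#' 60 mmol/L, at least 90% of CFSPID-type draws fall in the intermediate
#' band [30, 60), and at least 99% of carrier/unaffected draws fall below
#' 30 mmol/L. Uses the caller's RNG state.
#'
#' @inheritParams sampleIrt
#' @return Numeric vector of non-negative sweat chloride values in mmol/L.
#' @export
sampleSweatChloride <- function(status, config, n = 1L) {
    if (length(status) == 1L) status <- rep(status, n)
    sp <- config@sweatParams
    m <- match(status, sp$status)
    if (anyNA(m))
        stop("no sweat chloride parameters for status '",
             status[which(is.na(m))[1L]], "'")
    mean <- sp$mean[m]; sd <- sp$sd[m]
    u <- stats::runif(length(status))
    ## inverse-CDF truncation at zero; sd = 0 degenerates to the location
    p0 <- stats::pnorm(0, mean = mean, sd = sd)
    stats::qnorm(p0 + u * (1 - p0), mean = mean, sd = sd)
}

## Solve the triangular mode on [a, b] so the distribution median equals m.
## Attainable medians are [b - (b-a)/sqrt(2), a + (b-a)/sqrt(2)].
.triangularMode <- function(a, m, b) {
    if (a == b) return(a)
    lo <- b - (b - a) / sqrt(2)
    hi <- a + (b - a) / sqrt(2)
    if (m < lo - 1e-9 || m > hi + 1e-9)
        stop(sprintf("median %g is not attainable on [%g, %g] by a triangular distribution",
                     m, a, b))
    if (m >= (a + b) / 2) a + 2 * (m - a)^2 / (b - a)
    else b - 2 * (b - m)^2 / (b - a)
}

#' Sample age at first CF clinic contact for a referral arm
#'
#' Contact ages (days) follow a triangular distribution on the configured
#' `[min, max]` range whose mode is solved so the distribution median equals
#' the configured median. Arms without clinic contact (screen-negative
#' routes) have no parameters and raise an error.
#'
#' @param arm a routing arm name (see [armLevels()]).
#' @param config a [PopulationConfig-class].
#' @param n number of draws.
#' @return Numeric vector of ages in days, bounded by the configured range.
#' @export
sampleContactAge <- function(arm, config, n = 1L) {
    stopifnot(length(arm) == 1L)
    ca <- config@contactAgeParams
    row <- match(arm, ca$arm)
    if (is.na(row))
        stop("no contact-age parameters for arm '", arm,
             "' (screen-negative arms have no clinic contact)")
    a <- ca$min[row]; m <- ca$median[row]; b <- ca$max[row]
    if (a == b) return(rep(a, n))
    cc <- .triangularMode(a, m, b)
    u <- stats::runif(n)
    fc <- (cc - a) / (b - a)
    ifelse(u < fc,
           a + sqrt(u * (b - a) * (cc - a)),
           b - sqrt((1 - u) * (b - a) * (b - cc)))
}

#' Generate a synthetic birth cohort
#'
#' Draws `n` newborn records with ground-truth genotype and status,
#' meconium ileus, IRT at first collection and day 21, sweat chloride, and
#' the pre-drawn optional-sweat uniform. Each sampled field uses its own
#' RNG sub-stream derived from `seed`, so output is bit-for-bit
#' reproducible and robust to changes in other fields' samplers. Birth days
#' are assigned in blocks of `config@dailyBatchSize` (the last day may be
#' partial).
#'
#' @param n cohort size (>= 0).
#' @param config a [PopulationConfig-class].
#' @param seed master integer seed.
#' @return data.frame with columns `infant_id`, `birth_day`, `allele_a`,
#'   `allele_b`, `true_status`, `meconium_ileus`, `irt1`, `irt2`,
#'   `sweat_chloride`, `uptake_draw`.
#' @examples
#' cohort <- generateCohort(500, defaultPopulation(), seed = 1)
#' table(cohort$true_status)
#' @export
generateCohort <- function(n, config = defaultPopulation(), seed = 1L) {
    stopifnot(n >= 0)
    validObject(config)
    n <- as.integer(n)
    cols <- c("infant_id", "birth_day", "allele_a", "allele_b",
              "true_status", "meconium_ileus", "irt1", "irt2",
              "sweat_chloride", "uptake_draw")
    if (n == 0L) {
        out <- data.frame(infant_id = character(), birth_day = integer(),
                          allele_a = character(), allele_b = character(),
                          true_status = character(),
                          meconium_ileus = logical(), irt1 = numeric(),
                          irt2 = numeric(), sweat_chloride = numeric(),
                          uptake_draw = numeric(),
                          stringsAsFactors = FALSE)
        return(out[cols])
    }
    st <- fieldStreams()
    geno <- withSubstream(seed, st[["genotype"]], sampleGenotype(config, n))
    status <- geno$true_status
    mi <- withSubstream(seed, st[["mi"]],
                        status == "cf" & stats::runif(n) < config@miProbGivenCf)
    irt1 <- withSubstream(seed, st[["irt1"]],
                          sampleIrt(status, "first", config))
    irt2 <- withSubstream(seed, st[["irt2"]],
                          sampleIrt(status, "day21", config))
    sweat <- withSubstream(seed, st[["sweat"]],
                           sampleSweatChloride(status, config))
    uptake <- withSubstream(seed, st[["uptake"]], stats::runif(n))
    data.frame(infant_id = sprintf("NB%07d", seq_len(n)),
               birth_day = (seq_len(n) - 1L) %/% config@dailyBatchSize + 1L,
               allele_a = geno$allele_a,
               allele_b = geno$allele_b,
               true_status = status,
               meconium_ileus = mi,
               irt1 = irt1,
               irt2 = irt2,
               sweat_chloride = sweat,
               uptake_draw = uptake,
               stringsAsFactors = FALSE)
}
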