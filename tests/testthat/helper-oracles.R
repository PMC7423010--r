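# Independent oracles and small fixture builders shared across tests.

# Brute-force top-k selection with stable ties: repeatedly take the maximum,
# earliest index first. Independent of the order()-based implementation.
bruteTopFraction <- function(values, fraction) {
    k <- ceiling(fraction * length(values) - 1e-9)
    remaining <- seq_along(values)
    picked <- integer()
    for (i in seq_len(k)) {
        best <- remaining[which.max(values[remaining])]
        picked <- c(picked, best)
        remaining <- setdiff(remaining, best)
    }
    sort(picked)
}

# Bisection quantile oracle on a CDF (used to cross-check the closed-form
# day-21 calibration).
bisectQuantile <- function(cdf, p, lower = 1e-9, upper = 1e6,
                           tol = 1e-9) {
    while (upper - lower > tol * max(1, lower)) {
        mid <- (lower + upper) / 2
        if (cdf(mid) < p) lower <- mid else upper <- mid
    }
    (lower + upper) / 2
}

# A three-allele population: one common panel CF allele, one panel
# varying/unclear allele, one off-panel CF allele. Frequencies configurable
# so genotype-class probabilities are controlled exactly.
tinyPopulation <- function(pCfOn = 0.01, pVu = 0.003, pCfOff = 0.002,
                           batch = 10L) {
    pop <- defaultPopulation()
    pop@alleles <- data.frame(
        allele_id = c("CFA", "VUB", "OFFC"),
        functional_class = c("cf_causing", "varying_or_unclear",
                             "cf_causing"),
        frequency = c(pCfOn, pVu, pCfOff),
        stringsAsFactors = FALSE)
    pop@dailyBatchSize <- as.integer(batch)
    pop
}

tinyPanel <- function() mutationPanel("tiny", c("CFA", "VUB"))

# One manually specified newborn record (ground truth derived from the
# supplied population's allele classes).
makeRecord <- function(id = "X1", alleleA = ".none", alleleB = ".none",
                       mi = FALSE, irt1 = 20, irt2 = 20, sweat = 15,
                       uptake = 0.99, pop = tinyPopulation()) {
    cls <- stats::setNames(
        c(pop@alleles$functional_class, "benign_or_none"),
        c(pop@alleles$allele_id, ".none"))
    data.frame(infant_id = id, birth_day = 1L,
               allele_a = alleleA, allele_b = alleleB,
               true_status = trueStatusFromClasses(cls[[alleleA]],
                                                   cls[[alleleB]]),
               meconium_ileus = mi, irt1 = irt1, irt2 = irt2,
               sweat_chloride = sweat, uptake_draw = uptake,
               stringsAsFactors = FALSE)
}
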