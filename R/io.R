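## File I/O: cohort and results tables as commented CSV, the YAML run
## configuration with full validation, and the bundled printed-counts
## fixture.

packageVersionString <- function() {
    as.character(utils::packageVersion("CFScreenSim"))
}

#' Short hash of a run configuration
#'
#' MD5 (first 8 hex digits) of the YAML serialization of the configuration,
#' written into output-file headers so a results file can be matched to the
#' exact configuration that produced it.
#'
#' @param config a [RunConfig-class], [PopulationConfig-class] or any
#'   YAML-serializable object.
#' @return 8-character hash string.
#' @export
configHash <- function(config) {
    obj <- if (is(config, "RunConfig")) .runConfigToList(config)
           else if (is(config, "PopulationConfig")) .populationToList(config)
           else config
    tf <- tempfile(fileext = ".yaml")
    on.exit(unlink(tf))
    yaml::write_yaml(obj, tf)
    substr(unname(tools::md5sum(tf)), 1L, 8L)
}

.writeCommented <- function(df, path, seed = NA, hash = NA,
                            what = "table", numericCols = character()) {
    for (cl in intersect(numericCols, names(df))) {
        x <- as.numeric(df[[cl]])
        v <- trimws(formatC(x, format = "f", digits = 4))
        v[is.na(x)] <- "NA"
        df[[cl]] <- v
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# CFScreenSim %s %s", packageVersionString(), what),
                 sprintf("# seed: %s", seed),
                 sprintf("# config_hash: %s", hash),
                 sprintf("# records: %d", nrow(df))), con)
    utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
}

#' Read and write cohort tables
#'
#' Cohorts are comma-separated text with a header row and leading `#`
#' comment lines carrying the package version, seed and configuration hash
#' (no timestamps, so identical runs are byte-identical). Floating-point
#' columns are written at 4 decimals.
#'
#' @param cohort cohort data.frame from [generateCohort()].
#' @param path file path.
#' @param seed,config recorded in the header for provenance.
#' @return `writeCohort()` returns `path` invisibly; `readCohort()` returns
#'   the cohort data.frame.
#' @export
writeCohort <- function(cohort, path, seed = NA, config = NULL) {
    hash <- if (!is.null(config)) configHash(config) else NA
    .writeCommented(cohort, path, seed, hash, "cohort",
                    c("irt1", "irt2", "sweat_chloride", "uptake_draw"))
    invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
    if (!file.exists(path))
        stop("cohort file not found: ", path)
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = c(infant_id = "character"))
}

#' Read and write screening-results tables
#'
#' Same commented-CSV conventions as [writeCohort()]. The labelled variant
#' (after [labelCohort()]) round-trips the diagnostic label and detection
#' channel columns as well.
#'
#' @param results results data.frame from [runProgram()] or
#'   [labelCohort()].
#' @inheritParams writeCohort
#' @export
writeResults <- function(results, path, seed = NA, config = NULL) {
    hash <- if (!is.null(config)) configHash(config) else NA
    .writeCommented(results, path, seed, hash, "results",
                    "contact_age_days")
    invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
    if (!file.exists(path))
        stop("results file not found: ", path)
    out <- utils::read.csv(path, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = c(infant_id = "character"))
    out$arm <- factor(out$arm, levels = armLevels())
    if ("detection_channel" %in% names(out))
        out$detection_channel <- factor(out$detection_channel,
                                        levels = detectionChannelLevels())
    if ("diagnostic_label" %in% names(out))
        out$diagnostic_label <- factor(out$diagnostic_label,
                                       levels = diagnosticLabelLevels())
    out
}

#' Load the bundled printed-counts fixture
#'
#' @param path fixture path; defaults to the YAML bundled with the package.
#' @return Named list of counts (see [reproducePrintedCounts()]).
#' @export
printedCounts <- function(path = system.file("extdata",
                                             "bc_printed_counts.yaml",
                                             package = "CFScreenSim")) {
    if (!nzchar(path) || !file.exists(path))
        stop("printed-counts fixture not found")
    yaml::read_yaml(path)
}

## ---------------------------------------------------------------------------
## Run configuration <-> YAML

.populationToList <- function(pop) {
    ip <- pop@irtParams
    irt <- list()
    for (tp in unique(ip$timepoint))
        irt[[tp]] <- lapply(split(ip[ip$timepoint == tp, ],
                                  ip$status[ip$timepoint == tp]),
                            function(r) list(meanlog = r$meanlog,
                                             sdlog = r$sdlog))
    sweat <- lapply(split(pop@sweatParams, pop@sweatParams$status),
                    function(r) list(mean = r$mean, sd = r$sd))
    ca <- pop@contactAgeParams
    contact <- lapply(split(ca, ca$arm),
                      function(r) list(min = r$min, median = r$median,
                                       max = r$max))
    list(alleles = lapply(seq_len(nrow(pop@alleles)), function(i)
             list(id = pop@alleles$allele_id[i],
                  class = pop@alleles$functional_class[i],
                  frequency = pop@alleles$frequency[i])),
         irt = irt,
         sweat = sweat,
         mi_prob_given_cf = pop@miProbGivenCf,
         optional_sweat_uptake = pop@optionalSweatUptake,
         contact_age = contact,
         daily_batch_size = as.integer(pop@dailyBatchSize))
}

.thresholdsToList <- function(th) {
    list(irt1_top_fraction = th@irt1TopFraction,
         failsafe_top_fraction = th@failsafeTopFraction,
         irt2_cutoff = th@irt2Cutoff,
         sweat_cf_cutoff = th@sweatCfCutoff,
         sweat_intermediate_low = th@sweatIntermediateLow,
         optional_sweat_uptake = th@optionalSweatUptake)
}

.runConfigToList <- function(cfg) {
    list(population = .populationToList(cfg@population),
         thresholds = .thresholdsToList(cfg@thresholds),
         panel = cfg@panelName,
         n_infants = cfg@nInfants,
         output_prefix = cfg@outputPrefix,
         seed = cfg@seed)
}

.checkKeys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown))
        stop("unknown configuration key(s) in ", where, ": ",
             paste(unknown, collapse = ", "))
}

.populationFromList <- function(x) {
    pop <- defaultPopulation()
    if (is.null(x)) return(pop)
    .checkKeys(x, c("alleles", "irt", "sweat", "mi_prob_given_cf",
                    "optional_sweat_uptake", "contact_age",
                    "daily_batch_size"), "population")
    if (!is.null(x$alleles))
        pop@alleles <- data.frame(
            allele_id = vapply(x$alleles, `[[`, "", "id"),
            functional_class = vapply(x$alleles, `[[`, "", "class"),
            frequency = vapply(x$alleles, `[[`, 0, "frequency"),
            stringsAsFactors = FALSE)
    if (!is.null(x$irt)) {
        .checkKeys(x$irt, c("first", "day21"), "population$irt")
        ip <- pop@irtParams
        for (tp in names(x$irt))
            for (st in names(x$irt[[tp]])) {
                row <- ip$status == st & ip$timepoint == tp
                if (!any(row))
                    ip <- rbind(ip, data.frame(status = st, timepoint = tp,
                                               meanlog = NA_real_,
                                               sdlog = NA_real_))
                row <- ip$status == st & ip$timepoint == tp
                ip$meanlog[row] <- x$irt[[tp]][[st]]$meanlog
                ip$sdlog[row] <- x$irt[[tp]][[st]]$sdlog
            }
        pop@irtParams <- ip
    }
    if (!is.null(x$sweat)) {
        sp <- pop@sweatParams
        for (st in names(x$sweat)) {
            row <- sp$status == st
            if (!any(row))
                sp <- rbind(sp, data.frame(status = st, mean = NA_real_,
                                           sd = NA_real_))
            row <- sp$status == st
            sp$mean[row] <- x$sweat[[st]]$mean
            sp$sd[row] <- x$sweat[[st]]$sd
        }
        pop@sweatParams <- sp
    }
    if (!is.null(x$mi_prob_given_cf))
        pop@miProbGivenCf <- x$mi_prob_given_cf
    if (!is.null(x$optional_sweat_uptake))
        pop@optionalSweatUptake <- x$optional_sweat_uptake
    if (!is.null(x$contact_age)) {
        ca <- pop@contactAgeParams
        for (arm in names(x$contact_age)) {
            row <- ca$arm == arm
            if (!any(row))
                ca <- rbind(ca, data.frame(arm = arm, min = NA_real_,
                                           median = NA_real_,
                                           max = NA_real_))
            row <- ca$arm == arm
            ca$min[row] <- x$contact_age[[arm]]$min
            ca$median[row] <- x$contact_age[[arm]]$median
            ca$max[row] <- x$contact_age[[arm]]$max
        }
        pop@contactAgeParams <- ca
    }
    if (!is.null(x$daily_batch_size))
        pop@dailyBatchSize <- as.integer(x$daily_batch_size)
    validObject(pop)
    pop
}

.thresholdsFromList <- function(x) {
    if (is.null(x)) return(defaultThresholds())
    .checkKeys(x, c("irt1_top_fraction", "failsafe_top_fraction",
                    "irt2_cutoff", "sweat_cf_cutoff",
                    "sweat_intermediate_low", "optional_sweat_uptake"),
               "thresholds")
    d <- defaultThresholds()
    algorithmThresholds(
        irt1TopFraction = x$irt1_top_fraction %||% d@irt1TopFraction,
        failsafeTopFraction = x$failsafe_top_fraction %||%
            d@failsafeTopFraction,
        irt2Cutoff = x$irt2_cutoff %||% d@irt2Cutoff,
        sweatCfCutoff = x$sweat_cf_cutoff %||% d@sweatCfCutoff,
        sweatIntermediateLow = x$sweat_intermediate_low %||%
            d@sweatIntermediateLow,
        optionalSweatUptake = x$optional_sweat_uptake %||%
            d@optionalSweatUptake)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and save run configurations
#'
#' The run configuration is a nested-key YAML file; every key is optional
#' and absent keys take package defaults, so an empty file yields the
#' default configuration. Unknown keys and invariant violations are errors
#' naming the offending key.
#'
#' @param path YAML file path.
#' @return `loadRunConfig()` returns a validated [RunConfig-class];
#'   `saveRunConfig()` writes `config` to `path` and returns it invisibly.
#' @examples
#' tf <- tempfile(fileext = ".yaml")
#' writeLines("thresholds:\n  irt2_cutoff: 45", tf)
#' loadRunConfig(tf)
#' @export
loadRunConfig <- function(path) {
    if (!file.exists(path))
        stop("configuration file not found: ", path)
    x <- yaml::read_yaml(path)
    if (is.null(x)) x <- list()
    .checkKeys(x, c("population", "thresholds", "panel", "n_infants",
                    "output_prefix", "seed"), "run configuration")
    cfg <- new("RunConfig",
               population = .populationFromList(x$population),
               thresholds = .thresholdsFromList(x$thresholds),
               panelName = x$panel %||% "panel130",
               nInfants = as.numeric(x$n_infants %||% 45000),
               outputPrefix = x$output_prefix %||% "cfscreen",
               seed = as.numeric(x$seed %||% 1))
    validObject(cfg)
    cfg
}

#' @rdname loadRunConfig
#' @param config a [RunConfig-class].
#' @export
saveRunConfig <- function(config, path) {
    stopifnot(is(config, "RunConfig"))
    yaml::write_yaml(.runConfigToList(config), path,
                     precision = 15L)
    invisible(config)
}

#' Resolve a panel name to a bundled panel
#'
#' @param name one of `"panel24"`, `"panel38"`, `"panel130"`.
#' @return A [MutationPanel-class].
#' @export
resolvePanel <- function(name) {
    panels <- bundledPanels()
    if (!name %in% names(panels))
        stop("unknown panel '", name, "'; bundled panels: ",
             paste(names(panels), collapse = ", "))
    panels[[name]]
}
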