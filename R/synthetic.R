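#' Configuration for the synthetic AML cohort generator
#'
#' Bundles and validates the generator parameters. Defaults correspond to
#' the reference cohort used throughout the package's validation: 400
#' samples, 2,000 genes, a 50-gene mutant expression program shifted by
#' 1.5 log2 units, 9% mutant prevalence, and a hidden 10% of wild-type
#' samples carrying the full program (the planted mutant-like class).
#'
#' @param n_samples number of samples (default 400).
#' @param n_genes number of genes (default 2000).
#' @param n_program_genes size of the planted mutant expression program
#'   (default 50, must be <= `n_genes`).
#' @param mutant_prevalence fraction of samples that are TP53 mutant, in
#'   (0, 1) (default 0.09).
#' @param mutlike_fraction fraction of wild-type samples carrying the full
#'   program, in \[0, 1) (default 0.10).
#' @param effect_size_delta program shift in log2 expression units per
#'   unit activation (default 1.5).
#' @param baseline_log_mean_range interval of baseline log2 mean
#'   expression (default c(3, 9)).
#' @param dispersion global negative-binomial dispersion (> 0,
#'   default 0.15; variance = mu + dispersion * mu^2).
#' @param hazard_coef_gamma log-hazard increase per unit activation
#'   (default 1.5).
#' @param baseline_hazard baseline event hazard per day (default
#'   `log(2)/861`, i.e. a median survival of 861 days at zero
#'   activation).
#' @param censor_rate target fraction of censored follow-up at baseline
#'   activation, in \[0, 1) (default 0.3).
#' @param n_drugs drugs in the ex vivo panel (default 122).
#' @param drug_resistance_coef AUC increase per unit activation
#'   (default 20).
#' @param seed integer seed; the same configuration always produces a
#'   bit-identical cohort.
#' @return validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(n_samples = 400, n_genes = 2000,
                             n_program_genes = 50,
                             mutant_prevalence = 0.09,
                             mutlike_fraction = 0.10,
                             effect_size_delta = 1.5,
                             baseline_log_mean_range = c(3, 9),
                             dispersion = 0.15,
                             hazard_coef_gamma = 1.5,
                             baseline_hazard = log(2) / 861,
                             censor_rate = 0.3,
                             n_drugs = 122,
                             drug_resistance_coef = 20,
                             seed = 1) {
    cfg <- list(n_samples = n_samples, n_genes = n_genes,
                n_program_genes = n_program_genes,
                mutant_prevalence = mutant_prevalence,
                mutlike_fraction = mutlike_fraction,
                effect_size_delta = effect_size_delta,
                baseline_log_mean_range = baseline_log_mean_range,
                dispersion = dispersion,
                hazard_coef_gamma = hazard_coef_gamma,
                baseline_hazard = baseline_hazard,
                censor_rate = censor_rate, n_drugs = n_drugs,
                drug_resistance_coef = drug_resistance_coef,
                seed = as.integer(seed))
    counts <- c("n_samples", "n_genes", "n_program_genes", "n_drugs")
    for (f in counts)
        if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 ||
            cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]]))
            stop("'", f, "' must be a non-negative integer")
    if (n_samples < 1) stop("'n_samples' must be positive")
    if (n_program_genes > n_genes)
        stop("'n_program_genes' must not exceed 'n_genes'")
    if (mutant_prevalence <= 0 || mutant_prevalence >= 1)
        stop("'mutant_prevalence' must lie in (0, 1)")
    if (mutlike_fraction < 0 || mutlike_fraction >= 1)
        stop("'mutlike_fraction' must lie in [0, 1)")
    if (censor_rate < 0 || censor_rate >= 1)
        stop("'censor_rate' must lie in [0, 1)")
    if (dispersion <= 0) stop("'dispersion' must be positive")
    if (baseline_hazard <= 0) stop("'baseline_hazard' must be positive")
    if (length(baseline_log_mean_range) != 2 ||
        diff(baseline_log_mean_range) < 0)
        stop("'baseline_log_mean_range' must be a non-decreasing interval")
    structure(cfg, class = "SimulationConfig")
}

#' Read a simulation configuration from JSON
#'
#' @param path JSON file whose fields match [simulationConfig()]
#'   arguments.
#' @return validated `SimulationConfig`.
#' @export
readSimulationConfig <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    do.call(simulationConfig, obj)
}

#' Generate a synthetic AML cohort with planted ground truth
#'
#' Simulates the statistical structure the subtype analysis assumes:
#' \itemize{
#' \item A per-sample \emph{activation} of a transcriptional program:
#'   exactly `round(mutant_prevalence * n_samples)` mutants with
#'   activation 1, a planted `mutlike_fraction` of wild-type samples also
#'   at activation 1 (the hidden mutant-like class), and Beta(1, 10)
#'   background activation for the remaining wild-type samples.
#' \item Negative-binomial counts whose log2 mean is a gene-specific
#'   baseline (uniform on `baseline_log_mean_range`) plus
#'   `effect_size_delta * activation` for program genes.
#' \item Exponential survival with hazard
#'   `baseline_hazard * exp(hazard_coef_gamma * activation)` and
#'   independent exponential censoring tuned so roughly `censor_rate` of
#'   baseline-activation follow-up is censored.
#' \item An ex vivo drug panel whose AUC increases (resistance) with
#'   activation, and blast percentage / WBC that decrease with it.
#' }
#'
#' @param config A `SimulationConfig` from [simulationConfig()].
#' @return list with components `cohort` ([AmlCohort-class] with `counts`
#'   assay and full clinical annotation), `drugs`
#'   ([DrugResponse-class], raw AUC), and `truth` (`data.frame`:
#'   `sample_id`, `activation`, `true_mutant`, `true_mutlike`,
#'   `program_gene` ids in `attr(truth, "program_genes")`).
#' @examples
#' cfg <- simulationConfig(n_samples = 60, n_genes = 100,
#'                         n_program_genes = 10, seed = 7)
#' sim <- generateCohort(cfg)
#' table(tp53Status(sim$cohort))
#' @export
generateCohort <- function(config) {
    if (!inherits(config, "SimulationConfig"))
        config <- do.call(simulationConfig, as.list(config))
    c2 <- config
    withSeed(seedStream(config$seed, "cohort-generator"), {
        n <- c2$n_samples
        sampleIds <- sprintf("S%04d", seq_len(n))
        geneIds <- sprintf("G%05d", seq_len(c2$n_genes))

        nMut <- round(c2$mutant_prevalence * n)
        mut <- logical(n)
        mut[sample.int(n, nMut)] <- TRUE
        nWt <- n - nMut
        nMutlike <- round(c2$mutlike_fraction * nWt)
        mutlike <- logical(n)
        mutlike[sample(which(!mut), nMutlike)] <- TRUE

        activation <- stats::rbeta(n, 1, 10)
        activation[mut | mutlike] <- 1

        # The program gene identities are a deterministic function of the
        # configuration (not the seed): independently seeded cohorts from
        # the same config share the planted program, the way two real
        # cohorts share a biological program.
        programGenes <- geneIds[round(seq(1, c2$n_genes,
                                          length.out = c2$n_program_genes))]
        baseline <- stats::runif(c2$n_genes,
                                 c2$baseline_log_mean_range[1],
                                 c2$baseline_log_mean_range[2])
        names(baseline) <- geneIds
        logMu <- matrix(baseline, nrow = c2$n_genes, ncol = n,
                        dimnames = list(geneIds, sampleIds))
        logMu[programGenes, ] <- logMu[programGenes, ] +
            rep(c2$effect_size_delta * activation,
                each = length(programGenes))
        mu <- 2^logMu
        counts <- matrix(
            stats::rnbinom(length(mu), mu = mu, size = 1 / c2$dispersion),
            nrow = c2$n_genes, dimnames = dimnames(mu))
        storage.mode(counts) <- "double"

        hazard <- c2$baseline_hazard * exp(c2$hazard_coef_gamma * activation)
        eventTime <- stats::rexp(n, rate = hazard)
        # Censoring hazard chosen so P(censor before event) at baseline
        # activation is approximately censor_rate.
        censHaz <- if (c2$censor_rate > 0)
            c2$baseline_hazard * c2$censor_rate / (1 - c2$censor_rate)
        else 0
        censTime <- if (censHaz > 0) stats::rexp(n, rate = censHaz)
                    else rep(Inf, n)
        osDays <- pmin(eventTime, censTime)
        osEvent <- as.integer(eventTime <= censTime)

        blast <- pmin(100, pmax(0, stats::rnorm(n, 70 - 20 * activation, 10)))
        wbc <- pmax(0.1, stats::rnorm(n, 50 - 25 * activation, 15))

        stage <- sample(c("diagnostic", "relapse", "residual"), n,
                        replace = TRUE, prob = c(0.65, 0.15, 0.20))
        pAdverse <- pmin(0.9, 0.25 + 0.5 * activation)
        eln <- vapply(pAdverse, function(p)
            sample(c("favorable", "intermediate", "adverse"), 1,
                   prob = c((1 - p) * 0.45, (1 - p) * 0.55, p)),
            character(1))
        allelic <- ifelse(mut,
                          sample(c("biallelic", "monoallelic"), n,
                                 replace = TRUE, prob = c(0.8, 0.2)),
                          "none")

        drugIds <- sprintf("drug%03d", seq_len(c2$n_drugs))
        drugBase <- stats::runif(c2$n_drugs, 80, 250)
        auc <- matrix(drugBase, nrow = c2$n_drugs, ncol = n,
                      dimnames = list(drugIds, sampleIds)) +
            rep(c2$drug_resistance_coef * activation,
                each = c2$n_drugs) +
            matrix(stats::rnorm(c2$n_drugs * n, 0, 10),
                   nrow = c2$n_drugs)

        ann <- data.frame(
            sample_id = sampleIds,
            tp53_status = ifelse(mut, "MUT", "WT"),
            disease_stage = stage,
            os_days = osDays, os_event = osEvent,
            blast_pct = blast, wbc = wbc,
            eln2022 = eln, allelic = allelic,
            stringsAsFactors = FALSE)
        truth <- data.frame(
            sample_id = sampleIds, activation = activation,
            true_mutant = mut, true_mutlike = mutlike,
            stringsAsFactors = FALSE)
        attr(truth, "program_genes") <- sort(programGenes)

        list(cohort = AmlCohort(counts, ann),
             drugs = DrugResponse(auc, stage = "raw_auc"),
             truth = truth)
    })
}

#' Write a generated cohort to disk as TSV files
#'
#' Emits `expression.tsv`, `annotation.tsv`, `drugs.tsv`, `truth.tsv` and
#' `program_genes.txt` into `dir`. The files round-trip losslessly through
#' [readExpression()] / [readAnnotation()] / [readDrugResponse()], and two
#' writes of the same cohort are byte-identical.
#'
#' @param sim list from [generateCohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
writeCohort <- function(sim, dir) {
    stopifnot(is.list(sim), is(sim$cohort, "AmlCohort"))
    if (ncol(sim$cohort) == 0)
        stop("cannot write an empty cohort")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(expression = file.path(dir, "expression.tsv"),
               annotation = file.path(dir, "annotation.tsv"),
               drugs = file.path(dir, "drugs.tsv"),
               truth = file.path(dir, "truth.tsv"),
               program_genes = file.path(dir, "program_genes.txt"))
    writeExpression(assay(sim$cohort, "counts"), paths[["expression"]])
    writeAnnotation(cohortAnnotation(sim$cohort), paths[["annotation"]])
    writeDrugResponse(sim$drugs, paths[["drugs"]])
    utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(attr(sim$truth, "program_genes"), paths[["program_genes"]])
    invisible(paths)
}

#' Read a cohort bundle written by [writeCohort()]
#'
#' @param dir directory containing the TSV files.
#' @return list with `cohort`, `drugs`, `truth` as in [generateCohort()].
#' @export
readCohort <- function(dir) {
    counts <- readExpression(file.path(dir, "expression.tsv"))
    ann <- readAnnotation(file.path(dir, "annotation.tsv"))
    drugs <- readDrugResponse(file.path(dir, "drugs.tsv"))
    truth <- utils::read.delim(file.path(dir, "truth.tsv"),
                               stringsAsFactors = FALSE)
    pg <- file.path(dir, "program_genes.txt")
    if (file.exists(pg))
        attr(truth, "program_genes") <- readLines(pg)
    list(cohort = AmlCohort(counts, ann), drugs = drugs, truth = truth)
}
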