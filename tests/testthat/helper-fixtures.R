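# Small in-code fixtures shared across tests.

# A tiny deterministic cohort: nGenes x nSamples Poisson-ish counts with a
# handful of mutants, suitable for interface-level tests.
tinyCohort <- function(nGenes = 20, nSamples = 12, nMut = 3, seed = 101) {
    withr::with_seed(seed, {
        counts <- matrix(rpois(nGenes * nSamples, 60),
                         nrow = nGenes,
                         dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                                         sprintf("s%02d", seq_len(nSamples))))
        ann <- data.frame(
            sample_id = colnames(counts),
            tp53_status = c(rep("MUT", nMut), rep("WT", nSamples - nMut)),
            os_days = rexp(nSamples, 1 / 500),
            os_event = rbinom(nSamples, 1, 0.7),
            stringsAsFactors = FALSE)
        AmlCohort(counts, ann)
    })
}

# Reference synthetic configuration at reduced size for fast tests that
# still need a recoverable planted signal.
smallConfig <- function(seed = 1, ...) {
    simulationConfig(n_samples = 200, n_genes = 400, n_program_genes = 30,
                     seed = seed, ...)
}

# The penalized logistic objective written out directly (independent of
# the package's penalizedLogisticObjective), for oracle comparisons.
directObjective <- function(beta0, beta, x, y, lambda, alpha) {
    eta <- beta0 + drop(crossprod(x, beta))
    mean(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta) +
        lambda * (alpha * sum(abs(beta)) +
                  (1 - alpha) / 2 * sum(beta^2))
}

# Jaccard index between two id sets.
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

mutlikeIds <- function(assignment) {
    g <- subtypeGroups(assignment)
    names(g)[g == "MUTLIKE"]
}
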