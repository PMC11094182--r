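#' Counts-per-million normalization
#'
#' `CPM(g, s) = counts(g, s) / libsize(s) * 1e6` where `libsize(s)` is the
#' column sum of raw counts.
#'
#' @param counts non-negative genes-by-samples count matrix.
#' @return CPM matrix of the same shape.
#' @export
cpmValues <- function(counts) {
    stopifnot(is.matrix(counts))
    lib <- colSums(counts)
    if (any(lib <= 0))
        stop("zero library size for sample(s): ",
             paste(colnames(counts)[lib <= 0], collapse = ", "))
    sweep(counts, 2, lib, "/") * 1e6
}

#' Per-gene z-scoring across samples
#'
#' Centers and scales each gene across samples using the sample standard
#' deviation (n - 1 denominator). Genes with zero variance get z = 0 for
#' every sample.
#'
#' @param x numeric genes-by-samples matrix.
#' @return z-scored matrix of the same shape.
#' @export
zscoreGenes <- function(x) {
    stopifnot(is.matrix(x))
    mu <- rowMeans(x)
    centered <- x - mu
    sdv <- sqrt(rowSums(centered^2) / (ncol(x) - 1))
    sdv[sdv == 0] <- Inf       # constant gene -> z identically 0
    centered / sdv
}

#' Normalize raw counts to the log2-CPM z-score representation
#'
#' The chain used throughout the package: counts are library-size
#' normalized to CPM, transformed as `log2(CPM + 1)`, then each gene is
#' z-scored across samples ([zscoreGenes()]). All model fitting and
#' scoring operates on the `zscore` stage; gene ranking for enrichment
#' operates on the `log2cpm` stage.
#'
#' For an [AmlCohort-class], the `cpm`, `log2cpm` and `zscore` assays are
#' added and the cohort returned; for a plain matrix of counts the z-score
#' matrix is returned.
#'
#' @param x count matrix or `AmlCohort` with a `counts` assay.
#' @return see Details.
#' @examples
#' m <- matrix(c(1, 9, 5, 5), 2, dimnames = list(c("g1","g2"), c("a","b")))
#' cpmValues(m)[, "a"]   # 1e5, 9e5
#' @export
setGeneric("normalizeExpression", function(x) {
    standardGeneric("normalizeExpression")
})

#' @rdname normalizeExpression
#' @export
setMethod("normalizeExpression", "matrix", function(x) {
    zscoreGenes(log2(cpmValues(x) + 1))
})

#' @rdname normalizeExpression
#' @export
setMethod("normalizeExpression", "AmlCohort", function(x) {
    cpm <- cpmValues(assay(x, "counts"))
    l2 <- log2(cpm + 1)
    assay(x, "cpm") <- cpm
    assay(x, "log2cpm") <- l2
    assay(x, "zscore") <- zscoreGenes(l2)
    x
})

#' Restrict two expression matrices to their shared gene space
#'
#' Cross-cohort model transfer requires both cohorts to carry the same
#' genes in the same order. Both matrices are restricted to the
#' intersection of their gene identifiers, sorted lexicographically.
#'
#' @param a,b genes-by-samples matrices at the same stage.
#' @return list with elements `a` and `b`, both restricted and reordered.
#' @export
harmonizeGenes <- function(a, b) {
    stopifnot(is.matrix(a), is.matrix(b))
    shared <- sort(intersect(rownames(a), rownames(b)))
    if (length(shared) == 0)
        stop("no shared gene identifiers between the two matrices")
    list(a = a[shared, , drop = FALSE], b = b[shared, , drop = FALSE])
}

#' Stratified train/test split of cohort samples
#'
#' Partitions samples into a training and a test set. By default the split
#' is stratified by TP53 status so that mutant prevalence in each side
#' matches the cohort within rounding — with a rare mutant class an
#' unstratified split can starve either side of mutants.
#'
#' @param ann annotation `data.frame` with `sample_id` and `tp53_status`
#'   columns, or an [AmlCohort-class].
#' @param trainFraction fraction of samples assigned to training,
#'   in (0, 1). Default 0.6.
#' @param seed integer seed; the same seed always yields the same split.
#' @param stratify stratify by `tp53_status` (default `TRUE`).
#' @return list with character vectors `train` and `test` of sample ids.
#' @export
splitTrainTest <- function(ann, trainFraction = 0.6, seed = 1,
                           stratify = TRUE) {
    if (is(ann, "AmlCohort")) ann <- cohortAnnotation(ann)
    if (!is.numeric(trainFraction) || trainFraction <= 0 ||
        trainFraction >= 1)
        stop("trainFraction must lie strictly between 0 and 1")
    ids <- ann$sample_id
    strata <- if (stratify) as.character(ann$tp53_status)
              else rep("all", length(ids))
    train <- character(0)
    withSeed(seedStream(seed, "train-test-split"), {
        for (s in unique(strata)) {
            sids <- ids[strata == s]
            nTrain <- round(trainFraction * length(sids))
            if (nTrain == 0 || nTrain == length(sids))
                warning("stratum '", s, "' has an empty train or test side")
            train <- c(train, sample(sids, nTrain))
        }
    })
    list(train = sort(train), test = sort(setdiff(ids, train)))
}
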