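#' Derive mutant-like labels from the top decile of wild-type ridge scores
#'
#' Wild-type samples whose ridge score lies strictly above the
#' nearest-rank `(1 - decile)` quantile of all wild-type scores are
#' labelled `MUTLIKE`; mutants always stay `MUT` regardless of score; the
#' remaining wild-type samples are `WT`. With the default `decile = 0.10`
#' this is the "top 10% of wild-type ridge scores" rule. The strict
#' inequality makes the rule tie-safe: if every wild-type score is equal,
#' no sample is mutant-like.
#'
#' @param scores `data.frame` from [scoreSamples()] covering (at least)
#'   all wild-type samples.
#' @param ann annotation `data.frame` with `sample_id` and `tp53_status`,
#'   or an [AmlCohort-class].
#' @param decile fraction of wild-type samples to call mutant-like
#'   (default 0.10).
#' @return A [SubtypeAssignment-class].
#' @export
deriveMutlikeLabels <- function(scores, ann, decile = 0.10) {
    if (is(ann, "AmlCohort")) ann <- cohortAnnotation(ann)
    stopifnot(is.data.frame(scores),
              all(c("sample_id", "ridge_score") %in% colnames(scores)))
    if (decile <= 0 || decile >= 1)
        stop("decile must lie strictly between 0 and 1")
    wtIds <- ann$sample_id[ann$tp53_status == "WT"]
    if (length(wtIds) < 10)
        stop("fewer than 10 wild-type samples; cannot take a top decile")
    s <- scores$ridge_score[match(wtIds, scores$sample_id)]
    if (anyNA(s))
        stop("scores missing for wild-type sample(s): ",
             paste(utils::head(wtIds[is.na(s)], 5), collapse = ", "))
    q <- sort(s)[ceiling((1 - decile) * length(s))]  # nearest-rank quantile
    grp <- ifelse(ann$tp53_status == "MUT", "MUT", "WT")
    grp[ann$sample_id %in% wtIds[s > q]] <- "MUTLIKE"
    rs <- scores$ridge_score[match(ann$sample_id, scores$sample_id)]
    new("SubtypeAssignment", sampleIds = ann$sample_id,
        group = factor(grp, levels = c("MUT", "MUTLIKE", "WT")),
        ridgeScore = rs, threshold = q)
}

#' Train the complementary wild-type-only (mutant-like) model
#'
#' Fits a ridge logistic model of `MUTLIKE` vs `WT` using wild-type
#' samples only, so the resulting model can detect mutant-like cases in
#' cohorts without relying on mutant profiles. The function refuses to run
#' if the supplied matrix contains any mutant sample. Samples are split
#' into train/test (stratified by label), the penalty is selected by
#' cross-validation on the training side, and held-out performance is
#' reported.
#'
#' @param x genes-by-samples `zscore` matrix containing wild-type samples
#'   only.
#' @param assignment A [SubtypeAssignment-class] covering the samples of
#'   `x`.
#' @param lambdaGrid candidate penalties for [selectLambdaCV()]; default
#'   a 20-point log grid over \[1e-3, 100\].
#' @param nFolds CV folds (default 5).
#' @param trainFraction train share of the internal split (default 0.6).
#' @param seed integer seed for split and folds.
#' @return list with `model` ([PenalizedModel-class]), `evaluation`
#'   (held-out metrics from [evaluateClassifier()]), `lambda`, `trainIds`,
#'   `testIds`.
#' @export
trainComplementaryModel <- function(x, assignment,
                                    lambdaGrid = defaultLambdaGrid(),
                                    nFolds = 5, trainFraction = 0.6,
                                    seed = 1) {
    stopifnot(is.matrix(x), is(assignment, "SubtypeAssignment"))
    grp <- subtypeGroups(assignment)
    if (!all(colnames(x) %in% names(grp)))
        stop("assignment does not cover all samples of 'x'")
    grp <- grp[colnames(x)]
    if (any(grp == "MUT"))
        stop("mutant samples present in the training matrix: ",
             paste(utils::head(colnames(x)[grp == "MUT"], 5),
                   collapse = ", "))
    y <- as.integer(grp == "MUTLIKE")
    if (sum(y) == 0)
        stop("no MUTLIKE samples among the wild-type training data")
    split <- splitTrainTest(
        data.frame(sample_id = colnames(x),
                   tp53_status = ifelse(y == 1, "MUT", "WT")),
        trainFraction = trainFraction, seed = seed)
    tr <- colnames(x) %in% split$train
    sel <- selectLambdaCV(x[, tr, drop = FALSE], y[tr], lambdaGrid,
                          alpha = 0, nFolds = nFolds, seed = seed)
    model <- fitPenalizedLogistic(x[, tr, drop = FALSE], y[tr],
                                  lambda = sel$lambda, alpha = 0)
    sc <- scoreSamples(model, x[, !tr, drop = FALSE])
    list(model = model,
         evaluation = evaluateClassifier(sc, y[!tr]),
         lambda = sel$lambda,
         trainIds = split$train, testIds = split$test)
}

# 20-point log-spaced ridge/elastic-net penalty grid. The floor of 1e-2
# keeps cross-validation away from the near-unregularized regime, where
# separable expression cohorts make the fits ill-conditioned.
defaultLambdaGrid <- function(from = 1e-2, to = 100, length.out = 20) {
    exp(seq(log(to), log(from), length.out = length.out))
}

#' Transfer a frozen mutant-like model to a second cohort
#'
#' Scores every sample of the target cohort with the model fitted on the
#' source cohort (gene spaces must already be harmonized, see
#' [harmonizeGenes()]), then applies the top-decile rule within the target
#' cohort's wild-type samples. Alternatively, `mode = "absolute"` reuses a
#' fixed score cutoff instead of recomputing the quantile.
#'
#' @param model frozen [PenalizedModel-class] from the source cohort.
#' @param x2 genes-by-samples `zscore` matrix of the target cohort; must
#'   contain every model gene.
#' @param ann2 target-cohort annotation (`sample_id`, `tp53_status`) or
#'   [AmlCohort-class].
#' @param decile top fraction rule for `mode = "quantile"` (default 0.10).
#' @param mode `"quantile"` (recompute the cutoff within the target
#'   cohort, the default) or `"absolute"` (use `threshold`).
#' @param threshold score cutoff for `mode = "absolute"`.
#' @return A [SubtypeAssignment-class] for the target cohort.
#' @export
transferModel <- function(model, x2, ann2, decile = 0.10,
                          mode = c("quantile", "absolute"),
                          threshold = NULL) {
    mode <- match.arg(mode)
    if (is(ann2, "AmlCohort")) ann2 <- cohortAnnotation(ann2)
    if (!any(ann2$tp53_status == "WT"))
        stop("target cohort contains no wild-type samples")
    scores <- scoreSamples(model, x2)
    if (mode == "quantile")
        return(deriveMutlikeLabels(scores, ann2, decile = decile))
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    s <- scores$ridge_score[match(ann2$sample_id, scores$sample_id)]
    grp <- ifelse(ann2$tp53_status == "MUT", "MUT",
                  ifelse(s > threshold, "MUTLIKE", "WT"))
    new("SubtypeAssignment", sampleIds = ann2$sample_id,
        group = factor(grp, levels = c("MUT", "MUTLIKE", "WT")),
        ridgeScore = s, threshold = threshold)
}

#' Derive a compact core gene signature by repeated elastic-net selection
#'
#' Runs `nIter` elastic-net fits of the binary target (mutant-like vs
#' wild-type) on stratified resamples of the samples, selecting the
#' penalty by cross-validation within each resample, and counts how often
#' each gene receives a nonzero coefficient. The core signature is the `k`
#' most frequently selected genes (ties broken lexicographically by gene
#' id). If fewer than `k` genes are ever selected, all ever-selected genes
#' are returned with a warning.
#'
#' @param x genes-by-samples `zscore` matrix (wild-type samples only).
#' @param y binary target (1 = mutant-like), aligned with columns of `x`.
#' @param nIter number of resampled fits (default 100).
#' @param k signature size (default 25).
#' @param alpha elastic-net mixing (default 0.5).
#' @param lambdaGrid candidate penalties (default [defaultLambdaGrid()]
#'   over \[0.05, 10\]; the higher floor keeps resampled fits of
#'   well-separated classes away from the separable regime).
#' @param nFolds CV folds within each iteration (default 5).
#' @param seed integer seed; iteration `i` uses stream `seed + i`.
#' @param scheme resampling scheme: `"bootstrap"` (stratified bootstrap,
#'   default) or `"subsample"` (random fraction without replacement).
#' @param subsampleFraction fraction for `scheme = "subsample"`
#'   (default 0.6).
#' @return A [SignatureReport-class].
#' @export
deriveCoreSignature <- function(x, y, nIter = 100, k = 25, alpha = 0.5,
                                lambdaGrid = defaultLambdaGrid(from = 0.05,
                                                               to = 10),
                                nFolds = 5, seed = 1,
                                scheme = c("bootstrap", "subsample"),
                                subsampleFraction = 0.6) {
    scheme <- match.arg(scheme)
    y <- coerceBinary(y)
    stopifnot(is.matrix(x), length(y) == ncol(x), nIter >= 1, k >= 1)
    count <- stats::setNames(integer(nrow(x)), rownames(x))
    for (i in seq_len(nIter)) {
        idx <- withSeed(seedStream(seed + i, "signature-resample"), {
            unlist(lapply(c(0L, 1L), function(cls) {
                pool <- which(y == cls)
                if (scheme == "bootstrap")
                    sample(pool, length(pool), replace = TRUE)
                else
                    sample(pool, max(2, round(subsampleFraction *
                                              length(pool))))
            }), use.names = FALSE)
        })
        sel <- selectLambdaCV(x[, idx, drop = FALSE], y[idx], lambdaGrid,
                              alpha = alpha, nFolds = nFolds,
                              seed = seed + i)
        fit <- fitPenalizedLogistic(x[, idx, drop = FALSE], y[idx],
                                    lambda = sel$lambda, alpha = alpha,
                                    thresh = 1e-8)
        nz <- fit@geneIds[fit@beta != 0]
        count[nz] <- count[nz] + 1L
    }
    ever <- names(count)[count > 0]
    if (length(ever) < k) {
        warning("only ", length(ever), " genes ever selected; ",
                "returning all of them")
        core <- ever[order(-count[ever], ever)]
    } else {
        ord <- order(-count, names(count))
        core <- names(count)[ord][seq_len(k)]
    }
    new("SignatureReport", selectionCount = count, coreGenes = core,
        nIter = as.integer(nIter), k = as.integer(k))
}

#' Refit a ridge model restricted to the core signature genes
#'
#' Fits a ridge logistic model of the binary target using only the core
#' signature genes and reports held-out performance — the check that a
#' compact signature suffices to classify the derived subtype.
#'
#' @param x genes-by-samples `zscore` matrix containing the signature
#'   genes.
#' @param y binary target aligned with columns of `x`.
#' @param genes character vector of signature gene ids (or a
#'   [SignatureReport-class]).
#' @param lambdaGrid,nFolds,trainFraction,seed as in
#'   [trainComplementaryModel()].
#' @return list with `model`, `evaluation`, `lambda`, `trainIds`,
#'   `testIds`.
#' @export
refitSignatureModel <- function(x, y, genes,
                                lambdaGrid = defaultLambdaGrid(),
                                nFolds = 5, trainFraction = 0.6,
                                seed = 1) {
    if (is(genes, "SignatureReport")) genes <- coreGenes(genes)
    if (length(genes) == 0)
        stop("empty signature gene list")
    missing <- setdiff(genes, rownames(x))
    if (length(missing))
        stop("signature gene(s) absent from the matrix: ",
             paste(utils::head(missing, 5), collapse = ", "))
    y <- coerceBinary(y)
    xs <- x[genes, , drop = FALSE]
    split <- splitTrainTest(
        data.frame(sample_id = colnames(xs),
                   tp53_status = ifelse(y == 1, "MUT", "WT")),
        trainFraction = trainFraction, seed = seed)
    tr <- colnames(xs) %in% split$train
    sel <- selectLambdaCV(xs[, tr, drop = FALSE], y[tr], lambdaGrid,
                          alpha = 0, nFolds = nFolds, seed = seed)
    model <- fitPenalizedLogistic(xs[, tr, drop = FALSE], y[tr],
                                  lambda = sel$lambda, alpha = 0)
    sc <- scoreSamples(model, xs[, !tr, drop = FALSE])
    list(model = model, evaluation = evaluateClassifier(sc, y[!tr]),
         lambda = sel$lambda, trainIds = split$train,
         testIds = split$test)
}
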