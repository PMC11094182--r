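#' Run the full mutant-like subtype discovery pipeline
#'
#' Executes the complete derivation on one cohort, with optional transfer
#' to a second cohort:
#' \enumerate{
#' \item normalize counts to the log2-CPM z-score stage;
#' \item stratified train/test split (default 60/40);
#' \item cross-validated ridge logistic fit of mutant vs rest on the
#'   training split, held-out evaluation on the test split;
#' \item ridge scores for all samples, mutant-like labels from the top
#'   decile of wild-type scores;
#' \item complementary wild-type-only model of mutant-like vs wild-type;
#' \item optional transfer of the complementary model to cohort B
#'   (shared gene space, per-cohort normalization and decile);
#' \item elastic-net core signature across resampled fits and a ridge
#'   refit restricted to the signature genes;
#' \item pairwise Kaplan-Meier / log-rank survival comparison of the
#'   three groups;
#' \item clinical comparisons (blast percentage, WBC) and, when a drug
#'   panel is supplied, AUC z-scoring with per-contrast t-tests and BH
#'   correction across drugs;
#' \item when gene sets are supplied, preranked enrichment for
#'   mutant-vs-wild-type and mutant-like-vs-wild-type (plus the
#'   cross-cohort concordance filter when cohort B is present).
#' }
#'
#' @param cohortA [AmlCohort-class] (counts stage).
#' @param cohortB optional second [AmlCohort-class] for transfer; when
#'   `NULL` the transfer stage is skipped with a notice.
#' @param drugsA optional [DrugResponse-class] for cohort A.
#' @param geneSets optional named list of gene sets for enrichment.
#' @param markers optional surface-marker gene ids; requires `cohortB`
#'   (the marker analysis is defined by cross-cohort concordance).
#' @param decile top wild-type score fraction labelled mutant-like
#'   (default 0.10).
#' @param trainFraction training share of the split (default 0.6).
#' @param lambdaGrid penalty grid for all cross-validated fits.
#' @param nFolds CV folds (default 5).
#' @param signatureIter elastic-net iterations (default 100).
#' @param signatureK core signature size (default 25).
#' @param signatureAlpha elastic-net mixing (default 0.5).
#' @param nPerm GSEA permutations (default 1000).
#' @param seed master seed; every stage derives its randomness from it.
#' @param outputDir optional directory; when given, assignment, scores,
#'   signature, survival and comparison tables plus a JSON run manifest
#'   are written there.
#' @return a named list with the per-stage results: `split`, `mutModel`,
#'   `mutEvaluation`, `scoresA`, `assignmentA`, `complementary`,
#'   `signature`, `signatureRefit`, `survivalA`, `clinicalA`, `drugZ`,
#'   `drugComparisons`, `transfer`, `survivalB`, `enrichmentA`,
#'   `enrichmentB`, `concordantSets`, `markerOverlap`, `manifest`.
#' @export
runFullPipeline <- function(cohortA, cohortB = NULL, drugsA = NULL,
                            geneSets = NULL, markers = NULL,
                            decile = 0.10, trainFraction = 0.6,
                            lambdaGrid = defaultLambdaGrid(),
                            nFolds = 5, signatureIter = 100,
                            signatureK = 25, signatureAlpha = 0.5,
                            nPerm = 1000, seed = 1, outputDir = NULL) {
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    res <- list()

    cohortA <- stage("normalize", normalizeExpression(cohortA))
    zA <- assay(cohortA, "zscore")
    annA <- cohortAnnotation(cohortA)
    yMut <- as.integer(annA$tp53_status == "MUT")

    split <- stage("split",
                   splitTrainTest(annA, trainFraction = trainFraction,
                                  seed = seed))
    res$split <- split
    tr <- annA$sample_id %in% split$train

    res$mutModel <- stage("fit", {
        sel <- selectLambdaCV(zA[, tr], yMut[tr], lambdaGrid, alpha = 0,
                              nFolds = nFolds, seed = seed)
        fitPenalizedLogistic(zA[, tr], yMut[tr], lambda = sel$lambda,
                             alpha = 0)
    })
    res$scoresA <- stage("score", scoreSamples(res$mutModel, zA))
    res$mutEvaluation <- stage("evaluate", {
        sc <- res$scoresA[match(split$test, res$scoresA$sample_id), ]
        evaluateClassifier(sc, yMut[match(split$test, annA$sample_id)])
    })
    res$assignmentA <- stage("derive",
        deriveMutlikeLabels(res$scoresA, annA, decile = decile))

    grpA <- subtypeGroups(res$assignmentA)
    wtIds <- annA$sample_id[annA$tp53_status == "WT"]
    res$complementary <- stage("complementary",
        trainComplementaryModel(zA[, wtIds], res$assignmentA,
                                lambdaGrid = lambdaGrid, nFolds = nFolds,
                                trainFraction = trainFraction,
                                seed = seed + 1L))

    yMutlike <- as.integer(grpA[wtIds] == "MUTLIKE")
    res$signature <- stage("signature",
        deriveCoreSignature(zA[, wtIds], yMutlike, nIter = signatureIter,
                            k = signatureK, alpha = signatureAlpha,
                            nFolds = nFolds, seed = seed + 2L))
    res$signatureRefit <- stage("signature_refit",
        refitSignatureModel(zA[, wtIds], yMutlike,
                            coreGenes(res$signature),
                            lambdaGrid = lambdaGrid, nFolds = nFolds,
                            trainFraction = trainFraction,
                            seed = seed + 3L))

    if (all(c("os_days", "os_event") %in% colnames(annA)))
        res$survivalA <- stage("survival", pairwiseSurvival(
            data.frame(os_days = annA$os_days, os_event = annA$os_event,
                       group = as.character(grpA[annA$sample_id]))))

    clinVars <- intersect(c("blast_pct", "wbc"), colnames(annA))
    if (length(clinVars)) {
        vals <- lapply(clinVars, function(v) annA[[v]])
        names(vals) <- clinVars
        g <- as.character(grpA[annA$sample_id])
        res$clinicalA <- stage("clinical", list(
            mut_vs_wt = groupComparisonTable(vals, g, c("MUT", "WT")),
            mutlike_vs_wt = groupComparisonTable(vals, g,
                                                 c("MUTLIKE", "WT"))))
    }

    if (!is.null(drugsA)) {
        res$drugZ <- stage("drug_z", drugAucZscores(drugsA))
        zmat <- aucValues(res$drugZ)
        g <- as.character(grpA[colnames(zmat)])
        vals <- lapply(rownames(zmat), function(d) zmat[d, ])
        names(vals) <- rownames(zmat)
        res$drugComparisons <- stage("drug_compare", list(
            mut_vs_wt = groupComparisonTable(vals, g, c("MUT", "WT")),
            mutlike_vs_wt = groupComparisonTable(vals, g,
                                                 c("MUTLIKE", "WT"))))
    }

    if (!is.null(geneSets)) {
        l2A <- assay(cohortA, "log2cpm")
        ids <- function(lv) names(grpA)[grpA == lv]
        res$enrichmentA <- stage("enrichment", list(
            mut_vs_wt = gseaPreranked(
                rankGenes(l2A, ids("MUT"), ids("WT")), geneSets,
                nPerm = nPerm, seed = seed + 4L),
            mutlike_vs_wt = gseaPreranked(
                rankGenes(l2A, ids("MUTLIKE"), ids("WT")), geneSets,
                nPerm = nPerm, seed = seed + 5L)))
    }

    if (is.null(cohortB)) {
        message("cohort B not supplied; transfer stage skipped")
    } else {
        res$transfer <- stage("transfer", {
            cohortB <- normalizeExpression(cohortB)
            annB <- cohortAnnotation(cohortB)
            h <- harmonizeGenes(assay(cohortA, "counts"),
                                assay(cohortB, "counts"))
            zB <- normalizeExpression(h$b)
            model <- res$complementary$model
            if (!all(model@geneIds %in% rownames(zB)))
                stop("cohort B lacks genes used by the transferred model")
            list(assignment = transferModel(model, zB, annB,
                                            decile = decile),
                 annB = annB, zB = zB,
                 log2cpmB = log2(cpmValues(h$b) + 1))
        })
        grpB <- subtypeGroups(res$transfer$assignment)
        annB <- res$transfer$annB
        if (all(c("os_days", "os_event") %in% colnames(annB)))
            res$survivalB <- stage("survival_b", pairwiseSurvival(
                data.frame(os_days = annB$os_days,
                           os_event = annB$os_event,
                           group = as.character(grpB[annB$sample_id]))))
        if (!is.null(geneSets)) {
            idsB <- function(lv) names(grpB)[grpB == lv]
            res$enrichmentB <- stage("enrichment_b", list(
                mut_vs_wt = gseaPreranked(
                    rankGenes(res$transfer$log2cpmB, idsB("MUT"),
                              idsB("WT")),
                    geneSets, nPerm = nPerm, seed = seed + 6L),
                mutlike_vs_wt = gseaPreranked(
                    rankGenes(res$transfer$log2cpmB, idsB("MUTLIKE"),
                              idsB("WT")),
                    geneSets, nPerm = nPerm, seed = seed + 7L)))
            res$concordantSets <- stage("concordance", list(
                mut_vs_wt = concordanceFilter(
                    res$enrichmentA$mut_vs_wt,
                    res$enrichmentB$mut_vs_wt),
                mutlike_vs_wt = concordanceFilter(
                    res$enrichmentA$mutlike_vs_wt,
                    res$enrichmentB$mutlike_vs_wt)))
        }
        if (!is.null(markers)) {
            l2A <- assay(cohortA, "log2cpm")
            l2B <- res$transfer$log2cpmB
            idsA <- function(lv) names(grpA)[grpA == lv]
            idsB <- function(lv) names(grpB)[grpB == lv]
            res$markerOverlap <- stage("markers", {
                mkMut <- concordantMarkers(
                    differentialTable(l2A, idsA("MUT"), idsA("WT"),
                                      genes = markers),
                    differentialTable(l2B, idsB("MUT"), idsB("WT"),
                                      genes = markers),
                    markers)
                mkLike <- concordantMarkers(
                    differentialTable(l2A, idsA("MUTLIKE"), idsA("WT"),
                                      genes = markers),
                    differentialTable(l2B, idsB("MUTLIKE"), idsB("WT"),
                                      genes = markers),
                    markers)
                surfaceMarkerOverlap(mkMut, mkLike)
            })
        }
    }

    res$manifest <- list(
        package_version = as.character(utils::packageVersion("mutlikeAML")),
        seed = seed, decile = decile, trainFraction = trainFraction,
        nFolds = nFolds, signatureIter = signatureIter,
        signatureK = signatureK, signatureAlpha = signatureAlpha,
        nPerm = nPerm, lambda_mut = res$mutModel@lambda,
        lambda_complementary = res$complementary$lambda,
        n_samples = ncol(cohortA), n_genes = nrow(cohortA),
        timestamp = format(Sys.time(), tz = "UTC"))

    if (!is.null(outputDir)) writePipelineOutputs(res, outputDir)
    res
}

# Write the pipeline's tabular artifacts and a JSON run manifest.
writePipelineOutputs <- function(res, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
        x, file.path(dir, f), sep = "\t", quote = FALSE,
        row.names = FALSE)
    wt(assignmentTable(res$assignmentA), "assignment_a.tsv")
    wt(res$scoresA, "scores_a.tsv")
    wt(selectionCounts(res$signature), "signature_counts.tsv")
    writeLines(coreGenes(res$signature),
               file.path(dir, "core_genes.txt"))
    writePenalizedModel(res$mutModel, file.path(dir, "mut_model.json"))
    writePenalizedModel(res$complementary$model,
                        file.path(dir, "mutlike_model.json"))
    if (!is.null(res$survivalA)) {
        wt(res$survivalA$medians, "survival_medians_a.tsv")
        wt(res$survivalA$tests, "survival_tests_a.tsv")
    }
    if (!is.null(res$transfer))
        wt(assignmentTable(res$transfer$assignment), "assignment_b.tsv")
    jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}
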