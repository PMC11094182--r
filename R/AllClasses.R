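#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assay<- assayNames colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' AmlCohort: an expression cohort with clinical annotation
#'
#' `AmlCohort` extends [SummarizedExperiment::SummarizedExperiment] and holds
#' a genes-by-samples expression matrix (assay `"counts"`, with `"cpm"`,
#' `"log2cpm"` and `"zscore"` assays added by [normalizeExpression()])
#' together with per-sample clinical annotation in `colData`: TP53 mutation
#' status, disease stage, overall-survival time and event flag, bone-marrow
#' blast percentage, white-blood-cell count, ELN 2022 risk category and
#' TP53 allelic status. Simulated cohorts additionally carry the planted
#' ground truth (`activation`, `true_mutant`, `true_mutlike`).
#'
#' @section Validity:
#' Gene and sample identifiers must be unique; the `counts` assay, when
#' present, must be non-negative and finite; `tp53_status` must be one of
#' `"MUT"`, `"WT"`; `os_days`, when present, must be non-negative.
#'
#' @seealso [AmlCohort()] the constructor, [normalizeExpression()],
#'   [generateCohort()]
#' @export
setClass("AmlCohort", contains = "SummarizedExperiment")

setValidity("AmlCohort", function(object) {
    msg <- character()
    gid <- rownames(object)
    sid <- colnames(object)
    if (is.null(gid) || is.null(sid))
        msg <- c(msg, "gene and sample identifiers must be set")
    if (!is.null(gid) && anyDuplicated(gid))
        msg <- c(msg, "duplicated gene identifiers")
    if (!is.null(sid) && anyDuplicated(sid))
        msg <- c(msg, "duplicated sample identifiers")
    if ("counts" %in% assayNames(object)) {
        cts <- assay(object, "counts")
        if (any(!is.finite(cts)))
            msg <- c(msg, "counts contain non-finite values")
        else if (any(cts < 0))
            msg <- c(msg, "counts must be non-negative")
    }
    cd <- colData(object)
    if (!"tp53_status" %in% colnames(cd))
        msg <- c(msg, "colData must contain 'tp53_status'")
    else if (!all(cd$tp53_status %in% c("MUT", "WT")))
        msg <- c(msg, "tp53_status must be 'MUT' or 'WT'")
    if ("os_days" %in% colnames(cd) &&
        any(stats::na.omit(cd$os_days) < 0))
        msg <- c(msg, "os_days must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Construct an AmlCohort
#'
#' @param counts Numeric genes-by-samples matrix of non-negative read
#'   counts with gene identifiers as rownames and sample identifiers as
#'   colnames.
#' @param annotation `data.frame` of per-sample annotation with a
#'   `sample_id` column matching `colnames(counts)` (any order) and at
#'   least a `tp53_status` column (`"MUT"`/`"WT"`).
#'
#' @return An [AmlCohort-class] object.
#' @examples
#' cts <- matrix(rpois(12, 50), nrow = 3,
#'               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ann <- data.frame(sample_id = paste0("s", 1:4),
#'                   tp53_status = c("MUT", "WT", "WT", "WT"))
#' AmlCohort(cts, ann)
#' @export
AmlCohort <- function(counts, annotation) {
    if (!is.matrix(counts) || !is.numeric(counts))
        stop("'counts' must be a numeric matrix")
    if (!is.data.frame(annotation) || !"sample_id" %in% colnames(annotation))
        stop("'annotation' must be a data.frame with a 'sample_id' column")
    if (anyDuplicated(annotation$sample_id))
        stop("duplicated sample_id in annotation")
    if (!setequal(annotation$sample_id, colnames(counts)))
        stop("annotation sample_id set does not match count matrix columns")
    ann <- annotation[match(colnames(counts), annotation$sample_id), ,
                      drop = FALSE]
    cd <- DataFrame(ann[setdiff(colnames(ann), "sample_id")],
                    row.names = ann$sample_id)
    se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
    new("AmlCohort", se)
}

#' @describeIn AmlCohort-class TP53 mutation status per sample
#'   (`"MUT"`/`"WT"`, named character vector).
#' @param x An `AmlCohort`.
#' @export
tp53Status <- function(x) {
    stopifnot(is(x, "AmlCohort"))
    stats::setNames(as.character(colData(x)$tp53_status), colnames(x))
}

#' @describeIn AmlCohort-class Per-sample annotation as a base
#'   `data.frame` with a leading `sample_id` column.
#' @export
cohortAnnotation <- function(x) {
    stopifnot(is(x, "AmlCohort"))
    cd <- as.data.frame(colData(x))
    data.frame(sample_id = colnames(x), cd, row.names = NULL,
               stringsAsFactors = FALSE)
}

setMethod("show", "AmlCohort", function(object) {
    callNextMethod()
    st <- colData(object)$tp53_status
    cat(sprintf("tp53_status: %d MUT, %d WT\n",
                sum(st == "MUT"), sum(st == "WT")))
})

#' DrugResponse: ex vivo drug sensitivity matrix
#'
#' Drugs-by-samples matrix of dose-response AUC values. `stage` is either
#' `"raw_auc"` (higher AUC = more resistant) or `"auc_z"` (per-drug
#' z-scores multiplied by -1, so higher = more sensitive; see
#' [drugAucZscores()]).
#'
#' @slot auc numeric drugs-by-samples matrix (missing values allowed).
#' @slot stage `"raw_auc"` or `"auc_z"`.
#' @export
setClass("DrugResponse",
         representation(auc = "matrix", stage = "character"))

setValidity("DrugResponse", function(object) {
    msg <- character()
    if (!is.numeric(object@auc))
        msg <- c(msg, "auc must be numeric")
    if (is.null(rownames(object@auc)) || is.null(colnames(object@auc)))
        msg <- c(msg, "auc must have drug rownames and sample colnames")
    else {
        if (anyDuplicated(rownames(object@auc)))
            msg <- c(msg, "duplicated drug identifiers")
        if (anyDuplicated(colnames(object@auc)))
            msg <- c(msg, "duplicated sample identifiers")
    }
    if (!object@stage %in% c("raw_auc", "auc_z"))
        msg <- c(msg, "stage must be 'raw_auc' or 'auc_z'")
    if (length(msg)) msg else TRUE
})

#' Construct a DrugResponse object
#'
#' @param auc drugs-by-samples numeric matrix of AUC values.
#' @param stage `"raw_auc"` (default) or `"auc_z"`.
#' @return A [DrugResponse-class] object.
#' @export
DrugResponse <- function(auc, stage = "raw_auc") {
    new("DrugResponse", auc = auc, stage = stage)
}

#' @describeIn DrugResponse-class the AUC matrix.
#' @param x A `DrugResponse`.
#' @export
aucValues <- function(x) {
    stopifnot(is(x, "DrugResponse"))
    x@auc
}

#' @describeIn DrugResponse-class the stage tag.
#' @export
drugStage <- function(x) {
    stopifnot(is(x, "DrugResponse"))
    x@stage
}

setMethod("show", "DrugResponse", function(object) {
    cat(sprintf("DrugResponse: %d drugs x %d samples [%s]\n",
                nrow(object@auc), ncol(object@auc), object@stage))
})

#' PenalizedModel: a fitted penalized logistic regression model
#'
#' Stores the intercept, per-gene coefficients and penalty settings of an
#' L1/L2-penalized logistic model fitted on z-scored expression. The ridge
#' score of a sample is the linear predictor
#' `beta0 + sum_j beta_j * x_j`; see [scoreSamples()].
#'
#' @slot geneIds ordered gene identifiers matching `beta`.
#' @slot beta per-gene coefficients.
#' @slot beta0 intercept (unpenalized).
#' @slot lambda penalty strength (>= 0).
#' @slot alpha elastic-net mixing in \[0, 1\] (0 = ridge, 1 = lasso).
#' @slot inputStage expression stage the model expects (normally
#'   `"zscore"`).
#' @export
setClass("PenalizedModel",
         representation(geneIds = "character", beta = "numeric",
                        beta0 = "numeric", lambda = "numeric",
                        alpha = "numeric", inputStage = "character"))

setValidity("PenalizedModel", function(object) {
    msg <- character()
    if (length(object@beta) != length(object@geneIds))
        msg <- c(msg, "length(beta) must equal length(geneIds)")
    if (anyDuplicated(object@geneIds))
        msg <- c(msg, "duplicated gene identifiers")
    if (length(object@beta0) != 1 || !is.finite(object@beta0))
        msg <- c(msg, "beta0 must be a single finite value")
    if (length(object@lambda) != 1 || object@lambda < 0)
        msg <- c(msg, "lambda must be a single non-negative value")
    if (length(object@alpha) != 1 || object@alpha < 0 || object@alpha > 1)
        msg <- c(msg, "alpha must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @describeIn PenalizedModel-class named coefficient vector.
#' @param object A `PenalizedModel`.
#' @export
modelCoefficients <- function(object) {
    stopifnot(is(object, "PenalizedModel"))
    stats::setNames(object@beta, object@geneIds)
}

#' @describeIn PenalizedModel-class the intercept.
#' @export
modelIntercept <- function(object) {
    stopifnot(is(object, "PenalizedModel"))
    object@beta0
}

setMethod("show", "PenalizedModel", function(object) {
    cat(sprintf(
        "PenalizedModel: %d genes, %d nonzero, lambda=%.4g, alpha=%.2f [%s]\n",
        length(object@beta), sum(object@beta != 0), object@lambda,
        object@alpha, object@inputStage))
})

#' SubtypeAssignment: MUT / MUTLIKE / WT group labels
#'
#' Per-sample subtype assignment produced by [deriveMutlikeLabels()] or
#' [transferModel()]: mutants keep the label `MUT`; wild-type samples whose
#' ridge score lies strictly above the within-cohort wild-type score
#' quantile (default: top decile) are labelled `MUTLIKE`; the rest are
#' `WT`.
#'
#' @slot sampleIds sample identifiers.
#' @slot group factor with levels `MUT`, `MUTLIKE`, `WT`.
#' @slot ridgeScore ridge score per sample (`NA` where unscored).
#' @slot threshold the wild-type score cutoff used.
#' @export
setClass("SubtypeAssignment",
         representation(sampleIds = "character", group = "factor",
                        ridgeScore = "numeric", threshold = "numeric"))

setValidity("SubtypeAssignment", function(object) {
    msg <- character()
    n <- length(object@sampleIds)
    if (length(object@group) != n || length(object@ridgeScore) != n)
        msg <- c(msg, "sampleIds, group and ridgeScore lengths must agree")
    if (!identical(levels(object@group), c("MUT", "MUTLIKE", "WT")))
        msg <- c(msg, "group levels must be MUT, MUTLIKE, WT")
    if (anyDuplicated(object@sampleIds))
        msg <- c(msg, "duplicated sample identifiers")
    if (length(object@threshold) != 1)
        msg <- c(msg, "threshold must be a single value")
    if (length(msg)) msg else TRUE
})

#' @describeIn SubtypeAssignment-class named group factor.
#' @param object A `SubtypeAssignment`.
#' @export
subtypeGroups <- function(object) {
    stopifnot(is(object, "SubtypeAssignment"))
    stats::setNames(object@group, object@sampleIds)
}

#' @describeIn SubtypeAssignment-class assignment as a `data.frame` with
#'   columns `sample_id`, `group`, `ridge_score`.
#' @export
assignmentTable <- function(object) {
    stopifnot(is(object, "SubtypeAssignment"))
    data.frame(sample_id = object@sampleIds,
               group = as.character(object@group),
               ridge_score = object@ridgeScore,
               stringsAsFactors = FALSE)
}

#' @describeIn SubtypeAssignment-class the score cutoff used.
#' @export
assignmentThreshold <- function(object) {
    stopifnot(is(object, "SubtypeAssignment"))
    object@threshold
}

setMethod("show", "SubtypeAssignment", function(object) {
    tab <- table(object@group)
    cat(sprintf(
        "SubtypeAssignment: %d samples (%d MUT, %d MUTLIKE, %d WT), cutoff %.4g\n",
        length(object@sampleIds), tab[["MUT"]], tab[["MUTLIKE"]],
        tab[["WT"]], object@threshold))
})

#' SignatureReport: gene selection frequencies across elastic-net runs
#'
#' Records, for every gene, how often it received a nonzero elastic-net
#' coefficient across resampled fits, and the resulting core gene list
#' (the `k` most frequently selected genes, ties broken lexicographically).
#'
#' @slot selectionCount named integer vector of per-gene selection counts.
#' @slot coreGenes the chosen core gene identifiers.
#' @slot nIter number of elastic-net iterations run.
#' @slot k requested core signature size.
#' @export
setClass("SignatureReport",
         representation(selectionCount = "integer", coreGenes = "character",
                        nIter = "integer", k = "integer"))

setValidity("SignatureReport", function(object) {
    msg <- character()
    if (is.null(names(object@selectionCount)))
        msg <- c(msg, "selectionCount must be named by gene")
    if (any(object@selectionCount < 0) ||
        any(object@selectionCount > object@nIter))
        msg <- c(msg, "selectionCount must lie in [0, nIter]")
    if (!all(object@coreGenes %in% names(object@selectionCount)))
        msg <- c(msg, "coreGenes must be among counted genes")
    if (length(msg)) msg else TRUE
})

#' @describeIn SignatureReport-class the core gene identifiers.
#' @param object A `SignatureReport`.
#' @export
coreGenes <- function(object) {
    stopifnot(is(object, "SignatureReport"))
    object@coreGenes
}

#' @describeIn SignatureReport-class per-gene selection counts
#'   as a `data.frame` sorted by decreasing count.
#' @export
selectionCounts <- function(object) {
    stopifnot(is(object, "SignatureReport"))
    cnt <- object@selectionCount
    ord <- order(-cnt, names(cnt))
    data.frame(gene_id = names(cnt)[ord], selection_count = unname(cnt[ord]),
               stringsAsFactors = FALSE)
}

setMethod("show", "SignatureReport", function(object) {
    cat(sprintf(
        "SignatureReport: %d iterations, %d genes ever selected, %d core genes\n",
        object@nIter, sum(object@selectionCount > 0),
        length(object@coreGenes)))
})
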