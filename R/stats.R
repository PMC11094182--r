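#' Convert raw drug AUC values to sensitivity z-scores
#'
#' Each drug's AUC values are z-scored across non-missing samples (sample
#' standard deviation) and multiplied by -1, so a high z-score indicates
#' drug sensitivity and a low one resistance. Drugs measured in fewer than
#' two samples are set entirely missing with a warning; constant rows
#' become all zero.
#'
#' @param x A [DrugResponse-class] at stage `"raw_auc"`, or a
#'   drugs-by-samples matrix.
#' @return object of the same kind at stage `"auc_z"`.
#' @export
drugAucZscores <- function(x) {
    if (is(x, "DrugResponse")) {
        if (drugStage(x) != "raw_auc")
            stop("drug response is not at the raw_auc stage")
        return(DrugResponse(drugAucZscores(aucValues(x)), stage = "auc_z"))
    }
    stopifnot(is.matrix(x))
    z <- x
    for (i in seq_len(nrow(x))) {
        v <- x[i, ]
        ok <- !is.na(v)
        if (sum(ok) < 2) {
            warning("drug '", rownames(x)[i],
                    "' has fewer than 2 measurements; set to missing")
            z[i, ] <- NA_real_
            next
        }
        s <- stats::sd(v[ok])
        z[i, ok] <- if (s == 0) 0 else -(v[ok] - mean(v[ok])) / s
    }
    z
}

#' Unpaired two-sample comparison (Student or Welch t-test)
#'
#' Two-sided unpaired t-test between two groups of values. With
#' `equalVar = TRUE` (default) the classic pooled-variance Student test is
#' used; otherwise Welch's unequal-variance form. If both groups have zero
#' variance and equal means the comparison is degenerate and `t = 0`,
#' `p = 1` is returned.
#'
#' @param x1,x2 numeric value vectors for the two groups (NAs dropped);
#'   each needs at least 2 observations.
#' @param equalVar pooled-variance Student test (default `TRUE`).
#' @param variable optional variable name carried into the output.
#' @return list with `variable`, `mean1`, `mean2`, `sem1`, `sem2`, `t`,
#'   `df`, `p`.
#' @export
compareGroups <- function(x1, x2, equalVar = TRUE,
                          variable = NA_character_) {
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 2 || length(x2) < 2)
        stop("each group needs at least 2 non-missing values")
    out <- list(variable = variable,
                mean1 = mean(x1), mean2 = mean(x2),
                sem1 = stats::sd(x1) / sqrt(length(x1)),
                sem2 = stats::sd(x2) / sqrt(length(x2)))
    if (stats::sd(x1) == 0 && stats::sd(x2) == 0) {
        d <- mean(x1) - mean(x2)
        out$t <- if (d == 0) 0 else sign(d) * Inf
        out$df <- length(x1) + length(x2) - 2
        out$p <- if (d == 0) 1 else 0
        return(out)
    }
    tt <- stats::t.test(x1, x2, var.equal = equalVar)
    out$t <- unname(tt$statistic)
    out$df <- unname(tt$parameter)
    out$p <- tt$p.value
    out
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up FDR adjustment:
#' `fdr_(i) = min_{j >= i} (p_(j) * m / j)`, capped at 1 and mapped back
#' to input order (equivalent to `p.adjust(method = "BH")`).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values in the input order.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1] with no missing values")
    stats::p.adjust(p, method = "BH")
}

#' Compare one variable across groups with BH correction per family
#'
#' Convenience wrapper running [compareGroups()] for each variable in a
#' named list of value vectors against a fixed pair of groups and
#' adjusting the family of p-values with [bhAdjust()]. The family is
#' exactly the set of variables passed in — callers decide the correction
#' family explicitly.
#'
#' @param values named list; each element a numeric vector of per-sample
#'   values aligned with `groups`.
#' @param groups per-sample group labels.
#' @param pair character vector of the two group labels to compare.
#' @param equalVar see [compareGroups()].
#' @return `data.frame` with one row per variable: group means/sems, `t`,
#'   `p`, `fdr`.
#' @export
groupComparisonTable <- function(values, groups, pair, equalVar = TRUE) {
    stopifnot(is.list(values), length(pair) == 2)
    groups <- as.character(groups)
    rows <- lapply(names(values), function(v) {
        x <- values[[v]]
        cmp <- compareGroups(x[groups == pair[1]], x[groups == pair[2]],
                             equalVar = equalVar, variable = v)
        as.data.frame(cmp, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$fdr <- bhAdjust(out$p)
    out
}

#' Descriptive PCA projection of samples
#'
#' Projects samples onto the leading principal components of the
#' gene-centered samples-by-genes matrix (via [stats::prcomp()], no
#' scaling). Intended as the descriptive overview plot of a cohort, not an
#' inferential tool.
#'
#' @param x genes-by-samples matrix (typically `zscore` stage).
#' @param nComponents number of components to return (default 2).
#' @return list with `coordinates` (samples x components), `varExplained`
#'   (fraction per returned component), `rotation` (genes x components
#'   loadings) and `center` (per-gene means removed before projection).
#' @export
projectPca <- function(x, nComponents = 2) {
    stopifnot(is.matrix(x))
    if (nComponents > min(dim(x)))
        stop("nComponents exceeds matrix rank bound")
    m <- t(x)
    if (all(abs(sweep(m, 2, colMeans(m))) < .Machine$double.eps * 100))
        stop("matrix is constant; no variance to decompose")
    pr <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    ve <- pr$sdev^2 / sum(pr$sdev^2)
    list(coordinates = pr$x[, seq_len(nComponents), drop = FALSE],
         varExplained = ve[seq_len(nComponents)],
         rotation = pr$rotation[, seq_len(nComponents), drop = FALSE],
         center = pr$center)
}
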