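#' Rank genes by a two-group differential statistic
#'
#' Computes a per-gene Welch t statistic (group A minus group B) on the
#' supplied expression matrix (conventionally `log2cpm` stage) and returns
#' genes sorted by decreasing statistic, ties broken lexicographically by
#' gene id. Genes with zero variance in both groups score 0 when the group
#' means are equal; if the means differ with zero variance, the infinite
#' statistic is clamped to just beyond the largest finite statistic so the
#' ordering is preserved and enrichment weights stay finite.
#'
#' @param x genes-by-samples numeric matrix.
#' @param idsA,idsB sample identifiers of the two groups (each >= 3).
#' @return `data.frame` with columns `gene_id`, `stat`, ordered by
#'   decreasing `stat`.
#' @export
rankGenes <- function(x, idsA, idsB) {
    stopifnot(is.matrix(x))
    if (length(idsA) < 3 || length(idsB) < 3)
        stop("each group needs at least 3 samples")
    missing <- setdiff(c(idsA, idsB), colnames(x))
    if (length(missing))
        stop("samples absent from matrix: ",
             paste(utils::head(missing, 5), collapse = ", "))
    a <- x[, idsA, drop = FALSE]; b <- x[, idsB, drop = FALSE]
    n1 <- ncol(a); n2 <- ncol(b)
    m1 <- rowMeans(a); m2 <- rowMeans(b)
    v1 <- rowSums((a - m1)^2) / (n1 - 1)
    v2 <- rowSums((b - m2)^2) / (n2 - 1)
    se <- sqrt(v1 / n1 + v2 / n2)
    d <- m1 - m2
    stat <- ifelse(se > 0, d / se, 0)
    inf <- se == 0 & d != 0
    if (any(inf)) {
        cap <- if (any(!inf & stat != 0)) 1.01 * max(abs(stat[!inf])) else 1
        stat[inf] <- sign(d[inf]) * cap
    }
    ord <- order(-stat, rownames(x))
    data.frame(gene_id = rownames(x)[ord], stat = unname(stat[ord]),
               stringsAsFactors = FALSE)
}

# Weighted running-sum enrichment score for a set given ranked weights.
# w: |stat|^p per ranked position; idx: positions of set members.
# Returns list(es, peak) where peak is the position of the extreme
# deviation (used for the leading edge).
calcEnrichmentScore <- function(w, idx) {
    N <- length(w)
    m <- length(idx)
    hitW <- numeric(N)
    hitW[idx] <- w[idx]
    tot <- sum(hitW)
    pHit <- if (tot > 0) cumsum(hitW) / tot else cumsum(hitW)
    miss <- rep.int(1, N)
    miss[idx] <- 0
    pMiss <- cumsum(miss) / (N - m)
    dev <- pHit - pMiss
    peak <- which.max(abs(dev))
    list(es = dev[peak], peak = peak)
}

#' Preranked gene-set enrichment with permutation-based NES and FDR
#'
#' Weighted Kolmogorov-Smirnov-like running-sum enrichment
#' (weight `|stat|^p`, default `p = 1`; `p = 0` gives the classic KS
#' statistic). The null distribution is built either from gene-label
#' permutations (random sets of the same size drawn from the ranked list,
#' default) or phenotype permutations (group labels shuffled and genes
#' re-ranked each time, requiring `exprs`/`idsA`/`idsB`). NES is the ES
#' divided by the mean absolute null ES of matching sign; the nominal p is
#' the smoothed same-sign permutation tail probability; FDR follows the
#' pooled-null convention: the fraction of all sign-matched null NES at
#' least as extreme, divided by the fraction of observed sign-matched NES
#' at least as extreme, capped at 1.
#'
#' @param ranked `data.frame` from [rankGenes()] (columns `gene_id`,
#'   `stat`) or a named, sorted statistic vector.
#' @param geneSets named list of gene-id vectors.
#' @param weight exponent `p` on `|stat|` (default 1).
#' @param nPerm permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param minSize,maxSize set-size filter after restriction to the ranked
#'   list (defaults 5 and `Inf`); sets outside the bounds or spanning the
#'   whole list are skipped with a message.
#' @param permType `"gene"` (default) or `"phenotype"`.
#' @param exprs,idsA,idsB expression matrix and group sample ids, required
#'   for `permType = "phenotype"`.
#' @return `data.frame` with one row per analyzed set: `set`, `size`,
#'   `es`, `nes`, `p_value`, `fdr`, `leading_edge` (gene ids collapsed
#'   with `";"`).
#' @export
gseaPreranked <- function(ranked, geneSets, weight = 1, nPerm = 1000,
                          seed = 1, minSize = 5, maxSize = Inf,
                          permType = c("gene", "phenotype"),
                          exprs = NULL, idsA = NULL, idsB = NULL) {
    permType <- match.arg(permType)
    if (is.numeric(ranked))
        ranked <- data.frame(gene_id = names(ranked), stat = unname(ranked),
                             stringsAsFactors = FALSE)
    genes <- ranked$gene_id
    N <- length(genes)
    w <- abs(ranked$stat)^weight
    sets <- lapply(geneSets, function(s) which(genes %in% s))
    sizes <- lengths(sets)
    keep <- sizes >= minSize & sizes <= maxSize & sizes < N
    if (any(!keep))
        message("skipping ", sum(!keep),
                " gene set(s) outside the size bounds")
    sets <- sets[keep]
    if (length(sets) == 0)
        stop("no gene set passes the size filter")
    obs <- lapply(sets, function(idx) calcEnrichmentScore(w, idx))
    es <- vapply(obs, `[[`, numeric(1), "es")

    nullES <- withSeed(seedStream(seed, "gsea-permutations"), {
        if (permType == "gene") {
            vapply(sets, function(idx) {
                m <- length(idx)
                vapply(seq_len(nPerm), function(p)
                    calcEnrichmentScore(w, sample.int(N, m))$es,
                    numeric(1))
            }, numeric(nPerm))
        } else {
            if (is.null(exprs) || is.null(idsA) || is.null(idsB))
                stop("phenotype permutation requires exprs, idsA, idsB")
            allIds <- c(idsA, idsB)
            perms <- vapply(seq_len(nPerm), function(p) {
                perm <- sample(allIds)
                rp <- rankGenes(exprs, perm[seq_along(idsA)],
                                perm[-seq_along(idsA)])
                wp <- abs(rp$stat)^weight
                vapply(names(sets), function(nm) {
                    idx <- which(rp$gene_id %in% genes[sets[[nm]]])
                    calcEnrichmentScore(wp, idx)$es
                }, numeric(1))
            }, numeric(length(sets)))
            t(matrix(perms, nrow = length(sets)))
        }
    })
    # columns of nullES correspond to sets, rows to permutations
    normalize <- function(e, null) {
        mpos <- mean(null[null > 0])
        mneg <- mean(abs(null[null < 0]))
        ifelse(e >= 0, e / mpos, e / mneg)
    }
    nes <- numeric(length(sets))
    pval <- numeric(length(sets))
    nullNES <- nullES
    for (j in seq_along(sets)) {
        null <- nullES[, j]
        nes[j] <- normalize(es[j], null)
        same <- null[sign(null) == sign(es[j])]
        pval[j] <- (1 + sum(abs(same) >= abs(es[j]))) / (1 + length(same))
        nullNES[, j] <- normalize(null, null)
    }
    pooled <- as.numeric(nullNES)
    fdr <- vapply(seq_along(sets), function(j) {
        s <- sign(nes[j])
        nullFrac <- mean(sign(pooled) == s & abs(pooled) >= abs(nes[j]))
        nullSide <- mean(sign(pooled) == s)
        obsFrac <- mean(sign(nes) == s & abs(nes) >= abs(nes[j]))
        obsSide <- mean(sign(nes) == s)
        if (nullSide == 0 || obsFrac == 0) return(0)
        min(1, (nullFrac / nullSide) / (obsFrac / obsSide))
    }, numeric(1))
    le <- vapply(seq_along(sets), function(j) {
        idx <- sets[[j]]
        peak <- obs[[j]]$peak
        lead <- if (es[j] >= 0) idx[idx <= peak] else idx[idx >= peak]
        paste(genes[lead], collapse = ";")
    }, character(1))
    data.frame(set = names(sets), size = lengths(sets), es = es,
               nes = nes, p_value = pval, fdr = fdr, leading_edge = le,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Keep gene sets concordantly significant in two cohorts
#'
#' The cross-dataset filter: a set is retained when its NES has the same
#' sign in both result tables and its FDR is below the cutoff in both,
#' independently.
#'
#' @param resA,resB `data.frame`s from [gseaPreranked()] sharing set
#'   names.
#' @param fdrCut FDR cutoff (default 0.05).
#' @return `data.frame` of the retained sets with NES and FDR from both
#'   cohorts.
#' @export
concordanceFilter <- function(resA, resB, fdrCut = 0.05) {
    m <- merge(resA[, c("set", "nes", "fdr")],
               resB[, c("set", "nes", "fdr")],
               by = "set", suffixes = c("_a", "_b"))
    keep <- sign(m$nes_a) == sign(m$nes_b) &
        m$fdr_a < fdrCut & m$fdr_b < fdrCut
    m[keep, , drop = FALSE]
}

#' Per-gene differential expression table (Welch t + BH)
#'
#' Per-gene Welch t-test between two groups with BH adjustment across the
#' tested genes — the family is exactly the genes passed in.
#'
#' @param x genes-by-samples matrix (conventionally `log2cpm`).
#' @param idsA,idsB sample ids of the two groups.
#' @param genes optional subset of genes to test (default all rows).
#' @return `data.frame`: `gene_id`, `stat`, `p`, `fdr`, `direction`
#'   (`"up"`/`"down"` for group A relative to group B).
#' @export
differentialTable <- function(x, idsA, idsB, genes = NULL) {
    if (!is.null(genes)) {
        genes <- intersect(genes, rownames(x))
        x <- x[genes, , drop = FALSE]
    }
    if (nrow(x) == 0)
        return(data.frame(gene_id = character(), stat = numeric(),
                          p = numeric(), fdr = numeric(),
                          direction = character(),
                          stringsAsFactors = FALSE))
    res <- lapply(rownames(x), function(g) {
        cmp <- compareGroups(x[g, idsA], x[g, idsB], equalVar = FALSE,
                             variable = g)
        data.frame(gene_id = g, stat = cmp$t, p = cmp$p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$fdr <- bhAdjust(out$p)
    out$direction <- ifelse(out$stat >= 0, "up", "down")
    out
}

#' Concordantly significant surface-marker genes across two cohorts
#'
#' For one group comparison performed in two cohorts, returns the marker
#' genes significant (FDR below cutoff) in both cohorts with the same
#' direction of change.
#'
#' @param deA,deB `data.frame`s from [differentialTable()] for the same
#'   comparison in two cohorts.
#' @param markers character vector of surface-marker gene ids.
#' @param fdrCut FDR cutoff (default 0.05).
#' @return `data.frame`: `gene_id`, `direction`.
#' @export
concordantMarkers <- function(deA, deB, markers, fdrCut = 0.05) {
    if (length(markers) == 0)
        return(data.frame(gene_id = character(), direction = character(),
                          stringsAsFactors = FALSE))
    a <- deA[deA$gene_id %in% markers & deA$fdr < fdrCut, ]
    b <- deB[deB$gene_id %in% markers & deB$fdr < fdrCut, ]
    m <- merge(a[, c("gene_id", "direction")],
               b[, c("gene_id", "direction")], by = "gene_id",
               suffixes = c("_a", "_b"))
    m <- m[m$direction_a == m$direction_b, , drop = FALSE]
    out <- data.frame(gene_id = m$gene_id, direction = m$direction_a,
                      stringsAsFactors = FALSE)
    out[order(out$gene_id), , drop = FALSE]
}

#' Surface markers shared by the mutant and mutant-like comparisons
#'
#' Intersects the concordant marker sets of the mutant-vs-wild-type and
#' mutant-like-vs-wild-type comparisons, requiring identical direction of
#' change, and flags the shared genes.
#'
#' @param markersMut,markersMutlike `data.frame`s from
#'   [concordantMarkers()] for the two comparisons.
#' @return list with `mut`, `mutlike` (the inputs, with an
#'   `in_intersection` flag) and `shared` (`data.frame`: `gene_id`,
#'   `direction`).
#' @export
surfaceMarkerOverlap <- function(markersMut, markersMutlike) {
    m <- merge(markersMut, markersMutlike, by = "gene_id",
               suffixes = c("_mut", "_mutlike"))
    shared <- m[m$direction_mut == m$direction_mutlike, , drop = FALSE]
    shared <- data.frame(gene_id = shared$gene_id,
                         direction = shared$direction_mut,
                         stringsAsFactors = FALSE)
    markersMut$in_intersection <- markersMut$gene_id %in% shared$gene_id
    markersMutlike$in_intersection <-
        markersMutlike$gene_id %in% shared$gene_id
    list(mut = markersMut, mutlike = markersMutlike, shared = shared)
}
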