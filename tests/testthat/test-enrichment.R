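test_that("gene ranking is antisymmetric with deterministic tie-breaks", {
    withr::with_seed(41, {
        x <- matrix(rnorm(30 * 12, 5), nrow = 30,
                    dimnames = list(sprintf("g%02d", 1:30),
                                    sprintf("s%02d", 1:12)))
    })
    a <- sprintf("s%02d", 1:6); b <- sprintf("s%02d", 7:12)
    r1 <- rankGenes(x, a, b)
    r2 <- rankGenes(x, b, a)
    expect_equal(r1$stat[match(r2$gene_id, r1$gene_id)], -r2$stat,
                 tolerance = 1e-12)
    # equal group means per gene -> all statistics zero, lexicographic order
    x0 <- x; x0[, b] <- x0[, a]
    r0 <- rankGenes(x0, a, b)
    expect_true(all(r0$stat == 0))
    expect_identical(r0$gene_id, sort(rownames(x)))
    expect_error(rankGenes(x, a[1:2], b), "at least 3")
})

test_that("planted program genes rank near the top", {
    sim <- generateCohort(
        simulationConfig(n_samples = 120, n_genes = 300,
                         n_program_genes = 10, effect_size_delta = 2,
                         seed = 13))
    co <- normalizeExpression(sim$cohort)
    l2 <- SummarizedExperiment::assay(co, "log2cpm")
    st <- tp53Status(sim$cohort)
    r <- rankGenes(l2, names(st)[st == "MUT"],
                   names(st)[st == "WT" & !sim$truth$true_mutlike])
    topDecile <- r$gene_id[seq_len(30)]
    expect_true(all(attr(sim$truth, "program_genes") %in% topDecile))
})

test_that("enrichment score matches hand-computed worked examples", {
    ranked <- data.frame(gene_id = paste0("g", 1:5), stat = c(5, 4, 3, 2, 1))
    # set at ranks {1, 4}: running sum peaks at 5/7
    res <- gseaPreranked(ranked, list(S = c("g1", "g4")), weight = 1,
                         nPerm = 50, seed = 1, minSize = 2)
    expect_equal(res$es, 5/7, tolerance = 1e-12)
    # top-m set -> ES exactly 1; bottom-m set -> exactly -1
    rankedN <- data.frame(gene_id = paste0("g", 1:12),
                          stat = seq(6, -5, length.out = 12))
    top <- gseaPreranked(rankedN, list(S = paste0("g", 1:4)),
                         nPerm = 50, seed = 1, minSize = 2)
    bottom <- gseaPreranked(rankedN, list(S = paste0("g", 9:12)),
                            nPerm = 50, seed = 1, minSize = 2)
    expect_equal(top$es, 1.0, tolerance = 1e-12)
    expect_equal(bottom$es, -1.0, tolerance = 1e-12)
    expect_identical(sign(top$nes), sign(top$es))
    expect_identical(sign(bottom$nes), sign(bottom$es))
    # leading edge of the top set is the set itself
    expect_setequal(strsplit(top$leading_edge, ";")[[1]], paste0("g", 1:4))
})

test_that("unweighted ES equals a brute-force KS running sum", {
    bruteKS <- function(n, idx) {
        m <- length(idx)
        run <- 0; best <- 0
        for (i in seq_len(n)) {
            run <- run + if (i %in% idx) 1 / m else -1 / (n - m)
            if (abs(run) > abs(best)) best <- run
        }
        best
    }
    withr::with_seed(43, {
        for (r in 1:15) {
            n <- sample(8:20, 1)
            m <- sample(2:(n - 2), 1)
            idx <- sort(sample(n, m))
            ranked <- data.frame(gene_id = paste0("g", 1:n),
                                 stat = sort(rnorm(n), decreasing = TRUE))
            res <- gseaPreranked(ranked,
                                 list(S = paste0("g", idx)),
                                 weight = 0, nPerm = 10, seed = 1,
                                 minSize = 2)
            expect_equal(res$es, bruteKS(n, idx), tolerance = 1e-12)
        }
    })
})

test_that("weighted ES agrees with the fgsea reference implementation", {
    skip_if_not_installed("fgsea")
    withr::with_seed(47, {
        stats <- sort(rnorm(100), decreasing = TRUE)
        names(stats) <- paste0("g", 1:100)
        sets <- list(A = sample(names(stats), 12),
                     B = sample(names(stats), 25))
    })
    ranked <- data.frame(gene_id = names(stats), stat = unname(stats))
    res <- gseaPreranked(ranked, sets, weight = 1, nPerm = 10, seed = 1)
    ref <- vapply(sets[res$set], function(s)
        fgsea::calcGseaStat(stats, selectedStats = which(names(stats) %in% s),
                            gseaParam = 1),
        numeric(1))
    expect_equal(res$es, unname(ref), tolerance = 1e-10)
})

test_that("permutation p-values are calibrated for random sets", {
    withr::with_seed(51, {
        stats <- sort(rnorm(600), decreasing = TRUE)
        names(stats) <- sprintf("g%04d", 1:600)
        sets <- lapply(1:200, function(i) sample(names(stats), 15))
        names(sets) <- paste0("rand", 1:200)
    })
    ranked <- data.frame(gene_id = names(stats), stat = unname(stats))
    res <- gseaPreranked(ranked, sets, nPerm = 500, seed = 9)
    rate <- mean(res$p_value < 0.05)
    expect_gte(rate, 0.03)
    expect_lte(rate, 0.07)
    expect_true(all(res$es >= -1 & res$es <= 1))
    expect_true(all(res$p_value > 0 & res$p_value <= 1))
})

test_that("gene sets spanning the whole ranked list are rejected", {
    ranked <- data.frame(gene_id = paste0("g", 1:6), stat = 6:1)
    expect_error(suppressMessages(
        gseaPreranked(ranked, list(S = paste0("g", 1:6)), minSize = 2)),
        "size filter")
})

test_that("concordance filter keeps sign-matched, doubly significant sets", {
    resA <- data.frame(set = c("s1", "s2", "s3"),
                       nes = c(2.1, 2.1, 1.5), fdr = c(0.01, 0.01, 0.01))
    resB <- data.frame(set = c("s1", "s2", "s3"),
                       nes = c(1.8, -1.8, 1.2), fdr = c(0.04, 0.01, 0.06))
    kept <- concordanceFilter(resA, resB)
    expect_identical(kept$set, "s1")   # s2 discordant sign, s3 fdr 0.06
    # self-comparison returns exactly the significant sets
    self <- concordanceFilter(resA, resA, fdrCut = 0.05)
    expect_setequal(self$set, resA$set[resA$fdr < 0.05])
})

test_that("surface-marker overlap requires shared identity and direction", {
    mkMut <- data.frame(gene_id = c("CD99", "IL1B", "KITX"),
                        direction = c("down", "up", "up"))
    mkLike <- data.frame(gene_id = c("CD99", "IL1B", "TLR2"),
                         direction = c("down", "down", "up"))
    ov <- surfaceMarkerOverlap(mkMut, mkLike)
    expect_identical(ov$shared$gene_id, "CD99")   # IL1B direction flips
    expect_true(ov$mut$in_intersection[ov$mut$gene_id == "CD99"])
    expect_false(any(ov$mutlike$in_intersection[
        ov$mutlike$gene_id != "CD99"]))

    empty <- concordantMarkers(
        data.frame(gene_id = "CD99", stat = 2, p = 0.001, fdr = 0.001,
                   direction = "up"),
        data.frame(gene_id = "CD99", stat = 2, p = 0.001, fdr = 0.001,
                   direction = "up"),
        markers = character(0))
    expect_identical(nrow(empty), 0L)
})

test_that("concordant markers are recovered from constructed DE tables", {
    makeCohortMatrix <- function(seed) {
        withr::with_seed(seed, {
            x <- matrix(rnorm(40 * 24, 6), nrow = 40,
                        dimnames = list(sprintf("m%02d", 1:40),
                                        sprintf("s%02d", 1:24)))
            a <- sprintf("s%02d", 1:12)
            x[sprintf("m%02d", 1:3), a] <- x[sprintf("m%02d", 1:3), a] + 4
            x[sprintf("m%02d", 4:5), a] <- x[sprintf("m%02d", 4:5), a] - 4
            x
        })
    }
    a <- sprintf("s%02d", 1:12); b <- sprintf("s%02d", 13:24)
    up <- sprintf("m%02d", 1:3); dn <- sprintf("m%02d", 4:5)
    # two independently drawn cohorts sharing only the planted shifts
    de1 <- differentialTable(makeCohortMatrix(53), a, b,
                             genes = sprintf("m%02d", 1:40))
    de2 <- differentialTable(makeCohortMatrix(54), a, b,
                             genes = sprintf("m%02d", 1:40))
    mk <- concordantMarkers(de1, de2, markers = sprintf("m%02d", 1:40))
    expect_setequal(mk$gene_id, c(up, dn))
    expect_identical(mk$direction[match(up, mk$gene_id)],
                     rep("up", 3))
    expect_identical(mk$direction[match(dn, mk$gene_id)],
                     rep("down", 2))
})
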