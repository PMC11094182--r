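makeToy <- function(n = 40, seed = 42) {
    withr::with_seed(seed, {
        x <- matrix(rnorm(2 * n), nrow = 2,
                    dimnames = list(c("gA", "gB"), sprintf("s%02d", 1:n)))
        y <- as.integer(x[1, ] + rnorm(n, 0, 0.8) > 0)
    })
    list(x = x, y = y)
}

test_that("penalty-dominated limits collapse to the null model", {
    toy <- makeToy()
    m <- fitPenalizedLogistic(toy$x, toy$y, lambda = 1e6, alpha = 0)
    expect_lt(max(abs(m@beta)), 1e-3)
    expect_equal(m@beta0, qlogis(mean(toy$y)), tolerance = 1e-3)
    # lasso at large lambda: exact zeros, not just small
    ml <- fitPenalizedLogistic(toy$x, toy$y, lambda = 10, alpha = 1)
    expect_identical(ml@beta, c(0, 0))
})

test_that("fitted objective matches independent optimizer oracles", {
    toy <- makeToy()
    obj <- function(par, lambda, alpha)
        directObjective(par[1], par[-1], toy$x, toy$y, lambda, alpha)
    for (la in c(0.01, 0.1, 1)) {
        m <- fitPenalizedLogistic(toy$x, toy$y, lambda = la, alpha = 0)
        oracle <- stats::optim(c(0, 0, 0), obj, lambda = la, alpha = 0,
                               method = "BFGS",
                               control = list(maxit = 1000,
                                              reltol = 1e-14))$value
        expect_equal(penalizedLogisticObjective(m, toy$x, toy$y), oracle,
                     tolerance = 1e-6)
    }
    # non-smooth penalties: nested grid-refinement oracle
    gridOracle <- function(lambda, alpha) {
        ctr <- c(0, 0, 0); width <- 4; best <- Inf
        for (r in 1:8) {
            g <- seq(-width, width, length.out = 11)
            for (a in ctr[1] + g) for (b in ctr[2] + g)
                for (cc in ctr[3] + g) {
                    v <- obj(c(a, b, cc), lambda, alpha)
                    if (v < best) { best <- v; bp <- c(a, b, cc) }
                }
            ctr <- bp; width <- width / 4
        }
        best
    }
    for (al in c(0.5, 1)) {
        m <- fitPenalizedLogistic(toy$x, toy$y, lambda = 0.1, alpha = al)
        expect_equal(penalizedLogisticObjective(m, toy$x, toy$y),
                     gridOracle(0.1, al), tolerance = 1e-6)
    }
})

test_that("fit guards reject degenerate input", {
    toy <- makeToy()
    expect_error(fitPenalizedLogistic(toy$x, rep(1, ncol(toy$x)), 0.1),
                 "both classes")
    xb <- toy$x; xb[1, 1] <- NA
    expect_error(fitPenalizedLogistic(xb, toy$y, 0.1), "non-finite")
    expect_error(fitPenalizedLogistic(toy$x, toy$y, -1), "lambda")
    expect_error(fitPenalizedLogistic(toy$x, toy$y, 0.1, alpha = 2),
                 "alpha")
})

test_that("objective never exceeds the null model and ridge norms shrink", {
    withr::with_seed(11, {
        x <- matrix(rnorm(30 * 60), nrow = 30,
                    dimnames = list(sprintf("g%02d", 1:30),
                                    sprintf("s%02d", 1:60)))
        y <- rbinom(60, 1, plogis(2 * x[1, ] - x[2, ]))
    })
    if (length(unique(y)) < 2) skip("degenerate draw")
    null <- directObjective(qlogis(mean(y)), numeric(30), x, y, 0, 0)
    grid <- c(0.01, 0.1, 0.5, 2, 10)
    norms <- vapply(grid, function(la) {
        m <- fitPenalizedLogistic(x, y, la, alpha = 0)
        expect_lte(penalizedLogisticObjective(m, x, y),
                   directObjective(qlogis(mean(y)), numeric(30), x, y,
                                   la, 0) + 1e-8)
        sqrt(sum(m@beta^2))
    }, numeric(1))
    expect_true(all(diff(norms) < 1e-8))   # non-increasing in lambda
})

test_that("cross-validated lambda selection is deterministic and honest", {
    withr::with_seed(13, {
        x <- matrix(rnorm(25 * 80), nrow = 25,
                    dimnames = list(sprintf("g%02d", 1:25),
                                    sprintf("s%02d", 1:80)))
        y <- rbinom(80, 1, plogis(1.5 * x[1, ]))
    })
    grid <- c(5, 1, 0.2, 0.05)
    sel <- selectLambdaCV(x, y, grid, alpha = 0, nFolds = 5, seed = 2)
    expect_true(sel$lambda %in% grid)
    expect_identical(selectLambdaCV(x, y, grid, alpha = 0, nFolds = 5,
                                    seed = 2), sel)
    # single-value grid returns that value
    one <- selectLambdaCV(x, y, 0.3, seed = 2)
    expect_identical(one$lambda, 0.3)
    # independent per-fold recomputation reproduces the cv table
    fold <- mutlikeAML:::stratifiedFolds(y, 5, seed = 2)
    path <- sort(unique(c(grid, max(grid) * c(100, 10, 3))),
                 decreasing = TRUE)
    dev <- sapply(1:5, function(f) {
        tr <- fold != f
        fit <- glmnet::glmnet(t(x)[tr, ], y[tr], family = "binomial",
                              alpha = 0, lambda = path,
                              standardize = FALSE, thresh = 1e-9,
                              maxit = 1e5)
        p <- predict(fit, t(x)[!tr, ], s = sort(grid, decreasing = TRUE),
                     type = "response")
        yt <- y[!tr]
        colMeans(-2 * (yt * log(pmax(p, 1e-15)) +
                       (1 - yt) * log(pmax(1 - p, 1e-15))))
    })
    expect_equal(unname(rowMeans(dev)), sel$cvTable$mean_deviance,
                 tolerance = 1e-10)
})

test_that("scores are the linear predictor with consistent probabilities", {
    z <- matrix(rnorm(6), nrow = 2,
                dimnames = list(c("gA", "gB"), c("u", "v", "w")))
    m0 <- new("PenalizedModel", geneIds = c("gA", "gB"), beta = c(0, 0),
              beta0 = 0.5, lambda = 1, alpha = 0, inputStage = "zscore")
    sc <- scoreSamples(m0, z)
    expect_equal(sc$ridge_score, rep(0.5, 3))
    expect_equal(sc$probability, rep(plogis(0.5), 3))
    expect_equal(sc$probability, 1 / (1 + exp(-sc$ridge_score)),
                 tolerance = 1e-12)

    m1 <- new("PenalizedModel", geneIds = "gA", beta = 2, beta0 = 0,
              lambda = 1, alpha = 0, inputStage = "zscore")
    z1 <- matrix(1.5, 1, 1, dimnames = list("gA", "s"))
    expect_equal(scoreSamples(m1, z1)$ridge_score, 3.0)

    # invariant to gene row order and to extra genes
    perm <- z[c(2, 1), ]
    m <- new("PenalizedModel", geneIds = c("gA", "gB"), beta = c(1, -2),
             beta0 = 0.1, lambda = 1, alpha = 0, inputStage = "zscore")
    expect_equal(scoreSamples(m, perm), scoreSamples(m, z))
    expect_error(scoreSamples(m, z[1, , drop = FALSE]), "gB")
})

test_that("AUROC equals brute-force pair concordance with tie half-credit", {
    s <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.3, 0.2, 0.1, 0.05, 0.0)
    y <- c(1,   1,   0,   1,   0,   1,   0,   0,   1,    0)
    pairs <- outer(s[y == 1], s[y == 0], function(a, b)
        (a > b) + 0.5 * (a == b))
    expect_equal(evaluateClassifier(s, y)$auroc, mean(pairs))
    # symmetry under sign flip
    expect_equal(evaluateClassifier(-s, y)$auroc,
                 1 - evaluateClassifier(s, y)$auroc)
    # perfect separation
    expect_equal(evaluateClassifier(c(3, 2, -1, -2), c(1, 1, 0, 0))$auroc, 1)
    expect_error(evaluateClassifier(s, rep(1, 10)), "both classes")
})
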