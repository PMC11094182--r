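#' Fit a penalized logistic regression on z-scored expression
#'
#' Minimizes the objective
#' \deqn{\frac{1}{n}\sum_i \left[-y_i \log p_i - (1-y_i)\log(1-p_i)\right]
#'   + \lambda\left[\alpha \|\beta\|_1 +
#'   \frac{1-\alpha}{2}\|\beta\|_2^2\right]}
#' with \eqn{p_i = \mathrm{logistic}(\beta_0 + x_i^\top \beta)} and an
#' unpenalized intercept. `alpha = 0` is pure ridge (the default used for
#' the mutant classifier), `alpha = 1` pure lasso. Features are assumed
#' pre-standardized by [normalizeExpression()]; no internal standardization
#' is applied, so coefficients are comparable across genes.
#'
#' The optimization is delegated to \pkg{glmnet}, whose binomial objective
#' is exactly the one above; the fit is run along a short warm-start path
#' ending at the requested `lambda` with a tight convergence threshold.
#'
#' @param x genes-by-samples matrix at the `zscore` stage.
#' @param y binary labels (0/1, logical, or a two-level factor with the
#'   second level as positive class), one per sample of `x`.
#' @param lambda penalty strength, >= 0.
#' @param alpha elastic-net mixing in \[0, 1\]; default 0 (ridge).
#' @param inputStage stage tag recorded in the model (default
#'   `"zscore"`).
#' @param thresh glmnet convergence threshold (default `1e-10`).
#' @return A [PenalizedModel-class].
#' @seealso [selectLambdaCV()], [scoreSamples()],
#'   [penalizedLogisticObjective()]
#' @export
fitPenalizedLogistic <- function(x, y, lambda, alpha = 0,
                                 inputStage = "zscore", thresh = 1e-10) {
    stopifnot(is.matrix(x))
    if (any(!is.finite(x)))
        stop("expression matrix contains non-finite values")
    y <- coerceBinary(y)
    if (length(y) != ncol(x))
        stop("length(y) must equal ncol(x)")
    if (length(unique(y)) < 2)
        stop("both classes must be present in 'y'")
    if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0)
        stop("lambda must be a single non-negative value")
    if (alpha < 0 || alpha > 1)
        stop("alpha must lie in [0, 1]")
    path <- if (lambda > 0) sort(lambda * c(100, 10, 3, 1),
                                 decreasing = TRUE)
            else c(1, 0.1, 0.01, 0)
    fit <- quietGlmnet(
        glmnet::glmnet(t(x), y, family = "binomial", alpha = alpha,
                       lambda = path, standardize = FALSE,
                       thresh = thresh, maxit = 1e5))
    j <- which(abs(fit$lambda - lambda) <= 1e-9 * max(lambda, 1))
    if (length(j) != 1)    # path truncated: solution diverges at this lambda
        stop("fit did not converge at lambda = ", lambda,
             "; increase the penalty")
    new("PenalizedModel",
        geneIds = rownames(x),
        beta = as.numeric(fit$beta[, j]),
        beta0 = as.numeric(fit$a0[j]),
        lambda = lambda, alpha = alpha, inputStage = inputStage)
}

coerceBinary <- function(y) {
    if (is.factor(y)) y <- as.integer(y) - 1L
    if (is.logical(y)) y <- as.integer(y)
    if (!all(y %in% c(0L, 1L)))
        stop("'y' must be binary (0/1, logical, or two-level factor)")
    as.integer(y)
}

#' Penalized logistic objective value of a model on data
#'
#' Evaluates the convex objective that [fitPenalizedLogistic()] minimizes,
#' at the model's coefficients. Useful for verifying fits against
#' independent optimizers.
#'
#' @param model A [PenalizedModel-class].
#' @param x genes-by-samples matrix covering the model's genes.
#' @param y binary labels.
#' @return single numeric objective value.
#' @export
penalizedLogisticObjective <- function(model, x, y) {
    stopifnot(is(model, "PenalizedModel"))
    y <- coerceBinary(y)
    eta <- scoreSamples(model, x)$ridge_score
    # -y*log p - (1-y)*log(1-p) = log(1 + exp(eta)) - y*eta, stabilized
    nll <- mean(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta)
    pen <- model@lambda * (model@alpha * sum(abs(model@beta)) +
                           (1 - model@alpha) / 2 * sum(model@beta^2))
    nll + pen
}

#' Select the penalty strength by stratified cross-validation
#'
#' Splits samples into `nFolds` folds stratified by class, fits the full
#' `lambdaGrid` path on each training fold, and picks the `lambda`
#' minimizing the mean held-out binomial deviance. With `oneSE = TRUE` the
#' largest `lambda` whose mean deviance is within one standard error of
#' the minimum is returned instead.
#'
#' @inheritParams fitPenalizedLogistic
#' @param lambdaGrid non-empty numeric vector of candidate penalties.
#' @param nFolds number of folds (>= 2), default 5.
#' @param seed integer seed controlling fold assignment.
#' @param oneSE apply the one-standard-error rule (default `FALSE`).
#' @return list with `lambda` (the selection) and `cvTable`, a
#'   `data.frame` with columns `lambda`, `mean_deviance`, `se_deviance`.
#' @export
selectLambdaCV <- function(x, y, lambdaGrid, alpha = 0, nFolds = 5,
                           seed = 1, oneSE = FALSE) {
    y <- coerceBinary(y)
    if (length(lambdaGrid) == 0)
        stop("lambdaGrid must be non-empty")
    grid <- sort(unique(lambdaGrid), decreasing = TRUE)
    # glmnet prefers a descending path of several values; pad above the
    # grid with warm-start points and read off predictions at the grid.
    path <- sort(unique(c(grid, max(grid, 1e-3) * c(100, 10, 3))),
                 decreasing = TRUE)
    fold <- stratifiedFolds(y, nFolds, seed)
    dev <- matrix(NA_real_, nFolds, length(grid))
    xt <- t(x)
    for (f in seq_len(nFolds)) {
        tr <- fold != f
        fit <- quietGlmnet(
            glmnet::glmnet(xt[tr, , drop = FALSE], y[tr],
                           family = "binomial", alpha = alpha,
                           lambda = path, standardize = FALSE,
                           thresh = 1e-9, maxit = 1e5))
        p <- stats::predict(fit, xt[!tr, , drop = FALSE], s = grid,
                            type = "response", exact = FALSE)
        dev[f, ] <- colMeans(binomialDeviance(y[!tr], p))
    }
    meanDev <- colMeans(dev)
    seDev <- apply(dev, 2, stats::sd) / sqrt(nFolds)
    best <- which.min(meanDev)   # ties: which.min takes the first,
                                 # i.e. the largest (most regularized) lambda
    if (oneSE) {
        ok <- meanDev <= meanDev[best] + seDev[best]
        best <- which(ok)[1]
    }
    list(lambda = grid[best],
         cvTable = data.frame(lambda = grid, mean_deviance = meanDev,
                              se_deviance = seDev))
}

#' Compute ridge scores and class probabilities for samples
#'
#' The ridge score of sample `i` is the linear predictor
#' `beta0 + sum_j beta_j * x[j, i]` — higher means the expression profile
#' more closely resembles the positive (mutant) class. The probability is
#' its logistic transform.
#'
#' @param model A [PenalizedModel-class].
#' @param x genes-by-samples matrix whose rownames cover the model's
#'   genes (extra genes are ignored; any row order is accepted).
#' @return `data.frame` with columns `sample_id`, `ridge_score`,
#'   `probability`.
#' @export
scoreSamples <- function(model, x) {
    stopifnot(is(model, "PenalizedModel"), is.matrix(x))
    missing <- setdiff(model@geneIds, rownames(x))
    if (length(missing))
        stop("matrix lacks ", length(missing), " model gene(s): ",
             paste(utils::head(missing, 5), collapse = ", "),
             if (length(missing) > 5) ", ..." else "")
    eta <- drop(crossprod(x[model@geneIds, , drop = FALSE], model@beta)) +
        model@beta0
    data.frame(sample_id = colnames(x), ridge_score = unname(eta),
               probability = unname(stats::plogis(eta)),
               stringsAsFactors = FALSE)
}

#' Classifier performance: AUROC, sensitivity, specificity
#'
#' AUROC is the rank-based concordance probability (ties get half
#' credit, the Mann-Whitney convention). Sensitivity and specificity are
#' computed at the probability-0.5 operating point, i.e. a positive call
#' when the ridge score exceeds 0.
#'
#' @param scores `data.frame` from [scoreSamples()] or a numeric score
#'   vector.
#' @param y binary labels aligned with `scores`.
#' @return list with `auroc`, `sensitivity`, `specificity`.
#' @export
evaluateClassifier <- function(scores, y) {
    if (is.data.frame(scores)) scores <- scores$ridge_score
    y <- coerceBinary(y)
    if (length(scores) != length(y))
        stop("scores and labels differ in length")
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    if (n1 == 0 || n0 == 0)
        stop("both classes must be present to evaluate a classifier")
    r <- rank(scores)
    auroc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    pos <- scores > 0
    list(auroc = auroc,
         sensitivity = mean(pos[y == 1]),
         specificity = mean(!pos[y == 0]))
}
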