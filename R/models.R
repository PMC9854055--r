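## The six regressors.
##
## Penalty conventions.  fitRidge/fitLasso minimize the raw penalized
## residual sum of squares
##     RSS + lambda * sum(beta^2)     (ridge)
##     RSS + lambda * sum(|beta|)     (lasso)
## with an unpenalized intercept, exactly as written.  `perObservation = TRUE`
## rescales lambda to the per-observation convention of the common reference
## toolkits (objective RSS/(2N) + lambda * penalty for lasso, with the ridge
## analogue RSS/(2N) + lambda/2 * sum(beta^2)), and `standardize = TRUE`
## applies the penalty on unit-variance columns (population SD), reporting
## coefficients back on the original scale.  Default model specs use the
## per-observation standardized convention with lambda = 1, which is what
## "default" ridge/lasso means in those toolkits; direct calls default to the
## raw convention.

#' Construct a model specification
#'
#' @param kind one of \code{"mlr"}, \code{"ridge"}, \code{"lasso"},
#'   \code{"rfr"}, \code{"gbr"}, \code{"knnr"}.
#' @param params named list of hyperparameters for \code{kind}; unset entries
#'   take the defaults of \code{\link{defaultSpec}}.
#' @param extended logical; fit on the 21-column extended feature matrix.
#' @param seed integer seed for stochastic fits.
#' @return a \code{\linkS4class{ModelSpec}}.
#' @export
modelSpec <- function(kind, params = list(), extended = FALSE, seed = 1L) {
    base <- defaultParams(kind)
    base[names(params)] <- params
    new("ModelSpec", kind = kind, params = base,
        extended = as.logical(extended), seed = as.integer(seed))
}

defaultParams <- function(kind) {
    switch(kind,
        mlr = list(),
        ## the reference toolkits define the two unit penalties differently:
        ## ridge takes lambda raw (negligible against an RSS of thousands of
        ## observations), lasso per observation (over-constraining when every
        ## |cor(x_j, y)| * sd(y) < 1); both penalize standardized columns
        ridge = list(lambda = 1, standardize = TRUE, perObservation = FALSE),
        lasso = list(lambda = 1, standardize = TRUE, perObservation = TRUE),
        rfr = list(ntree = 100L, maxDepth = Inf, nodesize = 1L,
                   bootstrap = TRUE),
        gbr = list(nrounds = 100L, learningRate = 0.1, maxDepth = 3L),
        knnr = list(k = 5L),
        stop(sprintf("unknown model kind: %s", kind)))
}

#' Default (untuned) model specification
#'
#' The hyperparameters a "default" fit means for each model kind: random
#' forest with 100 trees, unlimited depth, squared-error splitting and
#' bootstrap resampling; gradient boosting with 100 stages, learning rate 0.1
#' and depth-3 weak learners; 5 nearest neighbours; ridge and lasso with a
#' unit penalty in the per-observation standardized convention (the
#' convention under which a unit lasso penalty over-constrains weakly
#' correlated LogP data to the intercept-only model).  All values are
#' overridable via \code{\link{modelSpec}}.
#'
#' @inheritParams modelSpec
#' @return a \code{\linkS4class{ModelSpec}}.
#' @export
defaultSpec <- function(kind, extended = FALSE, seed = 1L) {
    modelSpec(kind, list(), extended = extended, seed = seed)
}

setMethod("show", "ModelSpec", function(object) {
    p <- object@params
    ptxt <- if (length(p))
        paste(names(p), vapply(p, function(v) paste(format(v), collapse = ","),
                               character(1L)), sep = "=", collapse = ", ")
    else "none"
    cat(sprintf("ModelSpec kind=%s extended=%s seed=%d\n  params: %s\n",
                object@kind, object@extended, object@seed, ptxt))
})

newLogPModel <- function(spec, fit, featNames) {
    new("LogPModel", spec = spec, fit = fit, featureNames = featNames)
}

setMethod("show", "LogPModel", function(object) {
    cat(sprintf("LogPModel (%s), feature width M = %d\n",
                object@spec@kind, length(object@featureNames)))
})

featNamesOf <- function(X) {
    if (!is.null(colnames(X))) colnames(X)
    else paste0("x", seq_len(ncol(X)))
}

checkXy <- function(X, y) {
    X <- as.matrix(X)
    if (nrow(X) == 0L) stop("no training rows")
    if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
    if (!all(is.finite(X)) || !all(is.finite(y)))
        stop("X and y must be finite")
    X
}

## ---- multivariate linear regression ---------------------------------------

#' Fit multivariate linear regression
#'
#' Ordinary least squares over the feature columns with an intercept,
#' minimizing the residual sum of squares.  A rank-deficient design is
#' resolved by the minimum-norm solution (via SVD pseudo-inverse) with a
#' warning.
#'
#' @param X feature matrix (N x M).
#' @param y numeric responses (LogP, log10 units).
#' @return a \code{\linkS4class{LogPModel}} whose fit holds \code{intercept}
#'   and \code{coefficients}.
#' @export
#' @examples
#' X <- cbind(a = c(1, 2, 3))
#' fitMLR(X, c(2, 4, 6))   # slope 2, intercept 0
fitMLR <- function(X, y) {
    X <- checkXy(X, y)
    Xa <- cbind(1, X)
    qrX <- qr(Xa)
    if (qrX$rank < ncol(Xa)) {
        warning("rank-deficient design matrix; returning the minimum-norm solution")
        sv <- svd(Xa)
        pos <- sv$d > max(dim(Xa)) * .Machine$double.eps * sv$d[1L]
        beta <- sv$v[, pos, drop = FALSE] %*%
            ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
        beta <- drop(beta)
    } else {
        beta <- qr.coef(qrX, y)
    }
    spec <- modelSpec("mlr")
    newLogPModel(spec,
                 list(intercept = unname(beta[1L]),
                      coefficients = unname(beta[-1L])),
                 featNamesOf(X))
}

standardizeCols <- function(Xc) {
    sds <- sqrt(colMeans(Xc^2))
    sds[sds == 0] <- 1
    list(Z = sweep(Xc, 2L, sds, "/"), sds = sds)
}

## ---- ridge ----------------------------------------------------------------

#' Fit ridge regression
#'
#' Minimizes \code{RSS + lambda * sum(beta^2)} with an unpenalized intercept,
#' by direct solve of the penalized normal equations on centered data.  See
#' the package vignette for the \code{standardize} / \code{perObservation}
#' conventions.
#'
#' @inheritParams fitMLR
#' @param lambda non-negative penalty weight.
#' @param standardize penalize on unit-variance columns.
#' @param perObservation interpret \code{lambda} in the per-observation
#'   convention (effective raw penalty \code{N * lambda}).
#' @return a \code{\linkS4class{LogPModel}}.
#' @export
fitRidge <- function(X, y, lambda, standardize = FALSE,
                     perObservation = FALSE) {
    if (lambda < 0) stop("lambda must be >= 0")
    X <- checkXy(X, y)
    n <- nrow(X)
    xm <- colMeans(X); ym <- mean(y)
    Xc <- sweep(X, 2L, xm); yc <- y - ym
    sds <- rep(1, ncol(X))
    if (standardize) {
        st <- standardizeCols(Xc); Xc <- st$Z; sds <- st$sds
    }
    lamEff <- if (perObservation) n * lambda else lambda
    beta <- unname(drop(solve(crossprod(Xc) + diag(lamEff, ncol(Xc)),
                              crossprod(Xc, yc))))
    beta <- beta / sds
    spec <- modelSpec("ridge", list(lambda = lambda,
                                    standardize = standardize,
                                    perObservation = perObservation))
    newLogPModel(spec,
                 list(intercept = ym - sum(xm * beta), coefficients = beta),
                 featNamesOf(X))
}

## ---- lasso ----------------------------------------------------------------

softThreshold <- function(z, gamma) sign(z) * pmax(abs(z) - gamma, 0)

#' Fit lasso regression
#'
#' Minimizes \code{RSS + lambda * sum(|beta|)} with an unpenalized intercept,
#' by cyclic coordinate descent on centered data.  At a sufficiently large
#' penalty every coefficient is set exactly to zero and the model collapses
#' to the intercept \code{mean(y)} (training R-squared exactly 0).
#' Non-convergence within \code{maxIter} sweeps produces a warning carrying
#' the iteration count.
#'
#' @inheritParams fitRidge
#' @param tol convergence tolerance on the maximum coefficient update.
#' @param maxIter maximum coordinate-descent sweeps.
#' @return a \code{\linkS4class{LogPModel}}.
#' @export
fitLasso <- function(X, y, lambda, standardize = FALSE,
                     perObservation = FALSE, tol = 1e-10, maxIter = 100000L) {
    if (lambda < 0) stop("lambda must be >= 0")
    X <- checkXy(X, y)
    n <- nrow(X)
    xm <- colMeans(X); ym <- mean(y)
    Xc <- sweep(X, 2L, xm); yc <- y - ym
    sds <- rep(1, ncol(X))
    if (standardize) {
        st <- standardizeCols(Xc); Xc <- st$Z; sds <- st$sds
    }
    lamEff <- if (perObservation) 2 * n * lambda else lambda
    p <- ncol(Xc)
    colSq <- colSums(Xc^2)
    beta <- numeric(p)
    r <- yc
    converged <- FALSE
    iter <- 0L
    scale <- max(abs(yc), 1)
    while (iter < maxIter) {
        iter <- iter + 1L
        delta <- 0
        for (j in seq_len(p)) {
            if (colSq[j] == 0) next
            bOld <- beta[j]
            z <- colSq[j] * bOld + sum(Xc[, j] * r)
            bNew <- softThreshold(z, lamEff / 2) / colSq[j]
            if (bNew != bOld) {
                r <- r + Xc[, j] * (bOld - bNew)
                beta[j] <- bNew
                delta <- max(delta, abs(bNew - bOld))
            }
        }
        if (delta <= tol * scale) { converged <- TRUE; break }
    }
    if (!converged)
        warning(sprintf("lasso coordinate descent did not converge in %d sweeps",
                        iter))
    beta <- unname(beta / sds)
    spec <- modelSpec("lasso", list(lambda = lambda,
                                    standardize = standardize,
                                    perObservation = perObservation))
    newLogPModel(spec,
                 list(intercept = ym - sum(xm * beta), coefficients = beta,
                      iterations = iter),
                 featNamesOf(X))
}

## ---- random forest --------------------------------------------------------

#' Fit a random forest regressor
#'
#' An ensemble of \code{ntree} regression trees whose prediction is the
#' plain mean over trees, fitted with squared-error splitting and (by
#' default) bootstrap resampling per tree, via the \pkg{randomForest}
#' package.  Deterministic under the spec's seed.  Depth is controlled
#' through the maximum leaf count (\code{maxnodes = 2^maxDepth}; \code{Inf}
#' leaves growth unrestricted).
#'
#' @inheritParams fitMLR
#' @param spec a \code{\linkS4class{ModelSpec}} of kind \code{"rfr"}
#'   (params: \code{ntree}, \code{maxDepth}, \code{nodesize},
#'   \code{bootstrap}).
#' @param seed overrides the spec's seed when given.
#' @return a \code{\linkS4class{LogPModel}}.
#' @export
fitRandomForest <- function(X, y, spec = defaultSpec("rfr"), seed = NULL) {
    X <- checkXy(X, y)
    p <- spec@params
    if (is.null(p$ntree) || p$ntree < 1L) stop("ntree must be >= 1")
    if (!is.null(seed)) spec@seed <- as.integer(seed)
    maxnodes <- if (is.finite(p$maxDepth)) as.integer(2^p$maxDepth) else NULL
    mtry <- if (!is.null(p$mtry)) p$mtry
            else max(floor(ncol(X) / 3), 1L)
    forest <- withSeed(spec@seed,
        randomForest::randomForest(
            x = X, y = y, ntree = as.integer(p$ntree), mtry = mtry,
            nodesize = if (is.null(p$nodesize)) 1L else as.integer(p$nodesize),
            maxnodes = maxnodes,
            replace = isTRUE(p$bootstrap), sampsize = nrow(X)))
    newLogPModel(spec, list(forest = forest), featNamesOf(X))
}

## ---- gradient boosting ----------------------------------------------------

#' Fit a gradient boosted regressor
#'
#' Stagewise sum of depth-limited regression trees, each fitted to the
#' residuals of the running prediction scaled by the learning rate,
#' initialized at \code{mean(y)}; squared-error loss.  Backed by
#' \pkg{xgboost} (single thread, no subsampling, no leaf regularization, so
#' each stage is an exact shrunken residual fit and the training RSS is
#' non-increasing in the number of stages).  Deterministic under the spec's
#' seed.
#'
#' @inheritParams fitRandomForest
#' @param spec a \code{\linkS4class{ModelSpec}} of kind \code{"gbr"}
#'   (params: \code{nrounds}, \code{learningRate}, \code{maxDepth}).
#' @return a \code{\linkS4class{LogPModel}}.
#' @export
fitGBR <- function(X, y, spec = defaultSpec("gbr"), seed = NULL) {
    X <- checkXy(X, y)
    p <- spec@params
    if (is.null(p$nrounds) || p$nrounds < 1L) stop("nrounds must be >= 1")
    if (is.null(p$learningRate) || p$learningRate <= 0)
        stop("learning rate must be > 0")
    if (!is.null(seed)) spec@seed <- as.integer(seed)
    params <- list(objective = "reg:squarederror",
                   eta = p$learningRate,
                   max_depth = as.integer(p$maxDepth),
                   lambda = 0, alpha = 0, min_child_weight = 1,
                   subsample = 1, colsample_bytree = 1,
                   base_score = mean(y),
                   nthread = 1, seed = spec@seed)
    booster <- xgboost::xgb.train(
        params = params,
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
        nrounds = as.integer(p$nrounds), verbose = 0)
    newLogPModel(spec,
                 list(raw = xgboost::xgb.save.raw(booster),
                      booster = booster),
                 featNamesOf(X))
}

gbrBooster <- function(fit) {
    if (!is.null(fit$booster)) fit$booster
    else xgboost::xgb.load.raw(fit$raw)
}

## ---- k nearest neighbours -------------------------------------------------

#' Fit a k-nearest-neighbours regressor
#'
#' Stores the training matrix; a prediction is the unweighted mean of the
#' responses of the K training rows nearest in (unscaled) Euclidean distance.
#' Ties at the K-th distance are broken by the lowest training-row index.
#'
#' @inheritParams fitMLR
#' @param k number of neighbours, \code{1 <= k <= N}.
#' @return a \code{\linkS4class{LogPModel}}.
#' @export
fitKNN <- function(X, y, k = 5L) {
    X <- checkXy(X, y)
    k <- as.integer(k)
    if (k < 1L || k > nrow(X))
        stop(sprintf("k must lie in 1..N (N = %d)", nrow(X)))
    spec <- modelSpec("knnr", list(k = k))
    newLogPModel(spec, list(X = X, y = as.numeric(y), k = k), featNamesOf(X))
}

knnPredict <- function(fit, Xq) {
    Xt <- fit$X
    ## squared distances, training rows x query rows
    d2 <- outer(rowSums(Xt^2), rep(1, nrow(Xq))) +
        outer(rep(1, nrow(Xt)), rowSums(Xq^2)) - 2 * tcrossprod(Xt, Xq)
    apply(d2, 2L, function(col) {
        nb <- order(col)[seq_len(fit$k)]  # order() is stable: lowest index wins ties
        mean(fit$y[nb])
    })
}

## ---- dispatch -------------------------------------------------------------

#' Fit a model from its specification
#'
#' Dispatches to the fitter for the spec's kind.  The feature matrix must
#' already have the width the spec expects (build it with
#' \code{\link{featurize}} using the spec's \code{extended} flag).
#'
#' @param spec a \code{\linkS4class{ModelSpec}}.
#' @inheritParams fitMLR
#' @return a \code{\linkS4class{LogPModel}}.
#' @export
fitModel <- function(spec, X, y) {
    stopifnot(is(spec, "ModelSpec"))
    p <- spec@params
    model <- switch(spec@kind,
        mlr = fitMLR(X, y),
        ridge = fitRidge(X, y, lambda = p$lambda,
                         standardize = isTRUE(p$standardize),
                         perObservation = isTRUE(p$perObservation)),
        lasso = fitLasso(X, y, lambda = p$lambda,
                         standardize = isTRUE(p$standardize),
                         perObservation = isTRUE(p$perObservation)),
        rfr = fitRandomForest(X, y, spec),
        gbr = fitGBR(X, y, spec),
        knnr = fitKNN(X, y, k = p$k))
    model@spec@extended <- spec@extended
    model@spec@seed <- spec@seed
    model
}

#' Predict LogP values
#'
#' @param object a fitted \code{\linkS4class{LogPModel}}.
#' @param newdata feature matrix whose width matches the model's.
#' @return numeric vector of predictions, one per row.
#' @export
setMethod("predict", "LogPModel", function(object, newdata, ...) {
    X <- as.matrix(newdata)
    M <- length(object@featureNames)
    if (ncol(X) != M)
        stop(sprintf("feature width mismatch: model expects M = %d, got %d",
                     M, ncol(X)))
    fit <- object@fit
    out <- switch(object@spec@kind,
        mlr = ,
        ridge = ,
        lasso = drop(X %*% fit$coefficients) + fit$intercept,
        rfr = unname(stats::predict(fit$forest, X)),
        gbr = {
            b <- gbrBooster(fit)
            stats::predict(b, xgboost::xgb.DMatrix(X, nthread = 1))
        },
        knnr = knnPredict(fit, X))
    as.numeric(out)
})

## ---- metrics --------------------------------------------------------------

#' Regression performance metrics
#'
#' Root mean square error, mean absolute error and the coefficient of
#' determination \eqn{R^2 = 1 - \sum(\hat y - y)^2 / \sum(y - \bar y)^2},
#' with \eqn{\bar y} the mean of the evaluated partition.  RMSE >= MAE for
#' every input (power-mean inequality), and R-squared is 1 exactly when the
#' predictions match the observations.
#'
#' @param y observed responses (length >= 2).
#' @param yhat predicted responses, same length.
#' @return named numeric vector \code{c(rmse, mae, r2)} (log units for the
#'   errors).
#' @export
#' @examples
#' evaluateModel(c(0, 1, 2), c(0, 0, 0))  # rmse sqrt(5/3), mae 1, r2 -1.5
evaluateModel <- function(y, yhat) {
    if (length(y) != length(yhat)) stop("y and yhat must have equal length")
    if (length(y) < 2L) stop("need at least 2 observations")
    if (!all(is.finite(y)) || !all(is.finite(yhat)))
        stop("y and yhat must be finite")
    res <- yhat - y
    c(rmse = sqrt(mean(res^2)), mae = mean(abs(res)),
      r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}
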