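# Six regressors: closed-form oracles, invariants, and cross-checks against
# independent implementations.

test_that("MLR recovers exact linear structure (normal-equations oracle)", {
  toy <- linearToy(n = 80, p = 5, sd = 0, seed = 3)
  m <- fitMLR(toy$X, toy$y)
  # independent oracle: solve the normal equations directly
  Xa <- cbind(1, toy$X)
  betaHat <- solve(crossprod(Xa), crossprod(Xa, toy$y))
  expect_equal(m@fit$intercept, betaHat[1], tolerance = 1e-10)
  expect_equal(m@fit$coefficients, betaHat[-1], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(m@fit$coefficients, toy$beta, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(m@fit$intercept, toy$intercept, tolerance = 1e-8)
})

test_that("MLR handles constant response and the 1-feature exact line", {
  X <- matrix(rnorm(30), 30, 1)
  m <- fitMLR(X, rep(4.2, 30))
  expect_equal(m@fit$coefficients, 0, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(m@fit$intercept, 4.2, tolerance = 1e-10)

  m2 <- fitMLR(cbind(c(1, 2, 3)), c(2, 4, 6))
  expect_equal(m2@fit$coefficients, 2, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(m2@fit$intercept, 0, tolerance = 1e-10)
})

test_that("rank-deficient designs fall back to the minimum-norm solution", {
  toy <- linearToy(n = 50, p = 3, sd = 0, seed = 4)
  X <- cbind(toy$X, dup = toy$X[, 1])    # exact collinearity
  expect_warning(m <- fitMLR(X, toy$y), "minimum-norm")
  # predictions must still reproduce the (noise-free) response
  expect_equal(predict(m, X), toy$y, tolerance = 1e-8)
})

test_that("ridge matches its closed form and shrinks towards zero", {
  # centered 1-feature toy: beta = sum(xy) / (sum(x^2) + lambda)
  x <- c(-1, 0, 1); y <- c(-1, 0, 1)
  m <- fitRidge(cbind(x), y, lambda = 1)
  expect_equal(m@fit$coefficients, 2 / 3, tolerance = 1e-12,
               ignore_attr = TRUE)

  toy <- linearToy(n = 60, p = 4, sd = 0.2, seed = 5)
  m0 <- fitRidge(toy$X, toy$y, lambda = 0)
  mlr <- fitMLR(toy$X, toy$y)
  expect_equal(m0@fit$coefficients, mlr@fit$coefficients, tolerance = 1e-8)
  big <- fitRidge(toy$X, toy$y, lambda = 1e12)
  expect_lt(max(abs(big@fit$coefficients)), 1e-6)
  expect_equal(big@fit$intercept, mean(toy$y), tolerance = 1e-4)
  expect_error(fitRidge(toy$X, toy$y, lambda = -1), ">= 0")
})

test_that("ridge coefficient norm is non-increasing in lambda", {
  toy <- linearToy(n = 60, p = 4, sd = 0.3, seed = 6)
  norms <- vapply(10^seq(-3, 3),
                  function(l) sum(fitRidge(toy$X, toy$y, l)@fit$coefficients^2),
                  numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("ridge agrees with glmnet in the per-observation convention", {
  skip_if_not_installed("glmnet")
  toy <- linearToy(n = 100, p = 5, sd = 0.3, seed = 7)
  # glmnet additionally scales the ridge penalty by the population SD of the
  # response (it standardizes y internally), so its lambda must be multiplied
  # by sd(y) to express the same objective
  sdy <- sqrt(mean((toy$y - mean(toy$y))^2))
  for (lam in c(0.05, 0.5)) {
    mine <- fitRidge(toy$X, toy$y, lambda = lam, standardize = TRUE,
                     perObservation = TRUE)
    g <- glmnet::glmnet(toy$X, toy$y, alpha = 0, lambda = lam * sdy,
                        standardize = TRUE, thresh = 1e-14)
    expect_equal(mine@fit$coefficients, as.numeric(coef(g))[-1],
                 tolerance = 1e-3, ignore_attr = TRUE)
    expect_equal(mine@fit$intercept, as.numeric(coef(g))[1],
                 tolerance = 1e-3)
  }
})

test_that("lasso matches the 1-D soft-threshold closed form", {
  x <- c(-1, 0, 1); y <- c(-1.5, 0, 1.5)
  sxy <- sum(x * y); sxx <- sum(x^2)
  for (lam in c(0.5, 1, 2, 5, 10)) {
    m <- fitLasso(cbind(x), y, lambda = lam)
    expected <- sign(sxy) * max(abs(sxy) - lam / 2, 0) / sxx
    expect_equal(m@fit$coefficients, expected, tolerance = 1e-9,
                 ignore_attr = TRUE, label = sprintf("lambda %.1f", lam))
  }
})

test_that("over-penalized lasso collapses to the intercept-only model", {
  toy <- linearToy(n = 80, p = 5, sd = 0.3, seed = 8)
  m <- fitLasso(toy$X, toy$y, lambda = 1e6)
  expect_true(all(m@fit$coefficients == 0))   # exact zeros, not small values
  expect_equal(m@fit$intercept, mean(toy$y), tolerance = 1e-12)
  metrics <- evaluateModel(toy$y, predict(m, toy$X))
  expect_identical(unname(metrics["r2"]), 0)  # R^2 exactly 0
})

test_that("lasso at lambda 0 matches MLR; sparsity grows with lambda", {
  toy <- linearToy(n = 80, p = 5, sd = 0.3, seed = 9)
  m0 <- fitLasso(toy$X, toy$y, lambda = 0)
  mlr <- fitMLR(toy$X, toy$y)
  expect_equal(m0@fit$coefficients, mlr@fit$coefficients, tolerance = 1e-6)
  nz <- vapply(10^seq(-2, 4),
               function(l) sum(fitLasso(toy$X, toy$y, l)@fit$coefficients != 0),
               numeric(1))
  expect_true(all(diff(nz) <= 0))
  expect_error(fitLasso(toy$X, toy$y, lambda = -0.1), ">= 0")
})

test_that("lasso agrees with glmnet in the per-observation convention", {
  skip_if_not_installed("glmnet")
  toy <- linearToy(n = 100, p = 5, sd = 0.3, seed = 10)
  for (lam in c(0.02, 0.2)) {
    mine <- fitLasso(toy$X, toy$y, lambda = lam, standardize = TRUE,
                     perObservation = TRUE)
    g <- glmnet::glmnet(toy$X, toy$y, alpha = 1, lambda = lam,
                        standardize = TRUE, thresh = 1e-14)
    expect_equal(mine@fit$coefficients, as.numeric(coef(g))[-1],
                 tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("a single unrestricted tree memorizes distinct rows", {
  toy <- linearToy(n = 40, p = 3, sd = 0.5, seed = 11)
  spec <- modelSpec("rfr", list(ntree = 1L, bootstrap = FALSE,
                                nodesize = 1L, mtry = 3L))
  m <- fitRandomForest(toy$X, toy$y, spec)
  expect_equal(unname(evaluateModel(toy$y, predict(m, toy$X))["rmse"]), 0,
               tolerance = 1e-10)
})

test_that("forest predictions stay within the response range and are seeded", {
  toy <- linearToy(n = 60, p = 4, sd = 0.5, seed = 12)
  m <- fitRandomForest(toy$X, toy$y, defaultSpec("rfr", seed = 5))
  Xnew <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, colnames(toy$X)))
  p <- predict(m, Xnew)
  expect_true(all(p >= min(toy$y) & p <= max(toy$y)))
  m2 <- fitRandomForest(toy$X, toy$y, defaultSpec("rfr", seed = 5))
  expect_identical(predict(m2, Xnew), p)
  expect_error(fitRandomForest(toy$X, toy$y,
                               modelSpec("rfr", list(ntree = 0L))), ">= 1")
})

test_that("boosting training RSS is non-increasing in the number of stages", {
  toy <- linearToy(n = 80, p = 4, sd = 0.4, seed = 13)
  rss <- vapply(c(1, 5, 10, 25, 50), function(B) {
    m <- fitGBR(toy$X, toy$y, modelSpec("gbr", list(nrounds = B)))
    sum((toy$y - predict(m, toy$X))^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-8))
  # one shrunken stage moves predictions off the mean towards the data
  m1 <- fitGBR(toy$X, toy$y, modelSpec("gbr", list(nrounds = 1L)))
  expect_lt(sum((toy$y - predict(m1, toy$X))^2),
            sum((toy$y - mean(toy$y))^2))
})

test_that("boosting is deterministic under its seed and validates inputs", {
  toy <- linearToy(n = 50, p = 3, sd = 0.4, seed = 14)
  a <- fitGBR(toy$X, toy$y, defaultSpec("gbr", seed = 3))
  b <- fitGBR(toy$X, toy$y, defaultSpec("gbr", seed = 3))
  expect_identical(predict(a, toy$X), predict(b, toy$X))
  expect_error(fitGBR(toy$X, toy$y, modelSpec("gbr", list(nrounds = 0L))),
               ">= 1")
})

test_that("KNN follows the exhaustive-sort oracle with stable tie-breaks", {
  # hand case: distances (1, 2, 2), K = 2 -> lowest-index neighbour wins tie
  Xtr <- cbind(c(1, 2, 2))
  ytr <- c(0, 3, 5)
  m <- fitKNN(Xtr, ytr, k = 2)
  expect_equal(predict(m, cbind(0)), mean(c(0, 3)))

  toy <- linearToy(n = 50, p = 3, sd = 0.4, seed = 15)
  Xq <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, colnames(toy$X)))
  for (k in c(1, 5, 50)) {
    m <- fitKNN(toy$X, toy$y, k = k)
    expect_equal(predict(m, Xq), knnOracle(toy$X, toy$y, Xq, k),
                 tolerance = 1e-10, label = sprintf("k = %d", k))
  }
  # K = 1 at a training row returns that row's response; K = N the mean
  m1 <- fitKNN(toy$X, toy$y, k = 1)
  expect_equal(predict(m1, toy$X[4, , drop = FALSE]), toy$y[4])
  mN <- fitKNN(toy$X, toy$y, k = nrow(toy$X))
  expect_equal(predict(mN, Xq), rep(mean(toy$y), 10))
  expect_error(fitKNN(toy$X, toy$y, k = 51), "1..N")
})

test_that("predict validates the feature width and dispatches by kind", {
  toy <- linearToy(n = 30, p = 4, sd = 0, seed = 16)
  m <- fitMLR(toy$X, toy$y)
  expect_error(predict(m, toy$X[, 1:3]), "expects M = 4")
  constant <- fitMLR(toy$X, rep(2.5, 30))
  expect_equal(predict(constant, toy$X), rep(2.5, 30), tolerance = 1e-9)
  # every kind returns one finite value per row on its training matrix
  specs <- list(defaultSpec("mlr"), defaultSpec("ridge"),
                defaultSpec("lasso"), defaultSpec("rfr"),
                defaultSpec("gbr"), defaultSpec("knnr"))
  for (s in specs) {
    fit <- fitModel(s, toy$X, toy$y)
    p <- predict(fit, toy$X)
    expect_length(p, 30)
    expect_true(all(is.finite(p)), label = s@kind)
  }
})

test_that("metrics match hand arithmetic and their defining identities", {
  y <- c(0, 1, 2); yhat <- c(0, 0, 0)
  m <- evaluateModel(y, yhat)
  expect_equal(unname(m["rmse"]), sqrt(5 / 3))
  expect_equal(unname(m["mae"]), 1)
  expect_equal(unname(m["r2"]), -1.5)

  perfect <- evaluateModel(y, y)
  expect_equal(unname(perfect), c(0, 0, 1))
  # mean predictor: R^2 exactly 0
  expect_identical(unname(evaluateModel(y, rep(mean(y), 3))["r2"]), 0)
  expect_error(evaluateModel(1:3, 1:4), "equal length")
  expect_error(evaluateModel(1, 1), "at least 2")
})

test_that("RMSE dominates MAE on random vectors; R2 is 1 only at equality", {
  for (seed in 1:20) {
    set.seed(seed)
    y <- rnorm(50); yhat <- y + rnorm(50, sd = runif(1, 0.01, 2))
    m <- evaluateModel(y, yhat)
    expect_gte(m[["rmse"]], m[["mae"]])
    expect_lt(m[["r2"]], 1)
  }
})

test_that("tree-ensemble and KNN models overfit relative to held-out data", {
  d <- simulateLogPDataset(generatorSpec(n = 600, seed = 21))
  ds <- curate(d$records)
  rec <- records(ds)
  X <- featurize(rec$hill, extended = FALSE)
  sp <- splitDataset(nrow(X), 0.8, seed = 2)
  for (kind in c("rfr", "gbr", "knnr")) {
    fit <- fitModel(defaultSpec(kind, seed = 2),
                    X[sp$train, ], rec$logp[sp$train])
    tr <- evaluateModel(rec$logp[sp$train], predict(fit, X[sp$train, ]))
    va <- evaluateModel(rec$logp[sp$heldOut], predict(fit, X[sp$heldOut, ]))
    expect_lt(tr[["rmse"]], va[["rmse"]])
  }
})
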