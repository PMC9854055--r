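# Post-hoc error analysis: functional-group detection, grouped error
# summaries, ranking, and the correlation screen.

test_that("functional groups are detected from SMILES substructures", {
  flags <- detectGroups(c(benzene = "c1ccccc1", ethanol = "CCO",
                          acetone = "CC(=O)C"))
  expect_equal(unname(flags["benzene", ]),
               c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
               ignore_attr = TRUE)
  expect_equal(unname(flags["ethanol", "alcohol"]), 1L)
  expect_equal(unname(flags["ethanol", "aromatic"]), 0L)
  expect_equal(unname(flags["acetone", "carbonyl"]), 1L)
})

test_that("a molecule can carry several flags at once", {
  flags <- detectGroups(c(benzoicAcid = "OC(=O)c1ccccc1",
                          chlorobenzene = "Clc1ccccc1",
                          acetonitrile = "CC#N",
                          butene = "CC=CC"))
  expect_equal(unname(flags["benzoicAcid", c("aromatic", "carbonyl", "alcohol")]),
               c(1L, 1L, 1L))
  expect_equal(unname(flags["chlorobenzene", c("aromatic", "halogenated")]),
               c(1L, 1L))
  expect_equal(unname(flags["acetonitrile", "amine_nitrile"]), 1L)
  expect_equal(unname(flags["butene", "unsaturated_aliphatic"]), 1L)
  expect_equal(unname(flags["butene", "aromatic"]), 0L)
})

test_that("unparseable SMILES error singly and are skipped in batch", {
  expect_error(detectGroups("not a smiles("), "unparseable SMILES")
  expect_warning(flags <- detectGroups(c("CCO", "not a smiles(", "CC=C")),
                 "skipping 1")
  expect_true(all(is.na(flags[2, ])))
  expect_equal(unname(flags[1, "alcohol"]), 1L)
  expect_equal(unname(flags[3, "unsaturated_aliphatic"]), 1L)
})

test_that("group summaries match a brute-force group-by oracle", {
  errors <- c(0.1, 0.4, 0.2, 0.8)
  flags <- rbind(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(0L, 1L))
  colnames(flags) <- c("aromatic", "alcohol")
  out <- groupErrorSummary(errors, flags)
  # oracle: exhaustive recomputation per group
  for (g in colnames(flags)) {
    e <- errors[flags[, g] == 1L]
    row <- out[out$group == g, ]
    expect_equal(row$n, length(e))
    expect_equal(row$mean, mean(e))
    expect_equal(row$median, median(e))
    expect_equal(row$p5, unname(quantile(e, 0.05)))
    expect_equal(row$p95, unname(quantile(e, 0.95)))
  }
  # multi-membership inflates the group totals beyond N
  expect_gte(sum(out$n), length(errors))
})

test_that("uniform errors give every non-empty group the same mean", {
  errors <- rep(0.37, 5)
  flags <- cbind(a = c(1L, 1L, 0L, 1L, 0L), b = c(0L, 1L, 1L, 0L, 0L),
                 empty = integer(5))
  out <- groupErrorSummary(errors, flags)
  expect_equal(out$mean[out$group %in% c("a", "b")], c(0.37, 0.37))
  expect_equal(out$n[out$group == "empty"], 0L)
  expect_true(is.na(out$mean[out$group == "empty"]))
})

test_that("error ranking matches a full sort with stable ties", {
  r <- rankErrors(c(0.1, 0.5, 0.3), k = 1)
  expect_equal(r$best$index, 1L)
  expect_equal(r$worst$index, 2L)

  set.seed(55)
  errors <- round(runif(100), 2)  # rounding forces ties
  r10 <- rankErrors(errors, k = 10)
  expect_equal(r10$best$error, sort(errors)[1:10])
  expect_equal(r10$worst$error, sort(errors, decreasing = TRUE)[1:10])
  # stability: among tied values the earlier index comes first
  expect_true(all(diff(r10$best$index[duplicated(r10$best$error) |
                                      duplicated(r10$best$error, fromLast = TRUE)]) != 0))

  rAll <- rankErrors(errors, k = 100)
  expect_equal(sort(rAll$best$index), 1:100)
  expect_equal(sort(rAll$worst$index), 1:100)
  # best and worst are two views of one global sort
  expect_equal(rAll$best$error, rev(rAll$worst$error))
  expect_error(rankErrors(errors, k = 101), "exceeds")
})

test_that("the correlation screen reports exact relationships", {
  withr::with_seed(66, {
    x1 <- rnorm(200); x2 <- rnorm(200)
  })
  X <- cbind(a = x1, b = x2, c = -x1, const = rep(1, 200))
  out <- correlationScreen(X, x1)   # response equals column a
  cors <- out$correlations
  expect_equal(cors["a", "LogP"], 1)
  expect_equal(cors["c", "LogP"], -1)
  expect_equal(cors, t(cors))
  expect_true(all(diag(cors)[c("a", "b", "c", "LogP")] == 1))
  expect_true(is.na(cors["const", "LogP"]))
  expect_true(is.na(out$ftest$statistic[out$ftest$feature == "const"]))
  expect_true(all(abs(cors[!is.na(cors)]) <= 1))
})

test_that("the F statistic matches its correlation identity", {
  withr::with_seed(67, {
    X <- cbind(u = rnorm(150), v = runif(150))
    y <- 0.8 * X[, "u"] + rnorm(150, sd = 0.5)
  })
  out <- correlationScreen(X, y)
  n <- 150
  for (f in c("u", "v")) {
    r <- out$correlations[f, "LogP"]
    expected <- r^2 * (n - 2) / (1 - r^2)   # univariate regression identity
    got <- out$ftest$statistic[out$ftest$feature == f]
    expect_equal(got, expected, tolerance = 1e-8)
  }
})

test_that("correlations are invariant to affine rescaling of columns", {
  withr::with_seed(68, {
    X <- cbind(a = rnorm(100), b = runif(100))
    y <- X[, "a"] + rnorm(100, sd = 0.3)
  })
  X2 <- cbind(a = 5 * X[, "a"] - 2, b = 0.1 * X[, "b"] + 7)
  expect_equal(correlationScreen(X, y)$correlations,
               correlationScreen(X2, y)$correlations, tolerance = 1e-12)
})

test_that("a planted signal yields the theoretical correlation", {
  withr::with_seed(69, {
    n <- 10000
    x1 <- rnorm(n)               # unit variance
    sigma <- 0.5
    y <- 0.5 * x1 + rnorm(n, sd = sigma)
    X <- cbind(x1 = x1, x2 = rnorm(n))
  })
  out <- correlationScreen(X, y)
  theory <- 0.5 / sqrt(0.25 + 0.5^2)  # population correlation, closed form
  expect_lt(abs(out$correlations["x1", "LogP"] - theory), 0.03)
})
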