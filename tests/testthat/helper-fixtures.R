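# Shared test fixtures, all built in code.

# random valid atom-count vectors (always at least one carbon so every
# derived feature is defined)
randomCounts <- function(seed) {
  withr::with_seed(seed, {
    counts <- stats::setNames(integer(10), logpElements())
    counts["C"] <- sample(1:40, 1)
    counts["H"] <- sample(0:80, 1)
    for (el in c("N", "O", "S", "P", "F", "Cl", "Br", "I"))
      counts[el] <- stats::rbinom(1, 1, 0.3) * sample(0:6, 1)
    counts
  })
}

# small regression toy with known linear signal
linearToy <- function(n = 60, p = 4, sd = 0, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    beta <- seq_len(p) / 2
    y <- drop(X %*% beta) + 1.5 + stats::rnorm(n, sd = sd)
    list(X = X, y = y, beta = beta, intercept = 1.5)
  })
}

# exhaustive KNN regression oracle: full distance sort with stable ties
knnOracle <- function(Xtr, ytr, Xq, k) {
  apply(Xq, 1, function(q) {
    d <- sqrt(colSums((t(Xtr) - q)^2))
    mean(ytr[order(d)[seq_len(k)]])
  })
}
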