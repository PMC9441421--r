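# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use explicit sum formulas / normal equations, not the
# lm/aov/cor code paths the package calls.

pearsonOracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# OLS by explicit normal equations; degree 1 or 2
olsOracle <- function(x, y, degree = 1) {
  X <- if (degree == 1) cbind(1, x) else cbind(1, x, x^2)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# one-way ANOVA F from between/within sums of squares
anovaFOracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); n <- length(values)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# small noiseless single-tensor study: every voxel shares tensor diagonal D
uniformStudy <- function(D, dims = c(6L, 6L, 4L), s0 = 1000, b = 1000) {
  att <- function(Di) array(s0 * exp(-b * Di * 1e-3), dims)
  DiffusionStudy(array(s0, dims), att(D[1]), att(D[2]), att(D[3]), bValue = b)
}

# tiny two-decade cohort table built by hand
tinyCohort <- function(valuesByDecade) {
  ages <- unlist(lapply(seq_along(valuesByDecade), function(i) {
    rep(10 * i + 5, length(valuesByDecade[[i]]))
  }))
  idx <- unlist(valuesByDecade)
  makeCohortTable(sprintf("t%02d", seq_along(idx)), ages, idx, idx)
}
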