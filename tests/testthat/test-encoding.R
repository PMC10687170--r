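# Encoding strength, performance selection, and connectivity.

test_that("encoding strength is the channel-mean |Spearman| with the state", {
  set.seed(2)
  state <- rnorm(40)
  # strictly monotone series on every channel -> strength 1
  mono <- list(exp(state), -3 * state + 7)
  expect_equal(encoding_strength(mono, state), 1)
  # independent series -> near zero
  indep <- planted_series(state, gain = 0, n_channels = 50, seed = 3)
  expect_lt(encoding_strength(indep, state), 0.25)
  expect_gte(encoding_strength(indep, state), 0)
  expect_error(encoding_strength(mono, rep(0, 5)), ">= 10")
  expect_error(encoding_strength(list(rep(1, 40)), state), "constant")
})

test_that("channel magnitudes average arithmetically across channels", {
  # permutations of 1..25 with exact Spearman rho: swapping positions
  # (i, j) in the identity adds 2 (j - i)^2 to the rank-distance sum, and
  # rho = 1 - 6 S / (n (n^2 - 1)) with n = 25 needs S = 520 for rho = 0.8
  # and S = 1560 for rho = 0.4
  n <- 25
  state <- seq_len(n)
  swap <- function(v, i, j) { v[c(i, j)] <- v[c(j, i)]; v }
  ch1 <- swap(swap(state, 1, 15), 2, 10)          # 2(196 + 64) = 520
  ch2 <- swap(swap(swap(swap(state, 1, 25), 2, 16), 3, 5), 4, 6)  # 1560
  expect_equal(cor(ch1, state, method = "spearman"), 0.8)
  expect_equal(cor(ch2, state, method = "spearman"), 0.4)
  s <- encoding_strength(list(ch1, -ch2), state)  # sign must not matter
  expect_equal(s, 0.6, tolerance = 1e-9)
})

test_that("performance selection applies thresholds and representation", {
  perf <- c(30, 40, 48, 55, 62, 70)
  # strengths perfectly ordered with performance -> r = 1, selected
  sel <- select_performance_regions(perf / 100, perf,
                                    mean_performance = 51)
  expect_equal(sel$performance_r, 1, tolerance = 1e-12)
  expect_true(sel$selected)
  # all subjects above the cohort average -> rejected regardless of r
  sel2 <- select_performance_regions(perf / 100, perf,
                                     mean_performance = 20)
  expect_false(sel2$selected)
  expect_false(sel2$represented)
  # |r| matters, not sign: perfectly anti-ordered is still selected
  sel3 <- select_performance_regions(rev(perf) / 100, perf,
                                     mean_performance = 51)
  expect_true(sel3$selected)
  expect_error(select_performance_regions(c(0.1, 0.2), c(40, 60)), ">= 3")
})

test_that("channel connectivity is symmetric-in-magnitude and aligned", {
  set.seed(6)
  a <- lapply(1:3, function(i) rnorm(30))
  m <- channel_connectivity(a, a)
  expect_equal(diag(m), rep(1, 3), tolerance = 1e-12)
  expect_true(all(m >= 0 & m <= 1))
  # an anti-correlated copy still has magnitude 1
  m2 <- channel_connectivity(a, lapply(a, function(v) -v))
  expect_equal(diag(m2), rep(1, 3), tolerance = 1e-12)
  expect_error(channel_connectivity(a, list(rnorm(10))), "mismatch")
})

test_that("subject connectivity averages the declared pair set", {
  m <- matrix(c(0.8, 0.4, 0.6, 0.2), 2, 2)
  expect_equal(subject_connectivity(m), 0.5)   # cross-region: all entries
  # within-region: unique off-diagonal pairs only
  mw <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  expect_equal(subject_connectivity(mw, same_region = TRUE), 0.3)
  # naive-loop oracle on a random cross-region matrix
  set.seed(7)
  r <- matrix(runif(12), 3, 4)
  acc <- 0
  for (i in 1:3) for (j in 1:4) acc <- acc + r[i, j]
  expect_equal(subject_connectivity(r), acc / 12, tolerance = 1e-12)
})

test_that("performance connectivity stores r and truncates graph export", {
  perf <- c(35, 45, 52, 60, 68)
  res <- performance_connectivity(perf / 100, perf)
  expect_equal(res$performance_r, 1, tolerance = 1e-12)
  expect_true(res$exported)
  # weakly related strengths: stored but not exported (r <= 0.5)
  set.seed(8)
  s_weak <- c(0.52, 0.48, 0.55, 0.47, 0.50)
  res2 <- performance_connectivity(s_weak, perf)
  expect_true(res2$evaluable)
  expect_false(res2$exported)
  expect_lt(res2$performance_r, 0.5)
  # anti-ordered: r = -1, stored, excluded from the positive-edge graph
  res3 <- performance_connectivity((100 - perf) / 100, perf)
  expect_equal(res3$performance_r, -1, tolerance = 1e-12)
  expect_false(res3$exported)
  # too few subjects or one-sided cohorts are non-evaluable, not dropped
  res4 <- performance_connectivity(c(0.5, 0.6), c(40, 60))
  expect_false(res4$evaluable)
  res5 <- performance_connectivity(c(0.5, 0.6, 0.7), c(60, 65, 70),
                                   mean_performance = 51)
  expect_false(res5$evaluable)
})

test_that("population connectivity Fisher-averages within subject bounds", {
  expect_equal(population_connectivity(c(0.5, 0.5)), 0.5, tolerance = 1e-12)
  expect_equal(population_connectivity(c(0, 0.9)),
               tanh((atanh(0) + atanh(0.9)) / 2), tolerance = 1e-12)
  for (r in c(0, 0.3, 0.99)) expect_equal(tanh(atanh(r)), r,
                                          tolerance = 1e-12)
  # result lies between the min and max subject strengths
  set.seed(9)
  for (i in 1:20) {
    s <- runif(5)
    p <- population_connectivity(s)
    expect_gte(p, min(s) - 1e-12)
    expect_lte(p, max(s) + 1e-12)
  }
  # perfect correlations are clamped, not infinite
  expect_lt(population_connectivity(c(1, 1)), 1)
  expect_error(population_connectivity(0.7), ">= 2")
})

test_that("trial power series average masked pixels across epochs", {
  arr1 <- array(1, dim = c(5, 2, 3))
  arr2 <- array(3, dim = c(5, 2, 3))
  mask <- matrix(c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE), 2, 3)
  s <- trial_power_series(list(arr1, arr2), mask)
  expect_equal(s, rep(2, 5))
  # oracle on random data, single epoch
  set.seed(10)
  arr <- array(rnorm(5 * 2 * 3), dim = c(5, 2, 3))
  s2 <- trial_power_series(list(arr), mask)
  oracle <- sapply(1:5, function(tr) mean(arr[tr, , ][mask]))
  expect_equal(s2, oracle, tolerance = 1e-12)
})
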