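# Calibration and contract checks for the node-level score tests.

test_that("treatment-association p-values are uniform under the null", {
  set.seed(41)
  n <- 200
  tr <- rep(0:1, each = n / 2)
  M <- matrix(rnorm(n * 2000), n)            # mediators independent of T
  p <- apply(M, 2, function(m) test_alpha(m, tr)$p)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("outcome-association p-values are uniform under beta = 0", {
  set.seed(42)
  n <- 200
  tr <- rep(0:1, each = n / 2)
  y <- 0.5 * tr + rnorm(n)                   # outcome unrelated to mediator
  M <- matrix(rnorm(n * 2000), n) + tr       # mediator may depend on T
  p <- apply(M, 2, function(m) test_beta(m, tr, y)$p)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("perfect associations give vanishing p-values", {
  n <- 200
  tr <- rep(0:1, each = n / 2)
  expect_lt(test_alpha(tr + 0.001 * rnorm(n), tr)$p, 1e-6)
  set.seed(1)
  m <- rnorm(n)
  expect_lt(test_beta(m, tr, m, outcome_type = "continuous")$p, 1e-6)
})

test_that("score test p agrees with the Wald test on continuous outcomes", {
  set.seed(43)
  n <- 200
  tr <- rep(0:1, each = n / 2)
  x <- rnorm(n)
  for (i in 1:20) {
    m <- 0.2 * tr + 0.3 * x + rnorm(n)
    p_score <- test_alpha(m, tr, covariates = cbind(x))$p
    p_wald <- summary(lm(m ~ x + tr))$coefficients["tr", 4]
    expect_lt(abs(p_score - p_wald), 0.01)
  }
})

test_that("permutation p-values follow (b + 1) / (B + 1) and match asymptotics", {
  set.seed(44)
  n <- 200
  tr <- rep(0:1, each = n / 2)
  for (i in 1:10) {
    m <- 0.15 * tr + rnorm(n)
    a_asym <- test_alpha(m, tr)$p
    a_perm <- test_alpha(m, tr, method = "permutation", seed = i)
    expect_equal(a_perm$p, (a_perm$b + 1) / (a_perm$B + 1))
    tol <- 3 * sqrt(a_asym * (1 - a_asym) / a_perm$B)
    expect_lt(abs(a_perm$p - a_asym), tol + 0.02)
  }
  # b = B (statistic never exceeded) caps the p-value at 1
  expect_lte(test_alpha(rnorm(n), tr, method = "permutation", seed = 3)$p, 1)
})

test_that("permutation handles a separated binary outcome gracefully", {
  set.seed(45)
  n <- 100
  tr <- rep(0:1, each = n / 2)
  m <- rnorm(n)
  y <- as.numeric(m > 0)                     # complete separation on mediator
  res <- test_beta(m, tr, y, outcome_type = "binary",
                   method = "permutation", seed = 9)
  expect_true(res$p > 0 && res$p <= 1)
})

test_that("degenerate designs are refused", {
  n <- 50
  expect_error(test_alpha(rnorm(n), rep(1, n)), "degenerate")
  expect_error(test_alpha(rep(0.3, n), rep(0:1, each = 25)), "degenerate")
})

test_that("Sobel and joint-significance comparators follow their formulas", {
  expect_equal(joint_significance_test(0.01, 0.04), 0.04)
  expect_equal(sobel_test(0, 1, 0, 1), 1)     # z = 0 -> p = 1
  z <- 0.5 * 0.4 / sqrt(0.5^2 * 0.1^2 + 0.4^2 * 0.2^2)
  expect_equal(sobel_test(0.5, 0.2, 0.4, 0.1),
               2 * pnorm(abs(z), lower.tail = FALSE))
  expect_error(sobel_test(1, 0, 1, 1), "positive")
})

test_that("Sobel and joint-significance tests are superuniform under the full null", {
  set.seed(46)
  n <- 200
  tr <- rep(0:1, each = n / 2)
  p_sob <- p_js <- numeric(400)
  for (i in seq_along(p_sob)) {
    m <- rnorm(n)
    y <- rnorm(n)
    fa <- summary(lm(m ~ tr))$coefficients
    fb <- summary(lm(y ~ tr + m))$coefficients
    p_sob[i] <- sobel_test(fa["tr", 1], fa["tr", 2], fb["m", 1], fb["m", 2])
    p_js[i] <- joint_significance_test(fa["tr", 4], fb["m", 4])
  }
  # stochastically larger than uniform: deficit of small values, high mean
  expect_lt(mean(p_sob <= 0.05), 0.05)
  expect_lt(mean(p_js <= 0.05), 0.05)
  expect_gt(mean(p_sob), 0.55)
  expect_gt(mean(p_js), 0.55)
})
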