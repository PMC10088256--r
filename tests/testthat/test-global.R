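# Harmonic-mean combination, its Landau null distribution, and BH selection.

test_that("harmonic mean of equal p-values is the common value", {
  res <- hmp_combine(rep(0.05, 30))
  expect_equal(res$p_ring, 0.05)
  res_w <- hmp_combine(rep(0.05, 4), weights = c(0.4, 0.3, 0.2, 0.1))
  expect_equal(res_w$p_ring, 0.05)
})

test_that("worked harmonic-mean examples", {
  expect_equal(hmp_combine(c(0.01, 1))$p_ring, 1 / 50.5)
  res1 <- hmp_combine(0.037)
  expect_equal(res1$p_ring, 0.037)
  expect_equal(res1$global_p, 0.037)   # single test is exact
})

test_that("Landau tail matches an independent stable-law implementation", {
  # reference values computed with an independent stable-distribution
  # library (alpha = 1, beta = 1, scale pi/2)
  ref <- data.frame(
    x = c(-2, 0, 1, 5, 20, 100),
    sf = c(0.95490621, 0.63476130, 0.48771940,
           0.21039852, 0.05521116, 0.01038060))
  mine <- treemed:::.plandau_upper(ref$x + log(pi / 2))
  expect_equal(mine, ref$sf, tolerance = 1e-7)
  # asymptotic-series regime joins the quadrature regime smoothly
  lo <- treemed:::.plandau_upper(299.99)
  hi <- treemed:::.plandau_upper(300.01)
  expect_lt(abs(lo - hi) / lo, 1e-4)
})

test_that("the combined test is calibrated for independent uniform p-values", {
  set.seed(21)
  gp <- replicate(2000, hmp_combine(runif(99))$global_p)
  expect_lt(abs(mean(gp <= 0.05) - 0.05), 0.02)
  expect_gt(stats::ks.test(gp, "punif")$p.value, 0.01)
})

test_that("combination is order-invariant and monotone", {
  set.seed(22)
  p <- runif(50)
  expect_equal(hmp_combine(p)$global_p, hmp_combine(rev(p))$global_p)
  p2 <- p; p2[7] <- p2[7] / 10
  expect_lte(hmp_combine(p2)$global_p, hmp_combine(p)$global_p)
  expect_lte(hmp_combine(p)$global_p, 1)
  expect_warning(res <- hmp_combine(c(0, 0.5)), "clamped")
  expect_gt(res$global_p, 0)
})

test_that("Fisher combination matches the chi-square reference", {
  p <- c(0.1, 0.2, 0.7)
  res <- fisher_combine(p)
  expect_equal(res$stat, -2 * sum(log(p)))
  expect_equal(res$global_p, pchisq(res$stat, 6, lower.tail = FALSE))
})

test_that("BH selection follows the step-up rule", {
  sel <- bh_select(c(0.01, 0.02, 0.04, 0.5), q = 0.1)
  expect_equal(sel$selected, 1:3)
  expect_equal(bh_select(rep(1, 10), q = 0.1)$selected, integer(0))
  # a Bonferroni-significant p is always BH-selected
  p <- c(runif(19, 0.2, 1), 0.05 / 40)
  expect_true(20 %in% bh_select(p, q = 0.05)$selected)
})
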