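# The composite-null engine: null-proportion estimation, mixture weights,
# Grenander power functions, and the mixture p-value.

test_that("null proportion estimate is consistent under the pure null", {
  set.seed(11)
  z <- rnorm(2000)
  p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  est <- estimate_pi0(p, signs = sign(z))
  expect_lt(abs(est - 1), 0.05)
})

test_that("null proportion estimate recovers a half-null mixture", {
  set.seed(12)
  z <- c(rnorm(1000), rnorm(1000, mean = 3))
  p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  est <- estimate_pi0(p, signs = sign(z))
  expect_lt(abs(est - 0.5), 0.10)
})

test_that("estimator equals an independent quadrature of the functional", {
  set.seed(13)
  z <- c(rnorm(500), rnorm(100, 2.5))
  p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  mine <- estimate_pi0(p, signs = sign(z))
  oracle <- pi0_oracle(sign(z) * qnorm(1 - pmin(pmax(p, 1e-15), 1 - 1e-15) / 2))
  expect_lt(abs(mine - oracle), 1e-6)
  # one-sided conversion path agrees with its own oracle too
  mine1 <- estimate_pi0(p)
  oracle1 <- pi0_oracle(qnorm(1 - pmin(pmax(p, 1e-15), 1 - 1e-15)))
  expect_lt(abs(mine1 - oracle1), 1e-6)
})

test_that("estimates never exceed 1 and fall back for tiny inputs", {
  set.seed(14)
  p <- runif(50)
  expect_lte(estimate_pi0(p), 1)
  expect_warning(est <- estimate_pi0(runif(5)), "fewer than 20")
  expect_equal(est, 1)
})

test_that("mixture weights follow the product formulas", {
  nm <- combine_null_proportions(1, 1)
  expect_equal(c(nm$pi00, nm$pi10, nm$pi01), c(1, 0, 0))
  nm <- combine_null_proportions(0.8, 0.9)
  expect_equal(nm$pi0, 0.98)
  expect_equal(nm$pi00, 0.72 / 0.98)
  expect_equal(nm$pi10, 0.18 / 0.98)
  expect_equal(nm$pi01, 0.08 / 0.98)
  expect_equal(nm$pi00 + nm$pi10 + nm$pi01, 1)
})

test_that("maxp weights agree with product when pi0 matches algebraically", {
  a <- 0.85; b <- 0.7
  pi0 <- a + b - a * b
  nm_prod <- combine_null_proportions(a, b, approach = "product")
  nm_maxp <- combine_null_proportions(a, b, pi0_max = pi0, approach = "maxp")
  expect_equal(nm_prod$pi00, nm_maxp$pi00)
  expect_equal(nm_prod$pi10, nm_maxp$pi10)
  expect_equal(nm_prod$pi01, nm_maxp$pi01)
  # negative components are clamped and renormalised
  nm_neg <- combine_null_proportions(0.9, 0.95, pi0_max = 0.5,
                                     approach = "maxp")
  expect_gte(nm_neg$pi10, 0)
  expect_equal(nm_neg$pi00 + nm_neg$pi10 + nm_neg$pi01, 1)
})

test_that("Grenander slopes equal the brute-force concave majorant", {
  gren <- grenander_density(c(0.1, 0.4, 0.5, 0.9))
  oracle <- lcm_oracle(c(0.1, 0.4, 0.5, 0.9))
  expect_equal(gren$knots, oracle$knots)
  expect_equal(gren$slopes, oracle$slopes)
  set.seed(15)
  for (i in 1:10) {
    p <- round(runif(sample(4:10, 1)), 3)
    p[p == 0] <- 0.5
    gren <- grenander_density(p)
    oracle <- lcm_oracle(p)
    expect_equal(gren$knots, oracle$knots)
    expect_equal(gren$slopes, oracle$slopes)
  }
})

test_that("Grenander density is decreasing and integrates to one", {
  set.seed(16)
  p <- rbeta(300, 0.3, 1)
  gren <- grenander_density(p)
  expect_true(all(diff(gren$slopes) <= 1e-9))
  expect_equal(sum(gren$slopes * diff(gren$knots)), 1)
})

test_that("flat p-value grids give a flat conditional density", {
  J <- 100
  p <- (1:J) / J
  gren <- grenander_density(p)
  expect_equal(unique(round(gren$slopes, 10)), 1)
  nm <- combine_null_proportions(0.8, 0.9)
  f <- grenander_alt_cdf(p, nm, "alpha")
  # density 1 everywhere: conditional alt CDF reduces to the uniform CDF
  expect_equal(f(0.3), 0.3, tolerance = 1e-6)
})

test_that("alternative-enriched samples concentrate the estimated CDF near 0", {
  set.seed(17)
  p <- c(rbeta(500, 0.1, 1), runif(500))
  nm <- combine_null_proportions(0.5, 0.9)
  f <- grenander_alt_cdf(p, nm, "alpha")   # pi_alt = pi10 = 0.45/0.95
  expect_gt(f(0.05), 0.5)
  expect_equal(f(1), 1)
  expect_equal(f(0), 0)
})

test_that("mixture p-value reproduces its closed-form limits", {
  nm00 <- combine_null_proportions(1, 1)
  expect_equal(mixture_pvalue(0.2, nm00, 1, 1), 0.04)
  nm10 <- combine_null_proportions(0, 1)    # all alpha alternative
  expect_equal(c(nm10$pi00, nm10$pi10, nm10$pi01), c(0, 1, 0))
  expect_equal(mixture_pvalue(0.2, nm10, 1, 1), 0.2)
  nm <- structure(list(pi00 = 0.5, pi10 = 0.3, pi01 = 0.2),
                  class = "null_mix")
  expect_equal(mixture_pvalue(0.1, nm, 1, 1), 0.055)
})

test_that("mixture p-values never exceed the max-p statistic", {
  set.seed(18)
  for (i in 1:20) {
    pa <- runif(99); pb <- runif(99)
    cs <- treemed:::.composite_stage(pa, pb, sample(c(-1, 1), 99, TRUE),
                                     sample(c(-1, 1), 99, TRUE))
    expect_true(all(cs$p_mediation <= cs$p_max + 1e-12))
    expect_true(all(cs$p_mediation >= cs$null_mix$pi00 * cs$p_max^2 - 1e-12))
    expect_equal(cs$null_mix$pi00 + cs$null_mix$pi10 + cs$null_mix$pi01, 1)
  }
})

test_that("product and maxp approaches give similar mixtures on null data", {
  set.seed(19)
  pa <- runif(99); pb <- runif(99)
  sa <- sample(c(-1, 1), 99, TRUE); sb <- sample(c(-1, 1), 99, TRUE)
  cs_p <- treemed:::.composite_stage(pa, pb, sa, sb, approach = "product")
  cs_m <- treemed:::.composite_stage(pa, pb, sa, sb, approach = "maxp")
  expect_lt(abs(cs_p$null_mix$pi00 - cs_m$null_mix$pi00), 0.15)
  expect_lt(abs(cs_p$null_mix$pi10 - cs_m$null_mix$pi10), 0.15)
  expect_lt(abs(cs_p$null_mix$pi01 - cs_m$null_mix$pi01), 0.15)
})
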