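test_that("t test adapter handles both variants and degenerate input", {
  expect_identical(tTwoSample(c(1, 1, 1), c(1, 1, 1))$p_value, 1)
  expect_identical(tTwoSample(c(1, 1, 1), c(1, 1, 1))$statistic, 0)

  a <- c(1, 2, 3)
  big <- tTwoSample(a, a + 50, "pooled")
  expect_lt(big$p_value, 0.01)
  expect_identical(big$df, 4)

  # agreement with the exhaustive permutation oracle (pooled variant)
  set.seed(30)
  for (k in 1:5) {
    x <- rnorm(6); y <- rnorm(6, 0.5)
    pt <- tTwoSample(x, y, "pooled")$p_value
    pp <- oraclePermutationT(x, y, "pooled")
    expect_lt(abs(pt - pp), 0.12)
  }
})

test_that("Bonferroni alpha divides the family alpha", {
  expect_identical(bonferroniAlpha(1), 0.05)
  expect_equal(bonferroniAlpha(9), 0.00556, tolerance = 1e-3)
  expect_equal(round(bonferroniAlpha(9), 3), 0.006)
  expect_equal(bonferroniAlpha(7), 0.05 / 7)
  expect_error(bonferroniAlpha(0), "positive")
})

test_that("KS statistic equals the ECDF supremum oracle on tied integers", {
  expect_identical(ksTwoSample(1:5, 1:5)$statistic, 0)
  expect_identical(ksTwoSample(c(0, 0, 1), c(5, 6))$statistic, 1)

  set.seed(31)
  for (k in 1:60) {
    a <- sample(0:3, sample(2:6, 1), replace = TRUE)
    b <- sample(0:3, sample(2:6, 1), replace = TRUE)
    expect_equal(ksTwoSample(a, b)$statistic, oracleKsStatistic(a, b))
  }

  # invariance under a strictly monotone transform of both samples
  a <- c(0, 1, 1, 2, 4); b <- c(1, 2, 2, 3)
  f <- function(x) exp(x) + x
  expect_identical(ksTwoSample(a, b)$statistic,
                   ksTwoSample(f(a), f(b))$statistic)

  # tie-free agreement with the reference implementation
  set.seed(32)
  x <- rnorm(60); y <- rnorm(50, 0.4)
  ours <- ksTwoSample(x, y)
  ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 0.01)

  # exact permutation p on a small tied sample is a valid p in [0, 1]
  pe <- ksTwoSample(c(0, 0, 1), c(1, 1, 1), exact = "always")
  expect_gte(pe$p_value, 0); expect_lte(pe$p_value, 1)
  expect_match(pe$method, "exact")
})

test_that("categorical OLS matches the normal equations", {
  d4 <- data.frame(y = c(1, 3, 2, 7),
                   g = c("a", "a", "b", "b"),
                   h = c("u", "v", "u", "v"))
  fit <- olsCategorical(d4, "y", c("g", "h"))
  X <- cbind(1, c(0, 0, 1, 1), c(0, 1, 0, 1))
  beta <- oracleOlsSolve(X, d4$y)
  expect_equal(fit$coefficients$estimate, as.numeric(beta),
               tolerance = 1e-10)
  expect_identical(fit$n_observations, 4L)

  # residuals orthogonal to every design column
  r <- residuals(fit$fit)
  expect_lt(max(abs(t(X) %*% r)), 1e-10)

  # constant response: no effects, nothing explained
  dc <- data.frame(y = rep(2, 6), g = rep(c("a", "b"), 3),
                   h = rep(c("u", "v", "w"), 2))
  fc <- suppressWarnings(olsCategorical(dc, "y", c("g", "h")))
  expect_equal(fc$coefficients$estimate[-1], rep(0, 3), tolerance = 1e-12)
  expect_identical(fc$r_squared, 0)

  # noiseless known effects recovered exactly
  g <- rep(c("a", "b"), each = 6); h <- rep(c("u", "v", "w"), 4)
  yy <- 1 + 2 * (g == "b") + 0.5 * (h == "v") - 1 * (h == "w")
  fe <- suppressWarnings(  # interpolating design: exact fit expected
    olsCategorical(data.frame(y = yy, g = g, h = h), "y", c("g", "h")))
  expect_equal(fe$coefficients$estimate, c(1, 2, 0.5, -1),
               tolerance = 1e-10)

  dr <- data.frame(y = rnorm(4), g = c("a", "a", "b", "b"),
                   h = c("u", "u", "v", "v"))  # g aliases h
  expect_error(olsCategorical(dr, "y", c("g", "h")), "rank-deficient")
})

test_that("two-way ANOVA is calibrated under the null and SS types agree", {
  set.seed(33)
  pvals <- replicate(300, {
    d <- data.frame(y = rnorm(24), A = rep(c("x", "y"), each = 12),
                    B = rep(c("p", "q", "r"), 8))
    anovaTwoWay(d, "y", "A", "B")$p[1]
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)

  d <- data.frame(y = rnorm(24), A = rep(c("x", "y"), each = 12),
                  B = rep(c("p", "q", "r"), 8))
  t1 <- anovaTwoWay(d, "y", "A", "B", type = "I")
  t2 <- anovaTwoWay(d, "y", "A", "B", type = "II")
  t3 <- anovaTwoWay(d, "y", "A", "B", type = "III")
  expect_equal(t1$F, t2$F, tolerance = 1e-9)   # balanced: all types agree
  expect_equal(t2$F, t3$F, tolerance = 1e-9)

  # injected main effect of A only
  set.seed(34)
  d$y <- rnorm(24) + 3 * (d$A == "y")
  res <- anovaTwoWay(d, "y", "A", "B")
  expect_lt(res$p[res$term == "A"], 0.001)
  expect_gt(res$p[res$term == "B"], 0.001)

  dEmpty <- d[!(d$A == "x" & d$B == "p"), ]
  expect_error(anovaTwoWay(dEmpty, "y", "A", "B"), "empty design cells")
})
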