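test_that("group centring removes group means and is idempotent", {
  expect_equal(group_centre(c(1, 2, 3), rep("a", 3)), c(-1, 0, 1))
  expect_equal(group_centre(c(10, 20, 5), c("a", "a", "b")), c(-5, 5, 0))
  x <- c(-1, 0, 1, -2, 2)
  g <- c("a", "a", "a", "b", "b")
  expect_equal(group_centre(group_centre(x, g), g), group_centre(x, g))
  expect_error(group_centre(numeric(0), character(0)))
})

test_that("residualization is orthogonal to predictors and the intercept", {
  # exact linear response leaves zero residuals
  x <- 1:20
  expect_equal(residualize(3 + 2 * x, data.frame(x = x)), rep(0, 20),
               tolerance = 1e-10)

  # response orthogonal to x: residuals are just the centred response
  x <- rep(c(-1, 1), 10)
  y <- rep(c(1, 1, -1, -1), 5) + 5       # sample cor(x, y) = 0
  expect_equal(residualize(y, data.frame(x = x)), y - mean(y),
               tolerance = 1e-10)

  # matches the closed-form normal-equations fit on a hand-computable fixture
  x <- c(0, 1, 2, 3, 4)
  y <- c(1, 3, 2, 5, 4)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(residualize(y, data.frame(x = x)),
               y - (mean(y) + beta * (x - mean(x))), tolerance = 1e-12)
  r <- residualize(y, data.frame(x = x))
  expect_equal(sum(r), 0, tolerance = 1e-12)
  expect_equal(sum(r * x), 0, tolerance = 1e-12)

  expect_error(residualize(y, data.frame(a = x, b = 2 * x)), "rank deficient")
})

test_that("variance inflation factors follow 1 / (1 - R^2)", {
  # orthogonal covariates: VIF = 1
  x1 <- rep(c(-1, 1), 8)
  x2 <- rep(c(-1, -1, 1, 1), 4)
  expect_equal(unname(vif(data.frame(x1, x2))), c(1, 1), tolerance = 1e-10)

  # constructed sample correlation 0.6: VIF = 1 / (1 - 0.36) = 1.5625
  z <- rep(c(-1, 1, 1, -1), 4)            # orthogonal to x1, same norm
  y <- 0.6 * x1 + 0.8 * z
  expect_equal(unname(vif(data.frame(x1, y))), c(1.5625, 1.5625),
               tolerance = 1e-9)

  expect_error(vif(data.frame(x1, x1b = x1)), "collinearity")
})

test_that("permutation F-test detects strong effects and bounds p", {
  set.seed(60)
  x <- rnorm(60)
  y <- 3 * x + rnorm(60)
  res <- permutation_lm(y ~ x, data.frame(x = x, y = y),
                        n_perm = 2000, seed = 4)
  expect_lte(res$table$p_perm[1], 0.001)
  expect_equal(res$table$p_perm[1], 1 / 2001)  # minimal attainable p
  expect_error(permutation_lm(y ~ x, data.frame(x = x, y = y), n_perm = 0),
               "n_perm")
})

test_that("permutation p-values track the classical F-test under Gaussian errors", {
  set.seed(61)
  n <- 50
  d <- data.frame(x = rnorm(n), g = factor(rep(c("a", "b"), n / 2)))
  d$y <- 0.35 * d$x + rnorm(n)            # moderate effect
  res <- permutation_lm(y ~ g + x, d, n_perm = 4000, seed = 9)
  classical <- anova(stats::lm(y ~ g + x, d))
  for (i in 1:2) {
    p_cl <- classical[["Pr(>F)"]][i]
    mc_se <- sqrt(p_cl * (1 - p_cl) / 4000)
    expect_lt(abs(res$table$p_perm[i] - p_cl), 4 * mc_se + 1e-3)
  }
  # observed F equals the classical sequential F
  expect_equal(res$table$F, classical$`F value`[1:2], tolerance = 1e-9)
})

test_that("permutation p is stable across seeds", {
  set.seed(62)
  n <- 40
  d <- data.frame(x = rnorm(n))
  d$y <- 0.3 * d$x + rnorm(n)
  p1 <- permutation_lm(y ~ x, d, n_perm = 2000, seed = 1)$table$p_perm
  p2 <- permutation_lm(y ~ x, d, n_perm = 2000, seed = 2)$table$p_perm
  se <- sqrt(max(p1, 1 / 2001) * (1 - max(p1, 1 / 2001)) / 2000)
  expect_lt(abs(p1 - p2), 3 * se + 2 / 2001)
})

test_that("slope-vs-one t-test reproduces printed comparisons", {
  flat <- slope_vs_one_test(1, 0.06, 71)
  expect_equal(flat$t, 0)
  expect_equal(flat$p, 1)

  # strongly shallow carry-over slope
  st <- slope_vs_one_test(0.41, 0.06, 71)
  expect_equal(st$t, -9.83, tolerance = 0.001)
  expect_lt(st$p, 0.001)

  # slope indistinguishable from full transmission
  nd <- slope_vs_one_test(0.73, 0.17, 48)
  expect_equal(nd$t, -1.59, tolerance = 0.002)
  expect_equal(nd$p, 0.12, tolerance = 0.02)

  expect_error(slope_vs_one_test(0.5, 0, 10), "positive")
})
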