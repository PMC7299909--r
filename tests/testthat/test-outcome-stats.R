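test_that("trend contrast and Bonferroni arithmetic are exact", {
  stage <- rep(0:2, each = 10)
  outcome <- rep(c(10, 8, 6), each = 10)       # exact group means, no noise
  a <- suppressWarnings(ancova_compare(outcome, stage))
  expect_equal(unname(a$adjusted_means), c(10, 8, 6))
  expect_equal(a$trend$estimate, -4)           # (-1, 0, +1) contrast
  expect_equal(a$pairwise$p_corrected, pmin(1, 3 * a$pairwise$p_raw))
  expect_true(all(a$pairwise$p_corrected >= a$pairwise$p_raw))
  expect_true(all(a$pairwise$p_corrected <= 1))
})

test_that("ANCOVA trend p matches a from-scratch contrast computation", {
  set.seed(41)
  n <- 90
  stage <- rep(0:2, each = n / 3)
  covs <- data.frame(age = rnorm(n, 70, 8), sex = rbinom(n, 1, 0.5))
  y <- 20 - 1.5 * stage + 0.1 * covs$age + rnorm(n)
  a <- ancova_compare(y, stage, covs)
  # oracle: same lm, contrast L = c' mu with variance c' V c by hand
  fit <- lm(y ~ factor(stage) + age + sex, data = covs)
  cw <- c(-1, 0, 1)
  L <- rbind(c(1, 0, 0, mean(covs$age), mean(covs$sex)),
             c(1, 1, 0, mean(covs$age), mean(covs$sex)),
             c(1, 0, 1, mean(covs$age), mean(covs$sex)))
  est <- drop(cw %*% L %*% coef(fit))
  se <- sqrt(drop(t(cw) %*% L %*% vcov(fit) %*% t(L) %*% cw))
  p <- 2 * pt(-abs(est / se), df = fit$df.residual)
  expect_equal(a$trend$estimate, est, tolerance = 1e-10)
  expect_equal(a$trend$se, se, tolerance = 1e-10)
  expect_equal(a$trend$p, p, tolerance = 1e-10)
  expect_error(ancova_compare(y[stage > 0], stage[stage > 0]), "stage")
})

test_that("pRCTU regression recovers known slopes", {
  x <- seq(1, 3, length.out = 120)
  # exact fit by construction; lm warns that the summary may be unreliable
  r <- suppressWarnings(prctu_regression(2 * x, x))
  expect_equal(r$B, 2, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
  set.seed(42)
  n <- 300
  xr <- runif(n, 1, 3)
  y <- -0.7 * xr + rnorm(n, 0, 0.5)
  rr <- prctu_regression(y, xr)
  expect_lt(abs(rr$B + 0.7), 3 * rr$se)
  expect_lte(rr$adj_r_squared, rr$r_squared)
  stage <- rep(c(0, 1, 2), length.out = n)
  expect_error(prctu_regression(y, rep(1.5, n)), "constant")
  expect_error(prctu_regression(y, xr, subset = "positive_only"), "stage")
})

test_that("mediation obeys the OLS decomposition and verdict rules", {
  set.seed(43)
  n <- 300
  x <- sample(0:2, n, TRUE, prob = c(0.374, 0.104, 0.522))
  covs <- data.frame(age = rnorm(n, 70, 9))
  m <- 1 + 0.6 * x + rnorm(n, 0, 0.4)
  y_complete <- 5 - 0.7 * m + 0.02 * covs$age + rnorm(n, 0, 0.5)
  med <- mediation_path(x, m, y_complete, covs, n_boot = 500)
  expect_lt(abs(med$c_total - (med$c_prime + med$indirect)), 1e-10)
  expect_equal(med$verdict, "complete")
  # standardized coefficients are invariant to affine rescaling of M and Y
  med2 <- mediation_path(x, 10 * m + 3, 100 * y_complete - 7, covs,
                         n_boot = 500)
  expect_equal(med2$standardized, med$standardized, tolerance = 1e-10)

  y_partial <- 5 - 0.7 * m - 0.5 * x + rnorm(n, 0, 0.5)
  expect_equal(mediation_path(x, m, y_partial, covs, n_boot = 500)$verdict,
               "partial")
  y_incons <- 5 - 0.7 * m + 0.9 * x + rnorm(n, 0, 0.5)
  expect_equal(mediation_path(x, m, y_incons, covs, n_boot = 500)$verdict,
               "inconsistent")
  y_none <- 5 + rnorm(n, 0, 0.5)
  expect_equal(mediation_path(x, m, y_none, covs, n_boot = 500)$verdict,
               "none")
  expect_error(mediation_path(x, rep(1, n), y_complete, covs), "vary")
})

test_that("covariates orthogonal to X and M leave the paths nearly unchanged", {
  set.seed(44)
  n <- 400
  x <- sample(0:2, n, TRUE)
  m <- 0.5 * x + rnorm(n)
  y <- -0.6 * m + rnorm(n)
  z <- data.frame(noise = rnorm(n))   # independent of everything
  m0 <- mediation_path(x, m, y, n_boot = 200)
  m1 <- mediation_path(x, m, y, z, n_boot = 200)
  expect_equal(m1$a, m0$a, tolerance = 0.02)
  expect_equal(m1$b, m0$b, tolerance = 0.02)
  expect_equal(m1$c_prime, m0$c_prime, tolerance = 0.05)
})
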