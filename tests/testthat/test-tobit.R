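test_that("the censored log-likelihood matches term-by-term oracles", {
  # no censoring: reduces to the gaussian linear-model likelihood
  set.seed(31)
  X <- cbind(1, rnorm(20))
  y <- 5 + drop(X %*% c(1, 0.5)) + rnorm(20)   # all positive
  beta <- c(5.8, 0.4); sig <- 1.3
  expect_equal(tobit_loglik(beta, log(sig), y, X),
               sum(dnorm(y, drop(X %*% beta), sig, log = TRUE)),
               tolerance = 1e-12)

  # single censored point at the limit with zero linear predictor
  expect_equal(tobit_loglik(0, log(1), 0, matrix(1, 1, 1)), log(0.5),
               tolerance = 1e-12)

  # 5-row hand dataset: brute-force sum of cdf/pdf terms
  Xh <- cbind(1, c(-1, 0, 1, 2, 3))
  yh <- c(0, 0, 0.5, 2.1, 3.3)
  b <- c(0.2, 0.9); s <- 1.1
  eta <- Xh %*% b
  manual <- log(pnorm((0 - eta[1]) / s)) + log(pnorm((0 - eta[2]) / s)) +
    log(dnorm((yh[3] - eta[3]) / s) / s) +
    log(dnorm((yh[4] - eta[4]) / s) / s) +
    log(dnorm((yh[5] - eta[5]) / s) / s)
  expect_equal(tobit_loglik(b, log(s), yh, Xh), manual, tolerance = 1e-12)
})

test_that("with no censoring the MLE collapses onto OLS", {
  set.seed(32)
  n <- 400
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  y <- 50 + 2 * X[, 2] + rnorm(n, 0, 3)       # far from the limit
  tf <- tobit_fit(y, X)
  ols <- lm.fit(X, y)$coefficients
  expect_equal(unname(tf$beta), unname(ols), tolerance = 1e-4)
  expect_equal(tf$n_censored, 0L)
})

test_that("estimates are consistent under 40% censoring at large n", {
  set.seed(33)
  n <- 10000
  x <- rnorm(n)
  ystar <- 1 + 2 * x + rnorm(n, 0, 3)
  y <- pmax(0, ystar)
  tf <- tobit_fit(y, cbind(`(Intercept)` = 1, x = x))
  expect_gt(tf$n_censored / n, 0.3)
  expect_lt(abs(tf$beta[1] - 1), 3 * tf$se[1])
  expect_lt(abs(tf$beta[2] - 2), 3 * tf$se[2])
  expect_lt(abs(tf$sigma - 3), 0.1)
})

test_that("fits agree with the survreg left-censored gaussian cross-check", {
  skip_if_not_installed("survival")
  set.seed(34)
  n <- 500
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  y <- pmax(0, 1.5 + 0.8 * x1 - 0.5 * x2 + rnorm(n, 0, 2))
  X <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2)
  tf <- tobit_fit(y, X)
  sr <- survival::survreg(survival::Surv(y, y > 0, type = "left") ~ x1 + x2,
                          dist = "gaussian")
  expect_equal(unname(tf$beta), unname(coef(sr)), tolerance = 1e-4)
  expect_equal(unname(tf$sigma), unname(sr$scale), tolerance = 1e-3)
  expect_equal(tf$loglik, as.numeric(logLik(sr)), tolerance = 1e-6)
})

test_that("the returned optimum dominates random perturbations", {
  set.seed(35)
  n <- 300
  x <- rnorm(n)
  y <- pmax(0, 1 + x + rnorm(n, 0, 2))
  X <- cbind(`(Intercept)` = 1, x = x)
  tf <- tobit_fit(y, X)
  ll_hat <- tobit_loglik(tf$beta, log(tf$sigma), y, X)
  for (i in 1:100) {
    pert <- rnorm(3, 0, 0.05)
    ll_p <- tobit_loglik(tf$beta + pert[1:2], log(tf$sigma) + pert[3], y, X)
    expect_lte(ll_p, ll_hat + 1e-10)
  }
})

test_that("estimates are equivariant under outcome rescaling", {
  set.seed(36)
  n <- 400
  x <- rnorm(n)
  y <- pmax(0, 1 + 0.7 * x + rnorm(n, 0, 2))
  X <- cbind(`(Intercept)` = 1, x = x)
  f1 <- tobit_fit(y, X)
  f5 <- tobit_fit(5 * y, X)
  expect_equal(unname(f5$beta), 5 * unname(f1$beta), tolerance = 1e-5)
  expect_equal(f5$sigma, 5 * f1$sigma, tolerance = 1e-5)
})

test_that("partial R-squared matches OLS in the uncensored orthogonal case and is monotone in the effect", {
  set.seed(37)
  n <- 2000
  x <- rnorm(n)
  y <- 30 + 1.5 * x + rnorm(n, 0, 2)          # uncensored
  X <- cbind(`(Intercept)` = 1, x = x)
  full <- tobit_fit(y, X)
  red <- tobit_fit(y, X[, 1, drop = FALSE])
  pr2 <- partial_r2(full, red)
  expect_equal(pr2, summary(lm(y ~ x))$r.squared, tolerance = 0.01)
  expect_gte(pr2, 0); expect_lt(pr2, 1)

  # a stronger generating effect increases the exposure's partial R2
  mean_pr2 <- function(effect) {
    v <- vapply(1:15, function(s) {
      tab <- simulate_cohort(cohort_params(
        n = 795, effect_per_sd = c(effect, 0, 0), seed = 4000 + s))
      m <- run_model_sequence(tab, "max_oxphos", tiers = 3, ordinal = FALSE)
      m$model3$partial_r2
    }, numeric(1))
    mean(v)
  }
  expect_gt(mean_pr2(2.0), mean_pr2(0.55))
})

test_that("degenerate designs are rejected", {
  X <- cbind(1, rnorm(30))
  expect_error(tobit_fit(rep(0, 30), X), "all outcomes censored")
  expect_error(tobit_fit(rnorm(3), X[1:3, ]), "n > p")
  set.seed(38)
  x <- rnorm(100)
  y1 <- pmax(0, 1 + x + rnorm(100))
  y2 <- pmax(0, 1 + x + rnorm(100))
  f1 <- tobit_fit(y1, cbind(1, x))
  f2 <- tobit_fit(y2, cbind(1, x))
  expect_error(partial_r2(f1, f2), "same rows")
})
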