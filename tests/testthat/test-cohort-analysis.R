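test_that("standardization yields unit z-scores and records the natural-scale SDs", {
  tab <- simulate_cohort(cohort_params(n = 795, seed = 61))
  st <- standardize_exposures(tab)
  for (e in c("max_oxphos", "max_ets", "atp_max")) {
    z <- st[[paste0("z_", e)]]
    expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-12)
    expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-12)
    expect_equal(st[[paste0("z_", e, "_lower")]], -z)
  }
  reg <- attr(st, "sd_registry")
  expect_equal(unname(reg), c(18.4, 22.1, 0.15), tolerance = 0.08)
  tab$max_oxphos <- 50
  expect_error(standardize_exposures(tab), "zero variance")
})

test_that("spearman matches the hand-rank oracle and Pearson-on-ranks", {
  expect_equal(spearman(1:10, (1:10)^3)$estimate, 1)
  # Sum d^2 = 4 -> 1 - 6*4/(5*24) = 0.8
  s <- spearman(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(s$estimate, 0.8, tolerance = 1e-12)
  set.seed(62)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(spearman(x, y)$estimate, cor(rank(x), rank(y)),
               tolerance = 1e-12)
  # t-approximation oracle
  r <- spearman(x, y)$estimate
  expect_equal(spearman(x, y)$p.value,
               2 * pt(-abs(r * sqrt(48 / (1 - r^2))), 48), tolerance = 1e-12)
  expect_error(spearman(1:3, 3:1), "4 complete pairs")
})

test_that("exposures correlate negatively with PPFI under the default effects", {
  neg <- vapply(1:50, function(s) {
    tab <- simulate_cohort(cohort_params(n = 795, seed = 7000 + s))
    spearman(tab$max_oxphos, tab$ppfi)$estimate < 0
  }, logical(1))
  expect_gte(mean(neg), 0.95)
})

test_that("trend tests follow the pre-declared families and are calibrated", {
  tab <- simulate_cohort(cohort_params(n = 600, seed = 63))
  t1 <- describe_by_strata(tab)
  expect_setequal(unique(t1$test),
                  c("kruskal-wallis", "anova", "chi-square"))
  expect_true(all(t1$p_trend >= 0 & t1$p_trend <= 1))
  # PPFI defines the strata: its trend must be overwhelming
  expect_lt(t1$p_trend[t1$variable == "ppfi"], 1e-10)

  # a perfectly homogeneous 3x2 block gives chi-square = 0, p = 1
  dummy <- data.frame(
    stratum = factor(rep(c("none", "mild", "moderate_to_severe"), each = 20),
                     levels = c("none", "mild", "moderate_to_severe"),
                     ordered = TRUE),
    grp = rep(rep(c("a", "b"), each = 10), 3))
  plan <- data.frame(variable = "grp", type = "categorical")
  out <- describe_by_strata(dummy, plan)
  expect_equal(out$p_trend, 1, tolerance = 1e-12)

  # Kruskal-Wallis p-values are uniform under the null
  ps <- vapply(1:500, function(s) {
    set.seed(8000 + s)
    d <- data.frame(
      stratum = factor(sample(rep(c("none", "mild", "moderate_to_severe"),
                                  each = 50)),
                       levels = c("none", "mild", "moderate_to_severe"),
                       ordered = TRUE),
      v = rnorm(150))
    describe_by_strata(d, data.frame(variable = "v",
                                     type = "skewed"))$p_trend
  }, numeric(1))
  # the KW statistic is discrete at this n, so tied p-values are expected
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)

  # separated normals: ANOVA power check
  hits <- vapply(1:50, function(s) {
    set.seed(8600 + s)
    d <- data.frame(
      stratum = factor(rep(c("none", "mild", "moderate_to_severe"),
                           each = 200),
                       levels = c("none", "mild", "moderate_to_severe"),
                       ordered = TRUE),
      v = rnorm(600) + rep(0:2, each = 200))
    describe_by_strata(d, data.frame(variable = "v",
                                     type = "normal"))$p_trend < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("model tiers accumulate covariates and drop exactly the missing rows", {
  tab <- simulate_cohort(cohort_params(n = 795, seed = 64))
  ms <- run_model_sequence(tab, "max_ets")
  n_missing <- sum(is.na(tab$max_ets))
  for (m in ms) expect_identical(m$n, nrow(tab) - n_missing)
  # tier design sizes: M1 has site/tech(3) + age + sex + race (+exposure,
  # intercept); M2 adds 2; M3 adds 1
  p1 <- length(ms$model1$tobit$beta)
  expect_identical(length(ms$model2$tobit$beta), p1 + 2L)
  expect_identical(length(ms$model3$tobit$beta), p1 + 3L)
  td <- tidy_model_sequence(ms)
  expect_identical(nrow(td), 3L)
  expect_true(all(td$partial_r2 >= 0 & td$partial_r2 < 1))
  expect_true(all(is.finite(td$or)))
})

test_that("with null covariate effects the tiers agree on the exposure estimate", {
  diffs <- numeric(100)
  for (s in 1:100) {
    tab <- simulate_cohort(cohort_params(n = 400, seed = 9000 + s))
    ms <- run_model_sequence(tab, "max_oxphos", tiers = c(1, 3),
                             ordinal = FALSE)
    e1 <- ms$model1$tobit
    e3 <- ms$model3$tobit
    diffs[s] <- e3$beta[e3$exposure] - e1$beta[e1$exposure]
  }
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)))
})

test_that("pipeline output is deterministic given the cohort", {
  tab <- simulate_cohort(cohort_params(n = 500, seed = 65))
  a <- tidy_model_sequence(run_model_sequence(tab, "atp_max"))
  b <- tidy_model_sequence(run_model_sequence(tab, "atp_max"))
  expect_identical(a, b)
})

test_that("interaction and SPPB-stratified analyses behave as designed", {
  tab <- simulate_cohort(cohort_params(n = 795, seed = 66))
  ia <- interaction_and_strata(tab, "max_oxphos", "sppb_binary")
  expect_true(ia$interaction_p >= 0 && ia$interaction_p <= 1)
  expect_s3_class(ia$stratified$high, "tobit_fit")
  expect_s3_class(ia$stratified$low, "tobit_fit")

  # modifier constant -> error
  tab2 <- tab
  tab2$sppb <- 12
  expect_error(interaction_and_strata(tab2, "max_oxphos", "sppb_binary"),
               "constant")

  # effect only in the better-function stratum: the stratified pattern
  # reproduces in most seeds
  pat <- vapply(1:30, function(s) {
    tb <- simulate_cohort(cohort_params(
      n = 795, sppb_effect = list(high = c(1.2, 0, 0), low = c(0, 0, 0)),
      seed = 9500 + s))
    st <- interaction_and_strata(tb, "max_oxphos", "sppb_binary")$stratified
    e <- st$high$exposure
    st$high$beta[e] > st$low$beta[e]
  }, logical(1))
  expect_gte(mean(pat), 0.9)
})

test_that("cohort CSV round trip preserves values and missingness encoding", {
  tab <- simulate_cohort(cohort_params(n = 200, seed = 67))
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(tab, f)
  raw <- readLines(f)
  expect_true(any(grepl(",,", raw)))      # empty fields for NA
  back <- read_cohort_csv(f)
  expect_equal(back$ppfi, tab$ppfi, tolerance = 1e-10)
  expect_identical(is.na(back$max_ets), is.na(tab$max_ets))
  expect_identical(as.character(back$stratum), as.character(tab$stratum))
  unlink(f)
})
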