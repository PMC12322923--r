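test_that("test selection follows the normality/homoscedasticity rules", {
  set.seed(2)
  g1 <- rnorm(60); g2 <- rnorm(60, 0.5)
  res <- select_group_test(list(g1, g2))
  expect_identical(res$test, "t-test")

  set.seed(2)
  res_w <- select_group_test(list(rnorm(60), rnorm(60, 0.5, 10)))
  expect_identical(res_w$test, "welch t-test")

  set.seed(2)
  skewed <- lapply(1:3, function(i) rexp(40)^2 + i)
  res_k <- select_group_test(skewed, alpha = 0.05)
  expect_identical(res_k$test, "kruskal-wallis")
  # statistic matches a direct rank-based computation
  y <- unlist(skewed); g <- rep(1:3, each = 40)
  r <- rank(y); n <- length(y)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(x) length(x) * mean(x)^2)) - 3 * (n + 1)
  ties <- table(y)
  h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(res_k$statistic, h, tolerance = 1e-10)

  set.seed(1002)
  res_a <- select_group_test(list(rnorm(50), rnorm(50, 0.3), rnorm(50, 0.6)))
  expect_identical(res_a$test, "one-way anova")

  set.seed(2002)
  res_p <- select_group_test(list(rnorm(30), rnorm(30, 1)), paired = TRUE)
  expect_identical(res_p$test, "paired t-test")

  expect_error(select_group_test(list(rnorm(3))), "two groups")
  expect_error(select_group_test(list(rnorm(3), rnorm(2))), "at least 3")
})

test_that("noise-free cohorts recover the generating coefficients exactly", {
  cfg <- cohort_config(pattern_mix = c(`3` = 10L, `4` = 19L, `5` = 9L),
                       thickness = list(intercept = 2.75, sex_effect = -0.09,
                                        age_slope = -0.005, noise_sd = 0),
                       seed = 4)
  tab <- simulate_cohort_table(cfg)
  fit <- fit_thickness_model(tab)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[["(Intercept)"]], 2.75, tolerance = 1e-9)
  expect_equal(est[["sexmale"]], -0.09, tolerance = 1e-9)
  expect_equal(est[["age"]], -0.005, tolerance = 1e-9)
})

test_that("HC3 errors stay near classical errors for homoscedastic data", {
  set.seed(55)
  ok <- replicate(40, {
    tab <- simulate_cohort_table(cohort_config(seed = sample.int(1e6, 1)))
    fit <- fit_thickness_model(tab)
    se_cl <- sqrt(diag(vcov(fit$lm)))
    all(abs(fit$coefficients$se / se_cl - 1) < 0.25)
  })
  expect_gt(mean(ok), 0.9)
})

test_that("a strong sex effect is detected in nearly every large cohort", {
  set.seed(77)
  hits <- replicate(60, {
    cfg <- cohort_config(pattern_mix = c(`4` = 500L),
                         thickness = list(intercept = 2.75,
                                          sex_effect = -0.09,
                                          age_slope = -0.005,
                                          noise_sd = 0.055),
                         seed = sample.int(1e6, 1))
    fit <- fit_thickness_model(simulate_cohort_table(cfg))
    p <- with(fit$coefficients, p.value[term == "sexmale"])
    p < 0.05
  })
  expect_gt(mean(hits), 0.95)
})

test_that("rank-deficient designs error naming the aliased terms", {
  tab <- simulate_cohort_table(cohort_config(seed = 2))
  tab$dupe <- tab$sex  # perfectly aliased with sex
  expect_error(fit_thickness_model(tab, vascular = "dupe"), "aliased")
  tab$single <- "only-level"
  expect_error(fit_thickness_model(tab, vascular = "single"),
               "fewer than 2")
  expect_error(fit_thickness_model(tab, vascular = "nope"), "no column")
})

test_that("model comparison matches the direct RSS F identity and anova()", {
  set.seed(9)
  tab <- simulate_cohort_table(cohort_config(seed = 9))
  full <- fit_thickness_model(tab, vascular = "pattern")
  reduced <- fit_thickness_model(tab)
  cmp <- compare_models(full, reduced)
  rss_f <- sum(residuals(full$lm)^2)
  rss_r <- sum(residuals(reduced$lm)^2)
  f_direct <- ((rss_r - rss_f) / 2) / (rss_f / full$lm$df.residual)
  expect_equal(cmp$F.statistic, f_direct, tolerance = 1e-12)
  ref <- anova(reduced$lm, full$lm)
  expect_equal(cmp$F.statistic, ref$F[2], tolerance = 1e-10)
  expect_equal(cmp$p.value, ref$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(cmp$df, c(2L, full$lm$df.residual))

  same <- compare_models(full, full)
  expect_identical(same$F.statistic, 0)
  expect_identical(same$p.value, 1)

  other <- fit_thickness_model(tab, vascular = "pattern",
                               covariates = character(0))
  expect_error(compare_models(other, reduced), "not nested")
})

test_that("null vascular effects keep the comparison type-I error near 0.05", {
  n_sim <- 400
  set.seed(123)
  rejections <- replicate(n_sim, {
    tab <- simulate_cohort_table(cohort_config(seed = sample.int(1e6, 1)))
    # break any link between pattern and thickness: re-randomise the labels
    tab$pattern <- sample(tab$pattern)
    full <- fit_thickness_model(tab, vascular = "pattern")
    reduced <- fit_thickness_model(tab)
    compare_models(full, reduced)$p.value < 0.05
  })
  rate <- mean(rejections)
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / n_sim)
  expect_gt(rate, 0.05 - ci_half)
  expect_lt(rate, 0.05 + ci_half)
})

test_that("injected vascular effects are detected at cohort size 38", {
  cfg <- cohort_config(seed = 31)
  tab <- simulate_cohort_table(cfg)
  tab$thickness_mm <- tab$thickness_mm + 0.4 * (tab$pattern == 4)
  full <- fit_thickness_model(tab, vascular = "pattern")
  reduced <- fit_thickness_model(tab)
  expect_lt(compare_models(full, reduced)$p.value, 0.001)
})

test_that("adjusted thickness preserves the intercept as the mean", {
  tab <- simulate_cohort_table(cohort_config(seed = 14))
  reduced <- fit_thickness_model(tab)
  adj <- adjust_thickness(reduced)
  expect_equal(mean(adj), unname(coef(reduced$lm)[1]), tolerance = 1e-9)
  expect_equal(var(adj), var(residuals(reduced$lm)), tolerance = 1e-12)

  # covariate-free model: adjusted values shift to original values' structure
  null_fit <- fit_thickness_model(tab, covariates = character(0))
  expect_equal(adjust_thickness(null_fit), tab$thickness_mm,
               tolerance = 1e-12)

  # noise-free data: every adjusted value equals the intercept
  cfg0 <- cohort_config(thickness = list(intercept = 2.7, sex_effect = -0.1,
                                         age_slope = -0.004, noise_sd = 0),
                        seed = 15)
  fit0 <- fit_thickness_model(simulate_cohort_table(cfg0))
  expect_equal(adjust_thickness(fit0), rep(2.7, 38), tolerance = 1e-9)

  # group means of adjusted values match direct residual means + intercept
  grp <- tab$pattern
  direct <- tapply(residuals(reduced$lm), grp, mean) + coef(reduced$lm)[1]
  expect_equal(as.numeric(tapply(adj, grp, mean)), as.numeric(direct),
               tolerance = 1e-12)
})
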