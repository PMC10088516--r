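test_that("percent change follows the study convention and is scale invariant", {
  expect_equal(round(abs(percent_change(186.5, 121.3)), 1), 35.0)
  expect_equal(round(abs(percent_change(156.1, 116.4)), 1), 25.4)
  expect_equal(round(abs(percent_change(75.7, 64.2)), 1), 15.2)
  expect_equal(percent_change(7.3, 7.3), 0)
  # increases are negative under the study decrease convention
  expect_lt(percent_change(2.66, 2.92), 0)
  expect_equal(percent_increase(2.66, 2.92), -percent_change(2.66, 2.92))
  expect_error(percent_change(0, 5), "undefined")

  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10); k <- runif(1, -5, 5)
    if (k == 0) next
    expect_equal(percent_change(k * a, k * b), percent_change(a, b))
  }
})

test_that("signed-rank test matches exact enumeration and conventions", {
  # 5 pairs, all differences positive: exact two-sided p = 2/32
  r <- paired_wilcoxon(rep(0, 5), 1:5)
  expect_equal(r$p.value, 0.0625)
  expect_equal(unname(r$statistic), 15)

  # n = 8 with one negative difference equals the 2^8 enumeration
  d <- c(1, 2, 3, 4, 5, 6, 7, -8)
  expect_equal(paired_wilcoxon(rep(0, 8), d)$p.value, wilcoxon_enum_p(d))

  # stated error contracts
  expect_error(paired_wilcoxon(1:6, 1:6), "zero")
  expect_error(paired_wilcoxon(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 9)),
               "small-sample")
  expect_error(paired_wilcoxon(1:4, 2:5), "small-sample")
  expect_error(paired_wilcoxon(1:5, 1:6), "equal length")
})

test_that("exact p equals brute-force enumeration for n <= 10, ties included", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(5:10, 1)
    d <- if (rep %% 2 == 0) sample(c(-4:-1, 1:4), n, replace = TRUE) # many ties
      else round(rnorm(n, 0.3, 1), 3)
    d <- d[d != 0]
    if (length(d) < 5) next
    expect_equal(paired_wilcoxon(rep(0, length(d)), d)$p.value,
                 wilcoxon_enum_p(d), tolerance = 1e-12)
  }
  # independent cross-check against stats::wilcox.test on untied data
  set.seed(43)
  for (rep in 1:20) {
    d <- rnorm(sample(6:15, 1))
    expect_equal(paired_wilcoxon(rep(0, length(d)), d)$p.value,
                 wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("OLS recovers exact fits and flags degenerate designs", {
  x <- 1:10
  fit <- suppressWarnings(ols_regression(2 * x + 1, data.frame(x = x)))
  expect_equal(fit$estimate, 2, tolerance = 1e-9)
  expect_lt(fit$ci_high - fit$ci_low, 1e-9)

  expect_error(ols_regression(rnorm(10), data.frame(a = x, b = x)),
               "collinear")
  expect_error(ols_regression(rnorm(10), data.frame(a = rep(1, 10))),
               "constant")
  expect_error(ols_regression(rnorm(3), data.frame(a = 1:3, b = c(1, 3, 2))),
               "too few")

  # univariable mode fits one model per covariate
  set.seed(5)
  covs <- data.frame(a = rnorm(50), b = rnorm(50))
  y <- 1 + 2 * covs$a - covs$b + rnorm(50, 0, 0.1)
  uni <- ols_regression(y, covs, mode = "univariable")
  expect_identical(nrow(uni), 2L)
  expect_true(all(uni$model == "univariable"))
  multi <- ols_regression(y, covs)
  expect_equal(multi$estimate, c(2, -1), tolerance = 0.1)
  expect_true(all(multi$ci_low <= multi$estimate & multi$estimate <= multi$ci_high))
})

test_that("OLS confidence intervals achieve nominal coverage on pure noise", {
  set.seed(11)
  cover <- vapply(1:100, function(i) {
    x <- rnorm(200)
    f <- ols_regression(rnorm(200), data.frame(x = x))
    f$ci_low <= 0 && 0 <= f$ci_high
  }, TRUE)
  expect_gte(mean(cover), 0.90)
})

test_that("an injected 6% shift is recovered across every chunk", {
  sim <- simulate_chunk_cohort(30, 19, effect_pct = c(area_mm2 = 6), seed = 101)
  tab <- build_change_table(sim$cohort, sim$covariates)
  area <- tab$changes[tab$changes$feature == "area_mm2", ]
  expect_true(all(area$p_value < 0.05))
  expect_lt(abs(mean(area$pct_increase) - 6), 0.5)
  expect_true(all(abs(area$pct_increase - 6) < 1))
  # the decrease column is the negated increase
  expect_equal(area$pct_decrease, -area$pct_increase)
  # covariate table carries one row per covariate per cell, with CIs
  ce <- tab$covariate_effects
  expect_true(all(c("estimate", "ci_low", "ci_high") %in% names(ce)))
  expect_true(all(ce$ci_low <= ce$estimate & ce$estimate <= ce$ci_high))
})

test_that("cohort preconditions: missing timepoints and tiny cohorts", {
  sim <- simulate_chunk_cohort(6, 3, seed = 2)
  co <- sim$cohort
  drop <- co$subject_id == "S6" & co$timepoint == "followup"
  expect_warning(build_change_table(co[!drop, ]), "missing a timepoint")
  one <- co[co$subject_id %in% c("S1", "S2", "S3", "S4"), ]
  expect_error(build_change_table(one), "fewer than 5")
  expect_error(build_change_table(co[, 1:3]), "feature")
})
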