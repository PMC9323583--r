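test_that("icc equals 1 when rater columns are identical", {
  Y <- cbind(1:6, 1:6)
  for (m in c("ICC_1_1", "ICC_2_1", "ICC_3_1")) {
    r <- icc(Y, m)
    expect_equal(r$estimate, 1)
    expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
  }
})

test_that("consistency vs absolute agreement: systematic rater offset", {
  Y <- cbind(1:4, 1:4 + 10)
  expect_equal(icc(Y, "ICC_3_1")$estimate, 1)
  # hand computation: MSR = 10/3, MSC = 200, MSE = 0
  # ICC(2,1) = MSR / (MSR + k MSC / n) = (10/3) / (10/3 + 100)
  expect_equal(icc(Y, "ICC_2_1")$estimate, (10 / 3) / (10 / 3 + 100))
  expect_lt(icc(Y, "ICC_2_1")$estimate, 1)
})

test_that("icc matches brute-force ANOVA mean squares to 1e-10", {
  for (s in 1:50) {
    Y <- with_seed_local(s, matrix(rnorm(30, mean = 10), 10, 3))
    r2 <- icc(Y, "ICC_2_1")
    for (m in c("ICC_1_1", "ICC_2_1", "ICC_3_1"))
      expect_equal(icc(Y, m)$estimate, brute_icc(Y, m), tolerance = 1e-10)
    ms <- brute_mean_squares(Y)
    expect_equal(r2$mean_squares$between_subjects, ms$MSR, tolerance = 1e-10)
    expect_equal(r2$mean_squares$between_raters, ms$MSC, tolerance = 1e-10)
    expect_equal(r2$mean_squares$residual, ms$MSE, tolerance = 1e-10)
  }
})

test_that("icc rejects incomplete and degenerate tables", {
  tab <- data.frame(participant_id = c("a", "a", "b"),
                    rater_id = c("r1", "r2", "r1"), value = 1:3)
  expect_error(icc(tab), class = "fdretina_input_error")
  expect_error(icc(matrix(5, 4, 2)), class = "fdretina_input_error")
})

test_that("cv follows SD/mean x 100 and its invariances", {
  expect_equal(cv(list(c(2, 2, 2)))$cv_percent, 0)
  expect_equal(cv(list(c(1, 3)))$cv_percent, sqrt(2) / 2 * 100)
  expect_equal(round(cv(list(c(1, 3)))$cv_percent, 2), 70.71)
  # constant offset raises the mean, leaves SD: CV strictly decreases
  v <- list(c(1, 3), c(2, 5))
  expect_lt(cv(lapply(v, `+`, 10))$cv_percent, cv(v)$cv_percent)
  # aggregation modes differ on heterogeneous subjects
  expect_false(isTRUE(all.equal(cv(v, "overall")$cv_percent,
                                cv(v)$cv_percent)))
  expect_error(cv(list(c(-2, 1))), class = "fdretina_input_error")
  expect_error(cv(list(1)), class = "fdretina_input_error")
})

test_that("bland_altman reproduces hand-computed cases", {
  x <- c(1, 2, 3); y <- c(2, 2, 5)
  ba <- bland_altman(x, y)
  expect_equal(ba$bias, -1)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, -2.96)
  expect_equal(ba$loa_high, 0.96)
  expect_equal(ba$pairs$mean, c(1.5, 2, 4))
  same <- bland_altman(x, x)
  expect_equal(same$bias, 0)
  expect_equal(same$loa_high - same$loa_low, 0)
  off <- bland_altman(x, x + 3)
  expect_equal(off$bias, -3)
  expect_equal(off$sd_diff, 0)
  expect_error(bland_altman(1:4, 1:5), class = "fdretina_input_error")
})

test_that("paired_t matches the closed form and is antisymmetric", {
  x <- c(2, 0, 1, 1); y <- c(1, 1, 1, 1)  # differences (1, -1, 0, 0)
  r <- paired_t(x, y)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # strong consistent shift at n = 30 is overwhelmingly significant
  set.seed(42)
  a <- rnorm(30); b <- a + 1 + rnorm(30, 0, 0.05)
  expect_lt(paired_t(b, a)$p, 0.001)
  r1 <- paired_t(a, b); r2 <- paired_t(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  # agreement with the reference implementation
  tt <- stats::t.test(a, b, paired = TRUE)
  expect_equal(r1$t, unname(tt$statistic))
  expect_equal(r1$p, tt$p.value)
  expect_error(paired_t(c(1, 2), c(1, 2)), class = "fdretina_input_error")
})

test_that("normality_check has type-I control and power", {
  pnorm_reps <- vapply(1:100, function(s)
    with_seed_local(s, normality_check(rnorm(500))$p), 1)
  expect_gte(sum(pnorm_reps > 0.01), 98)
  pexp_reps <- vapply(1:100, function(s)
    with_seed_local(1000 + s, normality_check(rexp(500))$p), 1)
  expect_gte(sum(pexp_reps < 0.01), 95)
  expect_error(normality_check(rep(1, 10)), class = "fdretina_input_error")
  expect_error(normality_check(c(1, 2)), class = "fdretina_input_error")
})

test_that("cicchetti_label maps bands, boundaries, and is monotone", {
  expect_equal(cicchetti_label(c(0.722, 0.828, 0.651, 0.363)),
               c("good", "excellent", "good", "poor"))
  expect_equal(cicchetti_label(c(0.40, 0.60, 0.75)),
               c("fair", "good", "excellent"))
  grid <- seq(-1, 1, by = 0.01)
  lv <- match(cicchetti_label(grid),
              c("poor", "fair", "good", "excellent"))
  expect_true(all(diff(lv) >= 0))
  expect_error(cicchetti_label(1.2), class = "fdretina_input_error")
})

test_that("summaries format as mean +/- SD (range) and n (percent)", {
  s <- summarize_values(c(1, 2, 3), digits = 0)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$formatted, "2 ± 1 (1-3)")
  expect_equal(summarize_values(c(5, 5, 5))$sd, 0)
  expect_equal(format_count_percent(29, 43)$formatted, "29 (67.44)")
})
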