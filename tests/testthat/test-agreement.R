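test_that("residual sets validate their inputs", {
  rs <- residual_set(c(1, 2), c(0.5, 1))
  expect_equal(rs$residuals, c(0.5, 1))
  expect_equal(rs$n, 2L)
  expect_error(residual_set(1:3, 1:2), "equal length")
  expect_error(residual_set(numeric(), numeric()), "at least one")
  expect_error(residual_set(c(1, NA), c(1, 2)), "finite")
})

rs_from_residuals <- function(r) residual_set(r, rep(0, length(r)))

test_that("bias, relative bias and precision follow their definitions", {
  expect_equal(bias(rs_from_residuals(c(0.5, 0.1, 0.3))), 0.3)
  expect_equal(bias(rs_from_residuals(c(0, 0, 0))), 0)
  expect_equal(bias(rs_from_residuals(c(-1, 1))), 0)

  expect_equal(relative_bias(0), 0)
  expect_identical(relative_bias(log(2)), 100)  # exact, analytically forced
  # inverse check against a reported percentage
  expect_equal(relative_bias(log(1.3765)), 37.65)
  expect_true(all(diff(relative_bias(seq(-1, 1, 0.1))) > 0))  # increasing

  expect_equal(precision(rs_from_residuals(c(1, 2, 3))), 1)
  expect_equal(precision(rs_from_residuals(c(2, 2, 2))), 0)
  # direct-summation oracle
  r <- c(0.1, 0.5, 0.9, 1.3)
  expect_equal(precision(rs_from_residuals(r)),
               sqrt(sum((r - mean(r))^2) / (length(r) - 1)))
  expect_equal(precision(rs_from_residuals(r)), 0.5164, tolerance = 1e-4)
  expect_error(precision(rs_from_residuals(1)), "at least two")
})

test_that("accuracy is the mean absolute residual and bounds the bias", {
  expect_equal(accuracy_mae(rs_from_residuals(c(-1, 1))), 1)
  expect_equal(accuracy_mae(rs_from_residuals(0.3)), 0.3)
  expect_equal(accuracy_mae(rs_from_residuals(c(0.5, -0.1, 0.3))), 0.3)
  expect_equal(mean_offset(rs_from_residuals(c(-1, 1))), 0)

  withr::local_seed(42)
  for (i in 1:1000) {
    r <- stats::rnorm(sample(2:20, 1), stats::runif(1, -2, 2),
                      stats::runif(1, 0, 2))
    rs <- rs_from_residuals(r)
    expect_gte(accuracy_mae(rs), abs(bias(rs)))
    expect_gte(accuracy_mae(rs), mean_offset(rs))
  }
})

test_that("Bland-Altman limits sit symmetrically at 1.96 SD", {
  same <- residual_set(c(1, 2, 3), c(1, 2, 3))
  ba <- bland_altman(same)
  expect_equal(c(ba$ba_mean, ba$ba_upper, ba$ba_lower), c(0, 0, 0))

  const <- residual_set(c(2, 3, 4), c(1, 2, 3))
  ba <- bland_altman(const)
  expect_equal(c(ba$ba_mean, ba$ba_upper, ba$ba_lower), c(1, 1, 1))

  withr::local_seed(7)
  for (i in 1:20) {
    e <- stats::rnorm(10); a <- stats::rnorm(10)
    ba <- bland_altman(residual_set(e, a))
    expect_equal(ba$ba_upper + ba$ba_lower, 2 * ba$ba_mean)
    expect_equal(ba$ba_upper - ba$ba_mean, 1.96 * stats::sd(e - a))
    expect_equal(ba$points$mean, (e + a) / 2)
  }

  # a two-point set with mean difference 1.33 and SD 0.5051 reproduces the
  # reference limits 2.32 / 0.35 within rounding
  d <- 1.33 + c(-1, 1) * 0.5051 / sqrt(2)
  ba <- bland_altman(residual_set(d, c(0, 0)))
  expect_equal(ba$ba_upper, 2.32, tolerance = 0.01)
  expect_equal(ba$ba_lower, 0.35, tolerance = 0.05)
})

test_that("Pearson correlation handles exact and degenerate cases", {
  expect_equal(pearson_r(residual_set(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_equal(pearson_r(residual_set(-c(1, 2, 3) + 5, c(1, 2, 3))), -1)
  e <- c(1, 2, 3, 5); a <- c(1, 2, 3, 4)
  # direct product-moment formula as oracle
  r_manual <- sum((e - mean(e)) * (a - mean(a))) /
    sqrt(sum((e - mean(e))^2) * sum((a - mean(a))^2))
  expect_equal(pearson_r(residual_set(e, a)), r_manual)
  expect_equal(pearson_r(residual_set(e, a)), 0.9827, tolerance = 1e-4)
  expect_error(pearson_r(residual_set(c(1, 2), c(1, 2))), "three")
  expect_error(pearson_r(residual_set(c(1, 1, 1), c(1, 2, 3))),
               "zero-variance")
})

test_that("the normality gate passes normal and flags lognormal samples", {
  withr::local_seed(1)
  normal <- stats::rnorm(500)
  heavy <- exp(stats::rnorm(500, 0, 1.5))
  expect_true(normality_gate(normal)$pass)
  expect_false(normality_gate(heavy)$pass)
  small <- normality_gate(stats::rnorm(5))
  expect_false(small$conclusive)
  expect_true(is.na(small$pass))
})

test_that("grouped summaries are consistent and recover known structure", {
  withr::local_seed(99)
  n <- 1e4
  a <- stats::rnorm(n, 2, 1)
  e <- a + stats::rnorm(n, 0.3, 0.1)
  preds <- data.frame(predicted_lc50_ug_L = 10^e, known_lc50_ug_L = 10^a,
                      functional_group = sample(c("carbamate",
                                                  "thiophosphate"),
                                                n, replace = TRUE))
  s <- summarize_agreement(preds, "overall")
  expect_equal(s$relative_bias_pct, relative_bias(s$bias))
  expect_equal(s$bias, 0.3, tolerance = 3 * 0.1 / sqrt(n) / 0.3)
  expect_equal(s$precision, 0.1, tolerance = 0.05)
  expect_equal(s$ba_mean, s$bias)
  expect_gte(s$accuracy_mae, abs(s$bias))

  by_fg <- summarize_agreement(preds, "functional_group")
  expect_setequal(by_fg$group, c("carbamate", "thiophosphate"))
  expect_equal(sum(by_fg$n), n)

  # permutation invariance
  perm <- preds[sample(n), ]
  expect_equal(summarize_agreement(perm, "overall")[, -1],
               s[, -1])

  # all-exact predictions: zero bias and spread, correlation NA-safe
  exact <- data.frame(predicted_lc50_ug_L = c(1, 1, 1),
                      known_lc50_ug_L = c(1, 1, 1))
  se <- summarize_agreement(exact, "overall")
  expect_equal(se$bias, 0)
  expect_equal(se$precision, 0)
  expect_equal(se$accuracy_mae, 0)
  expect_true(is.na(se$pearson_r))

  one <- summarize_agreement(exact[1, ], "overall")
  expect_true(is.na(one$precision))
})
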