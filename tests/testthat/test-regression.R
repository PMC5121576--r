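test_that("a collinear series is fitted exactly", {
  trips <- toy_trips(c(2260, 2360, 2460), c(10, 12, 14))
  fit <- fit_iop_altitude(trips)
  expect_equal(fit$slope, 2, tolerance = 1e-12)       # 2 mmHg per 100 m
  expect_equal(fit$intercept, 10 - 2 * 22.6, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # perfectly collinear points give a zero-width interval
  expect_equal(fit$ci_low, fit$ci_high, tolerance = 1e-9)
})

test_that("fits match the closed-form OLS oracle on every study eye", {
  trips <- rabbit_trips()
  for (method in c("applanation", "indentation")) {
    fits <- fit_iop_altitude(trips, method = method)
    col <- paste0("iop_", method, "_mmhg")
    for (eye in unique(trips$eye_id)) {
      d <- trips[trips$eye_id == eye, ]
      oracle <- brute_force_ols(d$altitude_m / 100, d[[col]])
      row <- fits[fits$eye_id == eye, ]
      expect_equal(row$slope, oracle[["slope"]], tolerance = 1e-9)
      expect_equal(row$intercept, oracle[["intercept"]], tolerance = 1e-9)
    }
  }
})

test_that("fit is order-free and equivariant under constant IOP shifts", {
  trips <- rabbit_trips()
  base <- fit_iop_altitude(trips)
  shuffled <- trips[sample(nrow(trips)), ]
  refit <- fit_iop_altitude(shuffled)
  refit <- refit[match(base$eye_id, refit$eye_id), ]
  expect_equal(refit$slope, base$slope, tolerance = 1e-12)
  expect_equal(refit$intercept, base$intercept, tolerance = 1e-12)

  shifted <- trips
  shifted$iop_applanation_mmhg <- shifted$iop_applanation_mmhg + 5
  sfit <- fit_iop_altitude(shifted)
  expect_equal(sfit$slope, base$slope, tolerance = 1e-12)
  expect_equal(sfit$intercept, base$intercept + 5, tolerance = 1e-12)
  expect_equal(sfit$ci_low, base$ci_low, tolerance = 1e-12)
  expect_equal(sfit$ci_high, base$ci_high, tolerance = 1e-12)
})

test_that("r_squared equals the squared correlation of fitted and observed", {
  trips <- rabbit_trips()
  fits <- fit_iop_altitude(trips)
  for (eye in fits$eye_id) {
    d <- trips[trips$eye_id == eye, ]
    row <- fits[fits$eye_id == eye, ]
    fitted <- row$intercept + row$slope * d$altitude_m / 100
    expect_equal(row$r_squared, cor(fitted, d$iop_applanation_mmhg)^2,
                 tolerance = 1e-9)
  }
})

test_that("degenerate designs and short series are rejected", {
  expect_error(fit_iop_altitude(toy_trips(c(2260, 2360), c(10, 12))),
               class = "altiop_error_data")
  expect_error(fit_iop_altitude(toy_trips(c(2260, 2260, 2260), c(10, 12, 14))),
               class = "altiop_error_data")
})

test_that("slope confidence intervals use the t quantile at n - 2 df", {
  fits <- fit_iop_altitude(rabbit_trips())
  ci <- slope_confidence_interval(fits, level = 0.95)
  tq <- qt(0.975, df = fits$n - 2)
  expect_equal(ci$ci_low, fits$slope - tq * fits$se_slope, tolerance = 1e-12)
  expect_equal(ci$ci_high, fits$slope + tq * fits$se_slope, tolerance = 1e-12)
  # widening the level widens the interval
  ci99 <- slope_confidence_interval(fits, level = 0.99)
  expect_true(all(ci99$ci_low < ci$ci_low & ci99$ci_high > ci$ci_high))
  expect_error(slope_confidence_interval(fits, level = 1.2),
               class = "altiop_error_config")
})

test_that("significance classification is CI disjointness against the benchmark", {
  fits <- classify_significance(fit_iop_altitude(rabbit_trips()))
  got <- setNames(fits$significance, fits$eye_id)
  expect_identical(got[["SF6_100"]], "NS")  # benchmark against itself
  expect_identical(got[["SF6_50"]], "NS")
  expect_identical(got[["Air_100"]], "NS")
  expect_identical(got[["SF6_25"]], "NS")
  expect_identical(got[["Pneum"]], "Sig")
  expect_identical(got[["BSS"]], "Sig")
  expect_error(classify_significance(fits, benchmark = "nope"),
               class = "altiop_error_config")
})

test_that("method agreement reproduces the benchmark eye's correlation", {
  agree <- method_agreement(rabbit_trips())
  row <- agree[agree$eye_id == "SF6_100", ]
  expect_equal(row$pearson_r, 0.979, tolerance = 0.005)
  expect_equal(row$r_squared, row$pearson_r^2, tolerance = 1e-12)
  expect_false(any(agree$all_zero))
})

test_that("agreement handles identical and perfectly anticorrelated channels", {
  same <- toy_trips(c(2260, 2410, 2740, 3093, 3198), c(10, 12, 14, 15, 16))
  agree <- method_agreement(same)
  expect_equal(agree$pearson_r, 1)
  expect_true(agree$all_zero)
  expect_equal(agree$wilcoxon_p, 1)

  anti <- same
  anti$iop_applanation_mmhg <- 1:5
  anti$iop_indentation_mmhg <- 5:1
  expect_equal(method_agreement(anti)$pearson_r, -1)
})

test_that("exact signed-rank p matches stats::wilcox.test when ties are absent", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    x <- rnorm(n)
    y <- x + rnorm(n)  # continuous, so no ties or zeros
    ours <- altiop:::signed_rank_test(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact signed-rank p with ties approaches the normal approximation", {
  # integer data with heavy ties: exact DP must stay close to the z-test
  set.seed(7)
  x <- round(rnorm(30, sd = 3))
  y <- round(x + rnorm(30, sd = 2))
  big <- altiop:::signed_rank_test(x, y)        # n > 25 -> normal path
  exact <- altiop:::signed_rank_test(x[1:20], y[1:20])
  expect_true(big$p >= 0 && big$p <= 1)
  expect_true(exact$p >= 0 && exact$p <= 1)
})

test_that("tidy and glance return broom-shaped tibbles", {
  fits <- fit_iop_altitude(rabbit_trips())
  td <- tidy(fits)
  expect_true(all(c("eye_id", "term", "estimate") %in% names(td)))
  expect_equal(nrow(td), 2 * nrow(fits))
  gl <- glance(fits)
  expect_equal(gl$r.squared, fits$r_squared)
  expect_equal(unique(gl$conf.level), 0.95)
})
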