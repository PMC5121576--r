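test_that("equal source and target rigidity is the identity transform", {
  trips <- rabbit_trips()
  e <- rigidity("rabbit_mean")
  ex <- extrapolate_to_human(trips, e_source = e, e_target = e)
  expect_equal(ex$human_iop_mmhg, trips$iop_applanation_mmhg, tolerance = 1e-12)
  # and the refit reproduces the rabbit fit exactly
  refit <- fit_human_series(ex)
  rabbit <- fit_iop_altitude(trips)
  expect_equal(refit$slope, rabbit$slope, tolerance = 1e-12)
  expect_equal(refit$intercept, rabbit$intercept, tolerance = 1e-12)
  expect_equal(refit$ci_low, rabbit$ci_low, tolerance = 1e-12)
})

test_that("station-level extrapolation matches the hand-evaluated chain", {
  trips <- rabbit_trips()
  ex <- extrapolate_to_human(trips, e_target = 0.0215)
  peak <- ex[ex$eye_id == "SF6_100" & ex$altitude_m == 3198, ]
  expect_equal(peak$human_iop_mmhg, 36.42, tolerance = 1e-2)  # 16 -> 32 rabbit
  ex_max <- extrapolate_to_human(trips, e_target = 0.0343)
  peak_max <- ex_max[ex_max$eye_id == "SF6_100" & ex_max$altitude_m == 3198, ]
  expect_equal(peak_max$human_iop_mmhg, 59.4, tolerance = 0.1)
  # baseline station maps to the baseline pressure
  base <- ex[ex$eye_id == "SF6_100", ]
  expect_equal(base$human_iop_mmhg[1], base$baseline_mmhg[1])
  expect_true(all(ex$human_iop_mmhg > 0))
})

test_that("an explicit human baseline rescales the whole series", {
  trips <- rabbit_trips()
  own <- extrapolate_to_human(trips, e_target = 0.0215)
  fixed <- extrapolate_to_human(trips, e_target = 0.0215, baseline_iop = 15)
  for (eye in unique(trips$eye_id)) {
    a <- own$human_iop_mmhg[own$eye_id == eye]
    b <- fixed$human_iop_mmhg[fixed$eye_id == eye]
    expect_equal(b, a / a[1] * 15, tolerance = 1e-12)
  }
})

test_that("the BSS control eye stays flat under every coefficient", {
  trips <- rabbit_trips()
  for (e in human_coefficients()$value) {
    fit <- fit_human_series(extrapolate_to_human(trips, e_target = e))
    expect_lt(abs(fit$slope[fit$eye_id == "BSS"]), 0.3)
  }
})

test_that("extrapolation table has one row per eye and coefficient", {
  tab <- extrapolation_table(rabbit_trips())
  expect_equal(nrow(tab), 24)   # 6 eyes x 4 human coefficients
  expect_equal(dplyr::count(tab, coefficient)$n, rep(6, 4))
  # four benchmark rows, classified NS against themselves
  bench <- tab[tab$eye_id == "SF6_100", ]
  expect_equal(nrow(bench), 4)
  expect_true(all(bench$significance == "NS"))
  expect_error(extrapolation_table(rabbit_trips(), benchmark = "nope"),
               class = "altiop_error_config")
})

test_that("human slopes are monotone in the target rigidity for rising eyes", {
  tab <- extrapolation_table(rabbit_trips())
  ord <- c("pallikaris", "friedenwald", "dastiridou_mean", "dastiridou_max")
  rising <- c("SF6_100", "SF6_50", "SF6_25", "Air_100", "Pneum")
  for (eye in rising) {
    slopes <- tab$slope[match(paste(ord, eye),
                              paste(tab$coefficient, tab$eye_id))]
    expect_true(all(diff(slopes) > 0))
  }
})

test_that("gas-filled eyes outrank the controls in every coefficient", {
  tab <- extrapolation_table(rabbit_trips())
  for (nm in unique(tab$coefficient)) {
    d <- tab[tab$coefficient == nm, ]
    s <- setNames(d$slope, d$eye_id)
    expect_true(s[["SF6_100"]] >= s[["SF6_50"]])
    expect_true(min(s[c("SF6_50", "SF6_25", "Air_100")]) > s[["Pneum"]])
    expect_true(s[["Pneum"]] > s[["BSS"]])
  }
})

test_that("the travel advisory is exact linear arithmetic", {
  adv <- predict_travel_iop(15, 2.1, c(1.7, 2.5), 2260)
  expect_equal(adv$delta_iop, 47.46, tolerance = 1e-12)
  expect_equal(adv$predicted_iop, 62.46, tolerance = 1e-12)
  expect_equal(adv$ci_low, 53.42, tolerance = 1e-12)
  expect_equal(adv$ci_high, 71.5, tolerance = 1e-12)

  none <- predict_travel_iop(15, 2.1, c(1.7, 2.5), 0)
  expect_equal(none$predicted_iop, 15)
  expect_equal(c(none$ci_low, none$ci_high), c(15, 15))

  round_trip <- predict_travel_iop(10, 1, c(0.5, 1.5), 1000)
  expect_equal(round_trip$predicted_iop, 20)
  expect_equal(c(round_trip$ci_low, round_trip$ci_high), c(15, 25))

  expect_error(predict_travel_iop(15, 2.1, c(1.7, 2.5), -100),
               class = "altiop_error_domain")
})

test_that("the advisory is linear in altitude change and slope", {
  a1 <- predict_travel_iop(15, 2.1, c(1.7, 2.5), 500)
  a2 <- predict_travel_iop(15, 2.1, c(1.7, 2.5), 1000)
  expect_equal(a2$delta_iop, 2 * a1$delta_iop, tolerance = 1e-12)
  b2 <- predict_travel_iop(15, 4.2, c(3.4, 5.0), 500)
  expect_equal(b2$delta_iop, 2 * a1$delta_iop, tolerance = 1e-12)
})

test_that("report writer emits the CSV dialect and a text layout", {
  tab <- extrapolation_table(rabbit_trips())
  csv <- withr::local_tempfile(fileext = ".csv")
  write_extrapolation_report(tab, csv)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_named(back, c("case", "coefficient", "intercept", "slope_per_100m",
                       "ci_low", "ci_high", "significance"))
  expect_equal(nrow(back), 24)
  txt <- withr::local_tempfile(fileext = ".txt")
  write_extrapolation_report(tab, txt, format = "text")
  expect_true(any(grepl("friedenwald", readLines(txt))))
})
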