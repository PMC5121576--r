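#' Transform a measured trip series into human-equivalent pressures
#'
#' Applies the rigidity extrapolation chain station by station: each
#' pressure's log-excursion from the eye's baseline (its first station) is
#' converted to a volume change with the source-species rigidity and back to
#' a pressure with the target rigidity, anchored at the target baseline
#' pressure. The baseline station maps exactly to the baseline pressure, and
#' with `e_source == e_target` the transform is the identity.
#'
#' @inheritParams fit_iop_altitude
#' @param e_source Source-eye (rabbit) rigidity; default the study mean
#'   `rigidity("rabbit_mean")`.
#' @param e_target Target-eye (human) rigidity, e.g. `rigidity("friedenwald")`.
#' @param baseline_iop Target baseline pressure policy: `NULL` (default) uses
#'   each eye's own first-station pressure; a single number fixes the human
#'   baseline explicitly.
#' @return A tibble with columns `eye_id`, `phase`, `altitude_m`,
#'   `human_iop_mmhg`, `baseline_mmhg`, carrying the coefficient in attribute
#'   `e_target`.
#' @examples
#' rabbit_trips() |> extrapolate_to_human(e_target = rigidity("friedenwald"))
#' @export
extrapolate_to_human <- function(trips,
                                 e_source = rigidity("rabbit_mean"),
                                 e_target,
                                 method = c("applanation", "indentation"),
                                 baseline_iop = NULL) {
  method <- match.arg(method)
  trips <- validate_trips(trips)
  col <- paste0("iop_", method, "_mmhg")
  check_positive(e_source, "e_source")
  check_positive(e_target, "e_target")
  if (!is.null(baseline_iop)) check_positive(baseline_iop, "baseline_iop")
  eyes <- unique(trips$eye_id)
  out <- purrr::map(eyes, function(eye) {
    d <- trips[trips$eye_id == eye, , drop = FALSE]
    p <- d[[col]]
    p1 <- p[1]
    target_p1 <- if (is.null(baseline_iop)) p1 else baseline_iop
    tibble(
      eye_id = eye, phase = d$phase, altitude_m = d$altitude_m,
      human_iop_mmhg = extrapolate_pressure(p1, p, e_source, e_target,
                                            p1_target = target_p1),
      baseline_mmhg = target_p1
    )
  })
  out <- dplyr::bind_rows(out)
  structure(out, class = class(tibble()),
            e_source = e_source, e_target = e_target, method = method)
}

#' Fit the altitude regression on a human-equivalent series
#'
#' Same contract as [fit_iop_altitude()] (OLS of pressure on altitude/100),
#' applied to the output of [extrapolate_to_human()].
#'
#' @param extrapolated Output of [extrapolate_to_human()].
#' @inheritParams fit_iop_altitude
#' @return An `iop_fits` tibble, one row per eye.
#' @export
fit_human_series <- function(extrapolated,
                             points = c("all", "ascent_only"),
                             conf_level = 0.95) {
  points <- match.arg(points)
  check_conf_level(conf_level)
  stopifnot(all(c("eye_id", "altitude_m", "human_iop_mmhg") %in% names(extrapolated)))
  d <- extrapolated
  if (points == "ascent_only") d <- d[d$phase == "ascent", , drop = FALSE]
  eyes <- unique(d$eye_id)
  rows <- purrr::map(eyes, function(eye) {
    di <- d[d$eye_id == eye, , drop = FALSE]
    fit <- ols_line(di$altitude_m / 100, di$human_iop_mmhg, conf_level,
                    context = sprintf("human-equivalent series of eye '%s'", eye))
    tibble(eye_id = eye, !!!fit)
  })
  new_iop_fits(dplyr::bind_rows(rows), method = "human_equivalent",
               points = points, conf_level = conf_level, data = d)
}

#' Human extrapolation report across rigidity coefficients
#'
#' For every (eye, human rigidity coefficient) combination: transforms the
#' eye's series to human-equivalent pressures, refits the altitude
#' regression, and classifies its slope against the benchmark eye under the
#' same coefficient by confidence-interval overlap.
#'
#' @inheritParams extrapolate_to_human
#' @inheritParams fit_iop_altitude
#' @param coefficients A tibble of human coefficients with columns `name`,
#'   `value`; defaults to the four shipped human coefficients (Friedenwald,
#'   Pallikaris, Dastiridou mean and max).
#' @param benchmark `eye_id` of the benchmark eye (default `"SF6_100"`).
#' @return A tibble with one row per eye and coefficient: `coefficient`,
#'   `e_target`, `eye_id`, `n`, `intercept`, `slope`, `se_slope`, `ci_low`,
#'   `ci_high`, `r_squared`, `significance`.
#' @examples
#' extrapolation_table(rabbit_trips())
#' @export
extrapolation_table <- function(trips,
                                coefficients = human_coefficients(),
                                e_source = rigidity("rabbit_mean"),
                                benchmark = "SF6_100",
                                method = c("applanation", "indentation"),
                                points = c("all", "ascent_only"),
                                conf_level = 0.95) {
  method <- match.arg(method)
  points <- match.arg(points)
  stopifnot(all(c("name", "value") %in% names(coefficients)))
  trips <- validate_trips(trips)
  if (!benchmark %in% trips$eye_id) {
    abort(sprintf("benchmark eye '%s' not present in trips", benchmark),
          class = "altiop_error_config")
  }
  rows <- purrr::map2(coefficients$name, coefficients$value, function(nm, e) {
    ex <- extrapolate_to_human(trips, e_source = e_source, e_target = e,
                               method = method)
    fits <- fit_human_series(ex, points = points, conf_level = conf_level)
    fits <- classify_significance(fits, benchmark = benchmark)
    dplyr::bind_cols(tibble(coefficient = nm, e_target = e), as_tibble(fits))
  })
  dplyr::bind_rows(rows)
}

#' @rdname extrapolation_table
#' @export
human_coefficients <- function() {
  tab <- rigidity_coefficients()
  tab[tab$name != "rabbit_mean", , drop = FALSE]
}

#' Write the extrapolation report
#'
#' Emits the report of [extrapolation_table()] as CSV
#' (`case,coefficient,intercept,slope_per_100m,ci_low,ci_high,significance`)
#' or, with `format = "text"`, as an aligned text table grouped by
#' coefficient.
#'
#' @param report Output of [extrapolation_table()].
#' @param path File to write, or `""` for stdout.
#' @param format `"csv"` or `"text"`.
#' @return `report`, invisibly.
#' @export
write_extrapolation_report <- function(report, path = "", format = c("csv", "text")) {
  format <- match.arg(format)
  if (format == "csv") {
    out <- tibble(case = report$eye_id, coefficient = report$coefficient,
                  intercept = report$intercept, slope_per_100m = report$slope,
                  ci_low = report$ci_low, ci_high = report$ci_high,
                  significance = report$significance)
    readr::write_csv(out, file = if (identical(path, "")) stdout() else path)
  } else {
    lines <- character()
    for (nm in unique(report$coefficient)) {
      d <- report[report$coefficient == nm, , drop = FALSE]
      lines <- c(lines, sprintf("Coefficient %s (E = %.4f)", nm, d$e_target[1]),
                 sprintf("  %-10s Y = %7.2f + %5.2f x   %4.2f (%.1f to %.1f)  %s",
                         d$eye_id, d$intercept, d$slope, d$slope,
                         d$ci_low, d$ci_high, d$significance), "")
    }
    if (identical(path, "")) cat(lines, sep = "\n") else writeLines(lines, path)
  }
  invisible(report)
}

#' Predict IOP after an altitude gain (travel advisory)
#'
#' Linear advisory arithmetic: the IOP change is
#' `(altitude_change / 100) * slope`, added to the baseline, with a
#' confidence band obtained by propagating the slope interval the same way.
#' For example, a patient at sea level with baseline 15 mmHg and a response
#' of 2.1 mmHg per 100 m who ascends 2260 m is predicted at
#' 15 + 22.6 x 2.1 = 62.46 mmHg.
#'
#' @param baseline_iop Baseline IOP in mmHg (positive).
#' @param slope Slope in mmHg per 100 m.
#' @param ci Length-2 numeric, the slope's confidence bounds.
#' @param altitude_change Altitude gain in metres; must be non-negative
#'   (descent advisories are out of scope).
#' @return A one-row tibble: `altitude_change_m`, `delta_iop`,
#'   `predicted_iop`, `ci_low`, `ci_high` (mmHg).
#' @examples
#' predict_travel_iop(15, 2.1, c(1.7, 2.5), 2260)
#' @export
predict_travel_iop <- function(baseline_iop, slope, ci, altitude_change) {
  check_positive(baseline_iop, "baseline_iop")
  stopifnot(is.numeric(slope), length(ci) == 2, is.numeric(altitude_change))
  if (any(altitude_change < 0)) {
    abort("`altitude_change` must be non-negative (descent advisories are out of scope)",
          class = "altiop_error_domain")
  }
  k <- altitude_change / 100
  tibble(
    altitude_change_m = altitude_change,
    delta_iop = k * slope,
    predicted_iop = baseline_iop + k * slope,
    ci_low = baseline_iop + k * min(ci),
    ci_high = baseline_iop + k * max(ci)
  )
}
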