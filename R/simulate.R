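#' The study altitude profile
#'
#' The nine-station ascent/descent profile of the road trip between Mexico
#' City and the highest point of the Puebla highway, with phase labels
#' derived from position (first five stations ascent, remainder descent).
#'
#' @param station_altitudes Ordered altitudes in metres (>= 3 stations, all
#'   positive). Default: the study's nine stations.
#' @return A tibble with `station`, `altitude_m`, `phase`.
#' @export
study_profile <- function(station_altitudes = c(2260, 2410, 2740, 3093, 3198,
                                                3090, 2740, 2420, 2260)) {
  if (length(station_altitudes) < 3 || any(station_altitudes <= 0)) {
    abort("a profile needs >= 3 positive altitudes", class = "altiop_error_config")
  }
  peak <- which.max(station_altitudes)
  tibble(
    station = seq_along(station_altitudes),
    altitude_m = as.numeric(station_altitudes),
    phase = ifelse(seq_along(station_altitudes) <= peak, "ascent", "descent")
  )
}

#' Simulate a road-trip IOP series
#'
#' Generates a trip table with the statistical structure the regression stage
#' assumes: at each station the mean IOP is
#' `baseline_iop + true_slope * (altitude - first altitude) / 100`; both
#' tonometry channels are drawn as that mean (plus `method_offset` for the
#' indentation channel) with independent additive Gaussian noise per
#' replicate, replicate-averaged, and optionally rounded to whole mmHg (the
#' tonometers read in integer mmHg). Deterministic given `seed`.
#'
#' Defaults mirror the study conditions: a baseline around 15 mmHg, a slope
#' of 1.5 mmHg per 100 m (the order of the fully gas-filled eye), triplicate
#' measurement, and integer rounding.
#'
#' @param profile A profile from [study_profile()].
#' @param true_slope Mean IOP change in mmHg per 100 m of altitude rise.
#' @param baseline_iop Mean IOP at the first station, mmHg (> 0).
#' @param noise_sd SD of the additive measurement noise per replicate, mmHg
#'   (>= 0).
#' @param rounding `"integer"` (round averaged readings to whole mmHg, the
#'   default) or `"none"`.
#' @param replicates Readings averaged per station per channel (>= 1,
#'   default 3).
#' @param method_offset Additive bias of the indentation channel relative to
#'   applanation, mmHg (default 0).
#' @param eye_id Label for the simulated eye.
#' @param seed Optional integer seed; when given, output is reproducible.
#' @return A trip tibble with the same columns as [rabbit_trips()].
#' @examples
#' simulate_trip(true_slope = 2, noise_sd = 0, rounding = "none")
#' @export
simulate_trip <- function(profile = study_profile(),
                          true_slope = 1.5,
                          baseline_iop = 15,
                          noise_sd = 1.5,
                          rounding = c("integer", "none"),
                          replicates = 3,
                          method_offset = 0,
                          eye_id = "sim",
                          seed = NULL) {
  rounding <- match.arg(rounding)
  stopifnot(is.numeric(true_slope), length(true_slope) == 1)
  check_positive(baseline_iop, "baseline_iop")
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be >= 0", class = "altiop_error_config")
  }
  if (!is.numeric(replicates) || replicates < 1) {
    abort("`replicates` must be >= 1", class = "altiop_error_config")
  }
  if (!is.null(seed)) set.seed(seed)
  mu <- baseline_iop + true_slope * (profile$altitude_m - profile$altitude_m[1]) / 100
  n <- nrow(profile)
  draw <- function(offset) {
    reps <- matrix(rnorm(n * replicates, sd = noise_sd), nrow = n)
    v <- mu + offset + rowMeans(reps)
    if (rounding == "integer") round(v) else v
  }
  tibble(
    eye_id = eye_id, phase = profile$phase, altitude_m = profile$altitude_m,
    iop_applanation_mmhg = draw(0),
    iop_indentation_mmhg = draw(method_offset),
    temperature_c = NA_real_
  )
}

#' Parameter-recovery experiment for the regression stage
#'
#' Repeatedly simulates trips, fits [fit_iop_altitude()] to each, and
#' reports the mean slope estimate together with the fraction of 95%
#' confidence intervals that contain the true slope (empirical coverage).
#'
#' @inheritParams simulate_trip
#' @param n_reps Number of simulated trips (>= 100).
#' @param conf_level Confidence level whose coverage is assessed.
#' @param seed Integer seed for the whole experiment.
#' @return A one-row tibble: `n_reps`, `true_slope`, `mean_slope_estimate`,
#'   `ci_coverage`.
#' @examples
#' recovery_experiment(n_reps = 100, seed = 1)
#' @export
recovery_experiment <- function(n_reps = 500,
                                profile = study_profile(),
                                true_slope = 1.5,
                                baseline_iop = 15,
                                noise_sd = 1.5,
                                rounding = c("integer", "none"),
                                replicates = 3,
                                method_offset = 0,
                                conf_level = 0.95,
                                seed = NULL) {
  rounding <- match.arg(rounding)
  if (n_reps < 100) {
    abort("`n_reps` must be >= 100 for a stable coverage estimate",
          class = "altiop_error_config")
  }
  if (!is.null(seed)) set.seed(seed)
  slopes <- numeric(n_reps)
  covered <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    trips <- simulate_trip(profile = profile, true_slope = true_slope,
                           baseline_iop = baseline_iop, noise_sd = noise_sd,
                           rounding = rounding, replicates = replicates,
                           method_offset = method_offset, seed = NULL)
    fit <- fit_iop_altitude(trips, conf_level = conf_level)
    slopes[i] <- fit$slope
    covered[i] <- fit$ci_low <= true_slope && true_slope <= fit$ci_high
  }
  tibble(n_reps = n_reps, true_slope = true_slope,
         mean_slope_estimate = mean(slopes), ci_coverage = mean(covered))
}
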