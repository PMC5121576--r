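#' Read a Schiotz calibration table
#'
#' A calibration table maps a Schiotz tonometer scale reading, at a given
#' plunger weight, to the true intraocular pressure and the indentation
#' volume displaced by the plunger. The CSV dialect has header
#' `weight_g,scale_reading,pressure_mmhg,volume_mm3`, sorted by
#' (weight, scale reading). Within each weight, pressure must strictly
#' decrease and indentation volume strictly increase with the scale reading,
#' and at least two readings per weight are required.
#'
#' The package ships a small synthetic table
#' (`schiotz_calibration()`) for examples and tests; it has the shape of an
#' indentation-tonometry calibration but is not a reproduction of the
#' historical Friedenwald tables, which users can supply in the same format.
#'
#' @param path Path to a calibration CSV.
#' @return A tibble with columns `weight_g`, `scale_reading`,
#'   `pressure_mmhg`, `volume_mm3`.
#' @export
read_calibration_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("calibration file not found: %s", path), class = "altiop_error_data")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("weight_g", "scale_reading", "pressure_mmhg", "volume_mm3")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    abort(sprintf("calibration CSV is missing column(s): %s",
                  paste(missing, collapse = ", ")), class = "altiop_error_data")
  }
  tab <- dplyr::arrange(tab[needed], weight_g, scale_reading)
  validate_calibration(tab)
  tab
}

#' @rdname read_calibration_csv
#' @export
schiotz_calibration <- function() {
  read_calibration_csv(
    system.file("extdata", "schiotz_calibration_synthetic.csv", package = "altiop")
  )
}

validate_calibration <- function(tab) {
  split <- split(tab, tab$weight_g)
  for (chunk in split) {
    if (nrow(chunk) < 2) {
      abort(sprintf("calibration needs >= 2 rows per weight (weight %s has %d)",
                    format(chunk$weight_g[1]), nrow(chunk)),
            class = "altiop_error_data")
    }
    if (any(chunk$pressure_mmhg <= 0)) {
      abort("calibration pressures must be positive", class = "altiop_error_data")
    }
    if (any(diff(chunk$pressure_mmhg) >= 0) || any(diff(chunk$volume_mm3) <= 0)) {
      abort(sprintf(
        "calibration for weight %s must have strictly decreasing pressure and strictly increasing volume in scale reading",
        format(chunk$weight_g[1])), class = "altiop_error_data")
    }
  }
  invisible(tab)
}

#' Interpolate pressure and indentation volume from a calibration table
#'
#' Looks up one or more scale readings at a plunger weight. Exact grid
#' readings return the tabulated values; between grid points the pressure is
#' interpolated linearly in `log10(pressure)` (Friedenwald's framework is
#' linear in log pressure, so interpolating the log keeps interpolated
#' rigidity estimates consistent) and the indentation volume linearly.
#'
#' @param calibration A calibration tibble, see [read_calibration_csv()].
#' @param weight_g Plunger weight in grams; must be present in the table.
#' @param scale_reading Scale reading(s) to look up; must lie within the
#'   tabulated range for that weight.
#' @return A tibble with columns `weight_g`, `scale_reading`,
#'   `pressure_mmhg`, `volume_mm3`.
#' @examples
#' cal <- schiotz_calibration()
#' schiotz_lookup(cal, 5.5, c(4, 4.5))
#' @export
schiotz_lookup <- function(calibration, weight_g, scale_reading) {
  validate_calibration(calibration)
  stopifnot(length(weight_g) == 1 || length(weight_g) == length(scale_reading))
  weight_g <- rep_len(weight_g, length(scale_reading))
  out <- purrr::map2(weight_g, scale_reading, function(w, s) {
    chunk <- calibration[calibration$weight_g == w, ]
    if (nrow(chunk) == 0) {
      abort(sprintf("plunger weight %s g is not in the calibration table (supported: %s)",
                    format(w), paste(unique(calibration$weight_g), collapse = ", ")),
            class = "altiop_error_range")
    }
    rng <- range(chunk$scale_reading)
    if (!is.finite(s) || s < rng[1] || s > rng[2]) {
      abort(sprintf("scale reading %s outside tabulated range [%s, %s] for weight %s g",
                    format(s), format(rng[1]), format(rng[2]), format(w)),
            class = "altiop_error_range")
    }
    p <- 10^stats::approx(chunk$scale_reading, log10(chunk$pressure_mmhg), xout = s)$y
    v <- stats::approx(chunk$scale_reading, chunk$volume_mm3, xout = s)$y
    c(pressure_mmhg = p, volume_mm3 = v)
  })
  tibble(
    weight_g = weight_g,
    scale_reading = scale_reading,
    pressure_mmhg = purrr::map_dbl(out, "pressure_mmhg"),
    volume_mm3 = purrr::map_dbl(out, "volume_mm3")
  )
}

#' Estimate scleral rigidity from paired readings at two plunger weights
#'
#' The two-weight ("tabular") method: the same eye is measured with a light
#' and a heavy plunger; each reading is converted through the calibration
#' table to a (pressure, indentation volume) pair, and the rigidity follows
#' from Friedenwald's relation
#' `E = (log10 P_heavy - log10 P_light) / (V_heavy - V_light)`.
#' The result is invariant to which reading is called light or heavy.
#'
#' Replicate readings taken at one sitting should be averaged on the
#' scale-reading axis *before* calling this function (the lookup is
#' nonlinear, so averaging after lookup gives a slightly different answer).
#'
#' @inheritParams schiotz_lookup
#' @param weight_light,reading_light Weight (g) and scale reading of the
#'   lighter plunger measurement.
#' @param weight_heavy,reading_heavy Weight (g) and scale reading of the
#'   heavier plunger measurement.
#' @return A single rigidity estimate (log10 mmHg per mm^3).
#' @examples
#' cal <- schiotz_calibration()
#' rigidity_from_two_weights(cal, 5.5, 4, 10, 4)
#' @export
rigidity_from_two_weights <- function(calibration, weight_light, reading_light,
                                      weight_heavy, reading_heavy) {
  if (isTRUE(weight_light == weight_heavy)) {
    abort("the two readings must come from different plunger weights",
          class = "altiop_error_domain")
  }
  light <- schiotz_lookup(calibration, weight_light, reading_light)
  heavy <- schiotz_lookup(calibration, weight_heavy, reading_heavy)
  dv <- heavy$volume_mm3 - light$volume_mm3
  if (any(dv == 0)) {
    abort("degenerate input: the two readings map to the same indentation volume",
          class = "altiop_error_domain")
  }
  delta_log_pressure(light$pressure_mmhg, heavy$pressure_mmhg) / dv
}

#' Mean of several rigidity estimates
#'
#' Arithmetic mean across eyes, as used to pool the per-eye two-weight
#' estimates into a single species-level coefficient.
#'
#' @param values Numeric vector of rigidity estimates; must be non-empty.
#' @return The mean rigidity.
#' @export
mean_rigidity <- function(values) {
  if (length(values) == 0) {
    abort("cannot average an empty set of rigidity estimates",
          class = "altiop_error_domain")
  }
  check_positive(values, "values")
  mean(values)
}
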