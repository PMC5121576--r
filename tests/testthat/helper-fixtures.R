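## Tiny two-weight calibration used across Schiotz tests: two rows per weight,
## chosen so looked-up (pressure, volume) pairs are easy to reason about.
toy_calibration <- function() {
  tibble::tibble(
    weight_g      = c(5.5, 5.5, 10, 10),
    scale_reading = c(3, 5, 3, 5),
    pressure_mmhg = c(20, 10, 40, 20),
    volume_mm3    = c(10, 12, 25, 28)
  )
}

## Independent closed-form OLS oracle: slope = Sxy/Sxx, intercept = ybar - b xbar.
brute_force_ols <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  b <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(intercept = yb - b * xb, slope = b)
}

## A minimal valid trip table from bare vectors.
toy_trips <- function(altitude, iop, eye = "eye1", phase = NULL) {
  if (is.null(phase)) {
    peak <- which.max(altitude)
    phase <- ifelse(seq_along(altitude) <= peak, "ascent", "descent")
  }
  tibble::tibble(eye_id = eye, phase = phase, altitude_m = altitude,
                 iop_applanation_mmhg = iop, iop_indentation_mmhg = iop,
                 temperature_c = NA_real_)
}
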