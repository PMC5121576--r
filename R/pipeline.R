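#' Analysis configuration
#'
#' Bundles the tunable choices of the full pipeline: the source-species
#' rigidity, the set of human coefficients, the confidence level, the
#' tonometry channel, the point policy, and the benchmark eye.
#'
#' @param rabbit_rigidity Source rigidity (default the study mean).
#' @param human_coefficients Tibble of `name`, `value` human coefficients.
#' @param ci_level Confidence level in (0, 1), default 0.95.
#' @param method `"applanation"` or `"indentation"`.
#' @param points `"all"` or `"ascent_only"`.
#' @param benchmark_eye Benchmark eye id, default `"SF6_100"`.
#' @return A list of class `altiop_config`.
#' @export
analysis_config <- function(rabbit_rigidity = rigidity("rabbit_mean"),
                            human_coefficients = altiop::human_coefficients(),
                            ci_level = 0.95,
                            method = c("applanation", "indentation"),
                            points = c("all", "ascent_only"),
                            benchmark_eye = "SF6_100") {
  method <- match.arg(method)
  points <- match.arg(points)
  check_conf_level(ci_level)
  check_positive(rabbit_rigidity, "rabbit_rigidity")
  structure(list(rabbit_rigidity = rabbit_rigidity,
                 human_coefficients = human_coefficients,
                 ci_level = ci_level, method = method, points = points,
                 benchmark_eye = benchmark_eye),
            class = "altiop_config")
}

#' Run the full altitude-IOP pipeline
#'
#' Composes the three analysis stages on a trip table: per-eye rabbit
#' regressions with benchmark classification, tonometry method agreement,
#' and the human extrapolation report across rigidity coefficients.
#'
#' @param trips A trip tibble.
#' @param config An [analysis_config()].
#' @return A list of class `altiop_report` with elements `rabbit_fits`,
#'   `agreement`, `human_table`, and `config`.
#' @examples
#' report <- run_pipeline(rabbit_trips())
#' report$rabbit_fits
#' @export
run_pipeline <- function(trips, config = analysis_config()) {
  if (!inherits(config, "altiop_config")) {
    abort("`config` must come from analysis_config()", class = "altiop_error_config")
  }
  trips <- validate_trips(trips)
  if (nrow(trips) == 0) {
    abort("no trip measurements supplied", class = "altiop_error_data")
  }
  if (!config$benchmark_eye %in% trips$eye_id) {
    abort(sprintf("benchmark eye '%s' not present in data", config$benchmark_eye),
          class = "altiop_error_config")
  }
  fits <- fit_iop_altitude(trips, method = config$method, points = config$points,
                           conf_level = config$ci_level)
  fits <- classify_significance(fits, benchmark = config$benchmark_eye)
  agreement <- method_agreement(trips)
  human <- extrapolation_table(trips,
                               coefficients = config$human_coefficients,
                               e_source = config$rabbit_rigidity,
                               benchmark = config$benchmark_eye,
                               method = config$method, points = config$points,
                               conf_level = config$ci_level)
  structure(list(rabbit_fits = fits, agreement = agreement,
                 human_table = human, config = config),
            class = "altiop_report")
}

#' @export
print.altiop_report <- function(x, digits = 3, ...) {
  cat("== Altitude-IOP analysis report ==\n\n")
  cat(sprintf("Channel: %s | points: %s | CI level: %.2f | benchmark: %s\n\n",
              x$config$method, x$config$points, x$config$ci_level,
              x$config$benchmark_eye))
  cat("-- Per-eye regressions (mmHg per 100 m) --\n")
  print(as_tibble(x$rabbit_fits), n = Inf)
  cat("\n-- Tonometry method agreement --\n")
  print(x$agreement, n = Inf)
  cat("\n-- Human-equivalent extrapolation --\n")
  print(x$human_table, n = Inf)
  invisible(x)
}
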