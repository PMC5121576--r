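#' Fit per-eye linear regressions of IOP on altitude
#'
#' For each eye in a trip table, fits ordinary least squares of IOP (mmHg)
#' on altitude expressed in hundreds of metres, so the slope reads directly
#' as "mmHg per 100 m of altitude rise" and the intercept is the line's value
#' at altitude 0. By default all stations (ascent and descent) enter the fit;
#' `points = "ascent_only"` restricts to the ascent leg as a sensitivity
#' analysis.
#'
#' @param trips A trip table as returned by [read_trip_csv()],
#'   [rabbit_trips()] or [simulate_trip()]: columns `eye_id`, `phase`,
#'   `altitude_m` and at least one IOP column.
#' @param method Which tonometry channel to regress: `"applanation"`
#'   (Tono-pen, the default) or `"indentation"` (Schiotz).
#' @param points `"all"` stations or `"ascent_only"`.
#' @param conf_level Confidence level for the slope interval (default 0.95).
#' @return A tibble of class `iop_fits`, one row per eye, with columns
#'   `eye_id`, `n`, `intercept`, `slope`, `se_slope`, `ci_low`, `ci_high`,
#'   `r_squared`. Slope columns are in mmHg per 100 m.
#' @examples
#' fit_iop_altitude(rabbit_trips())
#' @export
fit_iop_altitude <- function(trips,
                             method = c("applanation", "indentation"),
                             points = c("all", "ascent_only"),
                             conf_level = 0.95) {
  method <- match.arg(method)
  points <- match.arg(points)
  check_conf_level(conf_level)
  trips <- validate_trips(trips)
  col <- paste0("iop_", method, "_mmhg")
  if (points == "ascent_only") {
    trips <- trips[trips$phase == "ascent", , drop = FALSE]
  }
  eyes <- unique(trips$eye_id)
  rows <- purrr::map(eyes, function(eye) {
    d <- trips[trips$eye_id == eye, , drop = FALSE]
    keep <- is.finite(d[[col]]) & is.finite(d$altitude_m)
    d <- d[keep, , drop = FALSE]
    fit <- ols_line(d$altitude_m / 100, d[[col]], conf_level,
                    context = sprintf("eye '%s' (%s)", eye, method))
    tibble(eye_id = eye, !!!fit)
  })
  out <- dplyr::bind_rows(rows)
  new_iop_fits(out, method = method, points = points, conf_level = conf_level,
               data = trips)
}

## OLS of y on x with a t-based slope interval; the one fit engine shared by
## the rabbit and the human-extrapolated series.
ols_line <- function(x, y, conf_level, context = "series") {
  n <- length(y)
  if (n < 3) {
    abort(sprintf("need >= 3 measurements to fit %s (got %d)", context, n),
          class = "altiop_error_data")
  }
  if (length(unique(x)) < 2) {
    abort(sprintf("degenerate design: constant altitude in %s", context),
          class = "altiop_error_data")
  }
  fit <- lm(y ~ x)
  slope <- coef(fit)[[2]]
  ## slope SE and R^2 from the residuals directly (summary.lm warns on
  ## zero-residual fits, which are legitimate here for noiseless input)
  sigma2 <- sum(fit$residuals^2) / (n - 2)
  se <- sqrt(sigma2 / sum((x - mean(x))^2))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(fit$residuals^2) / ss_tot
  tq <- qt(1 - (1 - conf_level) / 2, df = n - 2)
  list(
    n = n,
    intercept = coef(fit)[[1]],
    slope = slope,
    se_slope = se,
    ci_low = slope - tq * se,
    ci_high = slope + tq * se,
    r_squared = r2
  )
}

new_iop_fits <- function(tbl, method, points, conf_level, data = NULL) {
  structure(tbl,
            class = c("iop_fits", class(tibble())),
            method = method, points = points, conf_level = conf_level,
            trip_data = data)
}

check_conf_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1 || !is.finite(level) ||
      level <= 0 || level >= 1) {
    abort("`conf_level` must be a single number in (0, 1)",
          class = "altiop_error_config")
  }
  invisible(level)
}

#' Recompute slope confidence intervals at another level
#'
#' Returns t-distribution intervals `slope +/- t(1 - alpha/2, n - 2) * se`
#' for each fitted eye, without refitting.
#'
#' @param fits An `iop_fits` table from [fit_iop_altitude()].
#' @param level Confidence level in (0, 1).
#' @return A tibble with `eye_id`, `slope`, `ci_low`, `ci_high`.
#' @export
slope_confidence_interval <- function(fits, level = 0.95) {
  check_conf_level(level)
  stopifnot(all(c("eye_id", "slope", "se_slope", "n") %in% names(fits)))
  tq <- qt(1 - (1 - level) / 2, df = fits$n - 2)
  tibble(eye_id = fits$eye_id, slope = fits$slope,
         ci_low = fits$slope - tq * fits$se_slope,
         ci_high = fits$slope + tq * fits$se_slope)
}

#' Classify slopes against a benchmark eye by confidence-interval overlap
#'
#' Marks each eye `"Sig"` if its slope confidence interval is disjoint from
#' the benchmark eye's interval, and `"NS"` if the two intervals overlap (the
#' benchmark compared with itself is trivially `"NS"`). This is the
#' CI-overlap rule used to compare altitude responses across tamponade
#' configurations, with the fully gas-filled eye as benchmark.
#'
#' @param fits An `iop_fits` table (or any tibble with `eye_id`, `ci_low`,
#'   `ci_high`).
#' @param benchmark `eye_id` of the benchmark eye (default `"SF6_100"`).
#' @return `fits` with a `significance` column added.
#' @examples
#' rabbit_trips() |> fit_iop_altitude() |> classify_significance()
#' @export
classify_significance <- function(fits, benchmark = "SF6_100") {
  stopifnot(all(c("eye_id", "ci_low", "ci_high") %in% names(fits)))
  i <- match(benchmark, fits$eye_id)
  if (is.na(i)) {
    abort(sprintf("benchmark eye '%s' not present in fits", benchmark),
          class = "altiop_error_config")
  }
  blo <- fits$ci_low[i]
  bhi <- fits$ci_high[i]
  disjoint <- fits$ci_high < blo | fits$ci_low > bhi
  fits$significance <- ifelse(disjoint, "Sig", "NS")
  fits
}

#' Agreement between the two tonometry methods
#'
#' For each eye with paired applanation and indentation readings, computes a
#' paired two-sided Wilcoxon signed-rank test (zero differences dropped,
#' mid-ranks for ties, exact null distribution for up to 25 non-zero pairs,
#' normal approximation beyond), the Pearson and Spearman correlations
#' between the two channels, and the coefficient of determination
#' (`pearson_r` squared).
#'
#' @inheritParams fit_iop_altitude
#' @return A tibble with one row per eye: `eye_id`, `n_pairs`, `wilcoxon_p`,
#'   `pearson_r`, `spearman_rho`, `r_squared`, `all_zero` (TRUE when every
#'   paired difference is zero, in which case `wilcoxon_p` is reported as 1).
#' @examples
#' method_agreement(rabbit_trips())
#' @export
method_agreement <- function(trips) {
  trips <- validate_trips(trips, require_both = TRUE)
  eyes <- unique(trips$eye_id)
  rows <- purrr::map(eyes, function(eye) {
    d <- trips[trips$eye_id == eye, , drop = FALSE]
    a <- d$iop_applanation_mmhg
    s <- d$iop_indentation_mmhg
    keep <- is.finite(a) & is.finite(s)
    a <- a[keep]; s <- s[keep]
    if (length(a) < 5) {
      abort(sprintf("need >= 5 paired measurements for eye '%s' (got %d)",
                    eye, length(a)), class = "altiop_error_data")
    }
    w <- signed_rank_test(a, s)
    r <- cor(a, s)
    tibble(eye_id = eye, n_pairs = length(a),
           wilcoxon_p = w$p, pearson_r = r,
           spearman_rho = cor(a, s, method = "spearman"),
           r_squared = r^2, all_zero = w$all_zero)
  })
  dplyr::bind_rows(rows)
}

## Paired two-sided Wilcoxon signed-rank test. Zeros dropped, mid-ranks for
## ties. Exact p for n <= 25 via dynamic-programming convolution of the null
## distribution of the positive-rank sum over doubled ranks (doubling makes
## mid-ranks integral); normal approximation with tie correction otherwise.
signed_rank_test <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(p = 1, all_zero = TRUE, statistic = NA_real_))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25) {
    s <- as.integer(round(2 * r))      # doubled mid-ranks are integers
    total <- sum(s)
    dist <- c(1, rep(0, total))        # dist[k+1] = #subsets with doubled sum k
    for (si in s) {
      shifted <- c(rep(0, si), dist[seq_len(total + 1 - si)])
      dist <- dist + shifted
    }
    probs <- dist / 2^n
    w2 <- round(2 * w)
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[seq.int(w2 + 1, total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(p = p, all_zero = FALSE, statistic = w)
}

#' @export
tidy.iop_fits <- function(x, ...) {
  dplyr::bind_rows(
    tibble(eye_id = x$eye_id, term = "intercept", estimate = x$intercept),
    tibble(eye_id = x$eye_id, term = "slope_per_100m", estimate = x$slope,
           std.error = x$se_slope, conf.low = x$ci_low, conf.high = x$ci_high)
  ) |> dplyr::arrange(match(eye_id, x$eye_id))
}

#' @export
glance.iop_fits <- function(x, ...) {
  tibble(eye_id = x$eye_id, r.squared = x$r_squared, nobs = x$n,
         conf.level = attr(x, "conf_level"), points = attr(x, "points"))
}

#' @export
print.iop_fits <- function(x, ...) {
  cat(sprintf("IOP ~ altitude OLS fits (%s, %s stations, %.0f%% CI)\n",
              attr(x, "method") %||% "iop", attr(x, "points") %||% "all",
              100 * (attr(x, "conf_level") %||% 0.95)))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
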