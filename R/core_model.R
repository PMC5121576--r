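#' Friedenwald pressure-volume relations
#'
#' Friedenwald's model of the eye wall states that intraocular volume and the
#' base-10 logarithm of intraocular pressure are linearly related, with a
#' per-eye constant of proportionality `E` (the ocular, or scleral, rigidity):
#' `E = (log10 P2 - log10 P1) / (V2 - V1)`, with pressure in mmHg and volume
#' in mm^3. These helpers expose each leg of that relation in vectorised form.
#'
#' `delta_log_pressure()` returns `log10(p2) - log10(p1)`.
#' `volume_change()` converts a log-pressure change to the volume change that
#' produced it, `dlog / rigidity`. `log_change_from_volume()` is its exact
#' inverse, `dv * rigidity`. `pressure_ratio()` maps a log-pressure change back
#' to the dimensionless pressure ratio `P2/P1 = 10^dlog`.
#'
#' @param p1,p2 Pressures in mmHg; must be strictly positive.
#' @param dlog A change in log10 pressure (dimensionless log units).
#' @param dv An intraocular volume change in mm^3.
#' @param rigidity A scleral rigidity coefficient in log10(mmHg) per mm^3;
#'   must be strictly positive. See [rigidity_coefficients()].
#' @return A numeric vector.
#' @examples
#' delta_log_pressure(16, 32)                     # 0.30103
#' volume_change(0.30103, 0.01811667)             # ~16.6 mm^3
#' pressure_ratio(log_change_from_volume(16.6, 0.0215))
#' @name friedenwald
NULL

check_positive <- function(x, what) {
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    abort(
      sprintf("`%s` must be positive and finite; offending value(s): %s",
              what, paste(format(x[bad]), collapse = ", ")),
      class = "altiop_error_domain"
    )
  }
  invisible(x)
}

#' @rdname friedenwald
#' @export
delta_log_pressure <- function(p1, p2) {
  check_positive(p1, "p1")
  check_positive(p2, "p2")
  log10(p2) - log10(p1)
}

#' @rdname friedenwald
#' @export
volume_change <- function(dlog, rigidity) {
  stopifnot(is.numeric(dlog), all(is.finite(dlog)))
  check_positive(rigidity, "rigidity")
  dlog / rigidity
}

#' @rdname friedenwald
#' @export
log_change_from_volume <- function(dv, rigidity) {
  stopifnot(is.numeric(dv), all(is.finite(dv)))
  check_positive(rigidity, "rigidity")
  dv * rigidity
}

#' @rdname friedenwald
#' @export
pressure_ratio <- function(dlog) {
  stopifnot(is.numeric(dlog), all(is.finite(dlog)))
  10^dlog
}

#' Extrapolate a pressure change across eyes of different rigidity
#'
#' Carries an observed pressure excursion in one eye over to an eye with a
#' different scleral rigidity, holding the intraocular volume change fixed.
#' The observed `log10(p2/p1)` is converted to a volume change with the source
#' rigidity, converted back to a log-pressure change with the target rigidity,
#' and applied to the target eye's baseline pressure:
#'
#' `p1_target * 10^( e_target * (log10(p2/p1) / e_source) )`
#'
#' With `e_source == e_target` and `p1_target == p1` this is the identity and
#' returns `p2` exactly. This is the chain used to turn rabbit altitude
#' excursions into human-equivalent pressures.
#'
#' @param p1,p2 Source-eye baseline and excursion pressures (mmHg, positive).
#' @param e_source,e_target Scleral rigidity of the source and target eye
#'   (log10 mmHg per mm^3, positive).
#' @param p1_target Baseline pressure of the target eye (mmHg); defaults to
#'   the source baseline `p1`.
#' @return Target-eye pressure(s) in mmHg.
#' @examples
#' # a doubling seen in a rabbit eye, mapped to the average human eye
#' extrapolate_pressure(16, 32, e_source = 0.01811667, e_target = 0.0215)
#' @export
extrapolate_pressure <- function(p1, p2, e_source, e_target, p1_target = p1) {
  check_positive(p1_target, "p1_target")
  check_positive(e_source, "e_source")
  check_positive(e_target, "e_target")
  dlog <- delta_log_pressure(p1, p2)
  p1_target * pressure_ratio(log_change_from_volume(volume_change(dlog, e_source), e_target))
}

#' Scleral rigidity coefficients
#'
#' Loads the package's table of named scleral rigidity coefficients from its
#' JSON configuration (or from a user-supplied file in the same format: a flat
#' JSON object of `name: value` pairs). Shipped values are the study-eye mean
#' rabbit rigidity (`rabbit_mean`, 0.01811667) and four published human
#' coefficients: Friedenwald's classic average 0.0215, Pallikaris 0.0126, and
#' the Dastiridou mean 0.0224 and maximum 0.0343. Units are log10(mmHg) per
#' mm^3 of intraocular volume.
#'
#' @param path Optional path to a JSON file of coefficients; defaults to the
#'   configuration shipped with the package.
#' @return A tibble with columns `name` and `value`, ordered as in the file.
#' @examples
#' rigidity_coefficients()
#' @export
rigidity_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rigidity_coefficients.json", package = "altiop")
  }
  if (!file.exists(path)) {
    abort(sprintf("rigidity configuration not found: %s", path),
          class = "altiop_error_config")
  }
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- unlist(vals)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    abort("rigidity coefficients must be positive finite numbers",
          class = "altiop_error_config")
  }
  tibble(name = names(vals), value = unname(vals))
}

#' Look up one rigidity coefficient by name
#'
#' @param name Coefficient name, e.g. `"friedenwald"` or `"rabbit_mean"`.
#' @inheritParams rigidity_coefficients
#' @return A single numeric value.
#' @export
rigidity <- function(name, path = NULL) {
  tab <- rigidity_coefficients(path)
  i <- match(name, tab$name)
  if (anyNA(i)) {
    abort(sprintf("unknown rigidity coefficient(s): %s (available: %s)",
                  paste(name[is.na(i)], collapse = ", "),
                  paste(tab$name, collapse = ", ")),
          class = "altiop_error_config")
  }
  tab$value[i]
}
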