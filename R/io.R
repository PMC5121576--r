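#' Read and write trip measurement tables
#'
#' The trip CSV dialect has header
#' `eye_id,phase,altitude_m,iop_applanation_mmhg,iop_indentation_mmhg,temperature_c`,
#' one row per station, stations in travel order within each eye. Pressures
#' are mmHg, altitude is metres above sea level, temperature is optional and
#' unused by the analysis. Malformed rows are reported with their line
#' numbers; non-positive pressures or altitudes are rejected.
#'
#' @param path Path to a trip CSV.
#' @return A validated trip tibble (empty, with a warning, for an empty or
#'   header-only file).
#' @examples
#' trips <- read_trip_csv(system.file("extdata", "rabbit_trip.csv", package = "altiop"))
#' dplyr::count(trips, eye_id)
#' @export
read_trip_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("trip file not found: %s", path), class = "altiop_error_data")
  }
  if (file.size(path) == 0) {
    warn(sprintf("trip file is empty: %s", path))
    return(empty_trips())
  }
  ## readr warns when it finds parse problems; we inspect problems() below
  ## and promote them to errors with line numbers, so the warning is noise
  tab <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           eye_id = readr::col_character(),
                           phase = readr::col_character(),
                           .default = readr::col_double()
                         )))
  missing <- setdiff(trip_columns(), names(tab))
  if (length(missing)) {
    abort(sprintf("trip CSV is missing column(s): %s",
                  paste(missing, collapse = ", ")), class = "altiop_error_data")
  }
  prob <- readr::problems(tab)
  if (nrow(prob) > 0) {
    abort(sprintf("malformed trip CSV rows (file line, issue): %s",
                  paste(sprintf("line %d: expected %s", prob$row + 1, prob$expected),
                        collapse = "; ")),
          class = "altiop_error_data")
  }
  if (nrow(tab) == 0) return(empty_trips())
  validate_trips(tab[trip_columns()], path = path)
}

trip_columns <- function() {
  c("eye_id", "phase", "altitude_m", "iop_applanation_mmhg",
    "iop_indentation_mmhg", "temperature_c")
}

empty_trips <- function() {
  tibble(eye_id = character(), phase = character(), altitude_m = numeric(),
         iop_applanation_mmhg = numeric(), iop_indentation_mmhg = numeric(),
         temperature_c = numeric())
}

#' @rdname read_trip_csv
#' @param trips A trip tibble.
#' @export
write_trip_csv <- function(trips, path) {
  trips <- validate_trips(trips)
  readr::write_csv(trips[trip_columns()], path, na = "")
  invisible(trips)
}

## Shared structural validation: columns, types, positivity; row numbers
## (within the frame / file) are named in errors.
validate_trips <- function(trips, require_both = FALSE, path = NULL) {
  trips <- as_tibble(trips)
  if (!"temperature_c" %in% names(trips)) trips$temperature_c <- NA_real_
  missing <- setdiff(trip_columns(), names(trips))
  if (length(missing)) {
    abort(sprintf("trip table is missing column(s): %s",
                  paste(missing, collapse = ", ")), class = "altiop_error_data")
  }
  where <- if (is.null(path)) "row" else sprintf("%s line", basename(path))
  offset <- if (is.null(path)) 0 else 1   # header line in a file
  bad_alt <- which(!is.finite(trips$altitude_m) | trips$altitude_m <= 0)
  if (length(bad_alt)) {
    abort(sprintf("non-positive or non-numeric altitude at %s %s", where,
                  paste(bad_alt + offset, collapse = ", ")),
          class = "altiop_error_data")
  }
  for (col in c("iop_applanation_mmhg", "iop_indentation_mmhg")) {
    bad <- which(!is.na(trips[[col]]) & trips[[col]] <= 0)
    if (length(bad)) {
      abort(sprintf("non-positive %s at %s %s", col, where,
                    paste(bad + offset, collapse = ", ")),
            class = "altiop_error_data")
    }
  }
  if (require_both) {
    ok <- is.finite(trips$iop_applanation_mmhg) & is.finite(trips$iop_indentation_mmhg)
    if (!any(ok)) {
      abort("no stations with both tonometry channels present",
            class = "altiop_error_data")
    }
  }
  bad_phase <- which(!trips$phase %in% c("ascent", "descent"))
  if (length(bad_phase)) {
    abort(sprintf("phase must be 'ascent' or 'descent' at %s %s", where,
                  paste(bad_phase + offset, collapse = ", ")),
          class = "altiop_error_data")
  }
  trips
}

#' The packaged rabbit road-trip measurements
#'
#' The study's six-eye trip table: for each eye, nine stations (five ascent,
#' four descent) between 2260 m and 3198 m with IOP by both tonometry
#' methods. Eyes are labelled by tamponade configuration: `SF6_100`,
#' `SF6_50`, `SF6_25` (vitrectomy + 100/50/25% fill with nonexpansile 18%
#' SF6), `Air_100` (vitrectomy + room air), `BSS` (vitrectomy + saline,
#' control), and `Pneum` (no vitrectomy, 0.35 cc undiluted SF6, mimicking
#' pneumatic retinopexy).
#'
#' @return A trip tibble of 54 rows (6 eyes x 9 stations).
#' @examples
#' rabbit_trips()
#' @export
rabbit_trips <- function() {
  read_trip_csv(system.file("extdata", "rabbit_trip.csv", package = "altiop"))
}

#' The experimental eye configurations
#'
#' One row per study eye: whether it was vitrectomized, the tamponade agent,
#' and either the vitreous-cavity fill fraction or, for the non-vitrectomized
#' eye, the injected bubble volume.
#'
#' @return A tibble with `eye_id`, `vitrectomized`, `tamponade`,
#'   `fill_fraction`, `injected_volume_cc`.
#' @export
rabbit_eyes <- function() {
  tibble(
    eye_id = c("SF6_100", "SF6_50", "SF6_25", "Air_100", "BSS", "Pneum"),
    vitrectomized = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    tamponade = c("SF6_18pct", "SF6_18pct", "SF6_18pct", "room_air", "BSS",
                  "SF6_100pct_no_vitrectomy"),
    fill_fraction = c(1, 0.5, 0.25, 1, 1, NA),
    injected_volume_cc = c(NA, NA, NA, NA, NA, 0.35)
  )
}
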