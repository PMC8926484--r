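#' Fit per-marker log-log calibration curves
#'
#' Chromatographic detector response over a wide injection range is well
#' described by a power law, so calibration regresses the natural logarithm
#' of peak area on the natural logarithm of injected mass (µg) by ordinary
#' least squares, one curve per marker: `ln(area) = intercept + slope·ln(mass)`.
#' R² is the squared Pearson correlation of the ln-transformed points.
#'
#' @param data Data frame of calibration points with columns `mass_ug` and
#'   `area`, and a `marker` column when fitting several markers at once.
#' @param marker Optional single marker name when `data` has no `marker`
#'   column.
#' @return A tibble of class `herbqc_calibration` with one row per marker:
#'   `marker`, `slope`, `intercept`, `r2`, `range_low_ug`, `range_high_ug`,
#'   `n`. The linear range is the span of the fitted masses.
#' @examples
#' pts <- data.frame(mass_ug = c(2, 5, 10, 18),
#'                   area = exp(5.7314 + 0.9781 * log(c(2, 5, 10, 18))))
#' fit_calibration(pts, marker = "D")
#' @export
fit_calibration <- function(data, marker = NULL) {
  data <- as_tibble(data)
  for (col in c("mass_ug", "area")) {
    if (!col %in% names(data)) {
      stop_format(sprintf("calibration data needs column `%s`.", col))
    }
  }
  if (!"marker" %in% names(data)) {
    data$marker <- if (is.null(marker)) "marker" else marker
  }
  out <- data |>
    dplyr::group_by(.data$marker) |>
    dplyr::group_modify(~ fit_one_curve(.x)) |>
    dplyr::ungroup()
  class(out) <- c("herbqc_calibration", class(out))
  out
}

fit_one_curve <- function(df) {
  if (nrow(df) < 3) {
    stop_insufficient("need at least 3 calibration points per marker.")
  }
  check_positive(df$mass_ug, "mass_ug")
  check_positive(df$area, "area")
  lx <- log(df$mass_ug)
  ly <- log(df$area)
  fit <- lm(ly ~ lx)
  cf <- coef(fit)
  r2 <- cor(lx, ly)^2
  tibble(
    slope = unname(cf[2]), intercept = unname(cf[1]), r2 = r2,
    range_low_ug = min(df$mass_ug), range_high_ug = max(df$mass_ug),
    n = nrow(df))
}

get_curve <- function(curves, marker) {
  if (is.null(marker)) {
    if (nrow(curves) != 1) {
      stop_validation("`marker` must be given when several curves are present.")
    }
    return(curves[1, ])
  }
  row <- curves[curves$marker == marker, ]
  if (nrow(row) != 1) stop_validation(sprintf("no curve for marker %s.", marker))
  row
}

#' Predict peak area from injected mass
#'
#' Evaluates the fitted power-law response `exp(intercept)·mass^slope`.
#' A mass outside the fitted linear range triggers a warning, not an error:
#' single injections routinely bracket the range ends.
#'
#' @param curves A `herbqc_calibration` tibble from [fit_calibration()], or
#'   any data frame with columns `marker`, `slope`, `intercept` (and
#'   optionally `range_low_ug`/`range_high_ug`).
#' @param mass_ug Injected mass in µg (vectorised, all > 0).
#' @param marker Which curve to use (may be omitted for a single curve).
#' @return Numeric vector of predicted areas.
#' @export
predict_area <- function(curves, mass_ug, marker = NULL) {
  check_positive(mass_ug, "mass_ug")
  cv <- get_curve(curves, marker)
  if (all(c("range_low_ug", "range_high_ug") %in% names(cv))) {
    out_of_range <- mass_ug < cv$range_low_ug | mass_ug > cv$range_high_ug
    if (any(out_of_range)) {
      warn(sprintf("%d mass value(s) outside the linear range [%.3g, %.3g] ug.",
                   sum(out_of_range), cv$range_low_ug, cv$range_high_ug),
           class = "herbqc_range_warning")
    }
  }
  exp(cv$intercept + cv$slope * log(mass_ug))
}

#' Invert a calibration curve: peak area to injected mass
#'
#' The exact inverse of [predict_area()]:
#' `mass = exp((ln(area) − intercept)/slope)`.
#'
#' @inheritParams predict_area
#' @param area Peak area (vectorised, all > 0).
#' @return Numeric vector of injected masses in µg.
#' @export
invert_area <- function(curves, area, marker = NULL) {
  check_positive(area, "area")
  cv <- get_curve(curves, marker)
  exp((log(area) - cv$intercept) / cv$slope)
}

#' Write / read calibration curves as CSV
#'
#' @param x A `herbqc_calibration` tibble.
#' @param path File path.
#' @export
write_calibration <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(marker = readr::col_character()))
  class(out) <- c("herbqc_calibration", class(out))
  out
}

#' @export
tidy.herbqc_calibration <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "herbqc_calibration")
  out
}

#' @export
glance.herbqc_calibration <- function(x, ...) {
  tibble(n_markers = nrow(x), min_r2 = min(x$r2), max_r2 = max(x$r2),
         n_points = sum(x$n))
}
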