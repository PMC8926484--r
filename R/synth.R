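# Synthetic-data generator. Emulates the study design the package is meant
# for: a mixed reference solution of four triterpene-saponin markers injected
# at 3/5/10/15/20/25/30 ul, replicate sample injections of an extract, and
# batch fingerprints of 11 common peaks. Detector response per marker is a
# power law (log-log linear); injection noise is multiplicative Gaussian with
# a stated CV; batches differ by a total-content scale and a per-peak shape
# perturbation. Every draw is governed by one seed in the config.

#' The built-in four-marker panel
#'
#' Reference concentrations (mg/ml), common-peak positions (5, 8, 9, 10 of
#' 11), linear ranges (µg) and true power-law response parameters for the
#' four saponin markers D, A, F and B9, together with nominal retention
#' times used for peak assignment.
#'
#' @return A marker tibble (see [read_markers()]) with extra columns
#'   `slope`, `intercept`, `rt`.
#' @export
default_markers <- function() {
  tibble(
    name = c("D", "A", "F", "B9"),
    ref_conc_mg_ml = c(0.614, 0.242, 0.496, 0.385),
    common_peak_index = c(5L, 8L, 9L, 10L),
    linear_low_ug = c(1.84, 0.73, 1.49, 1.16),
    linear_high_ug = c(18.42, 7.26, 14.88, 11.55),
    slope = c(0.9781, 0.9925, 1.0209, 1.0403),
    intercept = c(5.7314, 6.1778, 5.7846, 5.4396),
    rt = default_peak_rts(11)[c(5, 8, 9, 10)])
}

default_peak_rts <- function(n_common) {
  base <- c(6.8, 11.2, 15.4, 19.9, 24.6, 29.3, 34.8, 40.2, 46.5, 52.9, 60.1)
  if (n_common == 11) base else seq(6, 66, length.out = n_common)
}

default_base_profile <- function(n_common) {
  base <- c(520, 860, 1240, 930, 3560, 640, 780, 620, 1830, 1310, 410)
  rep_len(base, n_common)
}

#' Configure the synthetic-data generator
#'
#' Defaults reproduce the study conditions the generators emulate: seven
#' injection volumes spanning the linear range, ~0.5% multiplicative area
#' noise (the observed precision band), five batches of eleven common peaks
#' with markers at positions 5/8/9/10, batch total-content scales spanning
#' roughly 0.5–1.2 (the observed spread of macro-quantitative similarity),
#' and a 5% per-peak shape perturbation.
#'
#' @param markers Marker tibble with `slope`, `intercept`, `rt` columns
#'   (default [default_markers()]).
#' @param volumes_ul Injection volumes for the reference series (µl).
#' @param noise_cv Multiplicative area noise, as a fraction (CV).
#' @param n_batches Number of batches in the fingerprint matrix.
#' @param n_common Common peaks per fingerprint (default 11).
#' @param batch_scales Per-batch total-content multipliers (recycled).
#' @param shape_noise_cv Per-peak profile perturbation CV (fraction).
#' @param base_profile Positive base areas of the `n_common` peaks; default
#'   a fixed 11-peak profile with the strongest peak at position 5.
#' @param sample_conc_ug_ul Sample solution concentration (µg/µl); the
#'   default 2 corresponds to a 20 mg / 10 ml preparation, i.e. a 40 µg
#'   load at 20 µl.
#' @param true_content_pct Named vector of true marker contents (% w/w)
#'   used for sample injections.
#' @param seed Integer seed fixing every random draw.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(markers = default_markers(),
                         volumes_ul = c(3, 5, 10, 15, 20, 25, 30),
                         noise_cv = 0.005,
                         n_batches = 5,
                         n_common = 11,
                         batch_scales = c(0.92, 0.54, 1.05, 1.17, 1.04),
                         shape_noise_cv = 0.05,
                         base_profile = NULL,
                         sample_conc_ug_ul = 2,
                         true_content_pct = c(D = 19.05, A = 2.07,
                                              F = 9.91, B9 = 9.97),
                         seed = 20220309) {
  markers <- validate_markers(markers)
  for (col in c("slope", "intercept", "rt")) {
    if (!col %in% names(markers)) {
      stop_config(sprintf("synthetic markers need a `%s` column.", col))
    }
  }
  check_positive(volumes_ul, "volumes_ul")
  check_nonnegative(noise_cv, "noise_cv")
  check_nonnegative(shape_noise_cv, "shape_noise_cv")
  if (!is.numeric(n_batches) || n_batches < 1) stop_config("`n_batches` must be >= 1.")
  if (!is.numeric(n_common) || n_common < max(markers$common_peak_index)) {
    stop_config("`n_common` must be at least the largest marker peak index.")
  }
  check_positive(batch_scales, "batch_scales")
  batch_scales <- rep_len(batch_scales, n_batches)
  if (is.null(base_profile)) base_profile <- default_base_profile(n_common)
  if (length(base_profile) != n_common) {
    stop_config("`base_profile` must have `n_common` entries.")
  }
  check_positive(base_profile, "base_profile")
  check_positive(sample_conc_ug_ul, "sample_conc_ug_ul")
  check_positive(true_content_pct, "true_content_pct")
  if (!all(markers$name %in% names(true_content_pct))) {
    stop_config("`true_content_pct` must name every marker.")
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_config("`seed` must be a single integer.")
  }
  structure(list(markers = markers, volumes_ul = volumes_ul,
                 noise_cv = noise_cv, n_batches = as.integer(n_batches),
                 n_common = as.integer(n_common), batch_scales = batch_scales,
                 shape_noise_cv = shape_noise_cv, base_profile = base_profile,
                 sample_conc_ug_ul = sample_conc_ug_ul,
                 true_content_pct = true_content_pct,
                 seed = as.integer(seed)),
            class = "synth_config")
}

response_area <- function(markers, mass_ug) {
  exp(markers$intercept) * mass_ug^markers$slope
}

#' Generate a mixed-reference injection series
#'
#' One peak table per injection volume: each marker's on-column mass is
#' `ref_conc × volume` and its area follows the marker's power-law response
#' times multiplicative noise `(1 + ε)`, `ε ~ N(0, noise_cv²)`.
#'
#' @param cfg A [synth_config()].
#' @return Named list of [peak_table()] objects (`ref_3ul`, `ref_5ul`, ...).
#' @export
gen_reference_series <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    out <- lapply(cfg$volumes_ul, function(v) {
      mass <- cfg$markers$ref_conc_mg_ml * v
      mu <- response_area(cfg$markers, mass)
      area <- mu * (1 + rnorm(length(mu), 0, cfg$noise_cv))
      peak_table(tibble(peak_id = cfg$markers$common_peak_index,
                        rt = cfg$markers$rt, area = area),
                 injection_id = sprintf("ref_%gul", v), volume_ul = v)
    })
    setNames(out, sprintf("ref_%gul", cfg$volumes_ul))
  })
}

#' Tabulate a reference series for calibration fitting
#'
#' Assigns each marker its peak in every injection (by retention time) and
#' attaches the known on-column mass, giving the `marker`/`mass_ug`/`area`
#' table [fit_calibration()] expects.
#'
#' @param series Output of [gen_reference_series()] (or any named list of
#'   peak tables with `volume_ul` attributes).
#' @param cfg The [synth_config()] that produced it.
#' @param rt_tolerance Minutes, default 0.2.
#' @return Tibble: `injection_id`, `volume_ul`, `marker`, `mass_ug`, `area`.
#' @export
reference_calibration_data <- function(series, cfg, rt_tolerance = 0.2) {
  purrr::map_dfr(series, function(t) {
    v <- attr(t, "volume_ul")
    hits <- assign_markers(t, cfg$markers, rt_tolerance)
    dplyr::mutate(hits,
                  injection_id = attr(t, "injection_id"), volume_ul = v,
                  mass_ug = cfg$markers$ref_conc_mg_ml[
                    match(.data$marker, cfg$markers$name)] * v) |>
      dplyr::select("injection_id", "volume_ul", "marker", "mass_ug", "area")
  })
}

#' Generate replicate sample injections
#'
#' Sample injections of an extract with known true marker contents: marker
#' mass on column is `content/100 × sample_conc × volume`, areas follow the
#' same response model and noise as the reference series.
#'
#' @param cfg A [synth_config()].
#' @param n_injections Number of replicate injections (default 6).
#' @param volume_ul Injection volume (default 20).
#' @return Named list of [peak_table()] objects.
#' @export
gen_sample_injections <- function(cfg, n_injections = 6, volume_ul = 20) {
  stopifnot(inherits(cfg, "synth_config"))
  load_ug <- cfg$sample_conc_ug_ul * volume_ul
  content <- cfg$true_content_pct[cfg$markers$name]
  with_seed(cfg$seed + 1L, {
    out <- lapply(seq_len(n_injections), function(i) {
      mass <- unname(content) / 100 * load_ug
      mu <- response_area(cfg$markers, mass)
      area <- mu * (1 + rnorm(length(mu), 0, cfg$noise_cv))
      peak_table(tibble(peak_id = cfg$markers$common_peak_index,
                        rt = cfg$markers$rt, area = area),
                 injection_id = sprintf("sample_%d", i), volume_ul = volume_ul)
    })
    setNames(out, sprintf("sample_%d", seq_len(n_injections)))
  })
}

#' Generate a batch fingerprint matrix with known ground truth
#'
#' Batch `b`'s profile is `base_profile × batch_scales[b] × (1 + δ_i)` with
#' per-peak shape noise `δ_i ~ N(0, shape_noise_cv²)`. With zero shape noise
#' every batch is proportional to the base profile, so macro-qualitative
#' similarity is exactly 1 and the projection content against the average
#' reference fingerprint is `100 × scale_b / mean(scales)` — recorded in the
#' returned ground truth.
#'
#' @param cfg A [synth_config()].
#' @return List with `fingerprints` (a [fingerprint_matrix()]) and `truth`
#'   (list: `base_profile`, `batch_scales`, `expected_c_pct`).
#' @export
gen_fingerprints <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_batches < 2) stop_config("`n_batches` must be >= 2 for fingerprints.")
  with_seed(cfg$seed + 2L, {
    rows <- t(vapply(seq_len(cfg$n_batches), function(b) {
      # clamp the multiplicative factor: areas stay positive even at large CVs
      cfg$base_profile * cfg$batch_scales[b] *
        pmax(1 + rnorm(cfg$n_common, 0, cfg$shape_noise_cv), 0.01)
    }, numeric(cfg$n_common)))
  })
  colnames(rows) <- paste0("p", seq_len(cfg$n_common))
  fm <- fingerprint_matrix(
    dplyr::bind_cols(tibble(batch_id = paste0("batch", seq_len(cfg$n_batches))),
                     as_tibble(rows)),
    rt = default_peak_rts(cfg$n_common))
  list(fingerprints = fm,
       truth = list(base_profile = cfg$base_profile,
                    batch_scales = cfg$batch_scales,
                    expected_c_pct = 100 * cfg$batch_scales /
                      mean(cfg$batch_scales)))
}
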