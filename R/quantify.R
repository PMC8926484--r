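#' Relative correction factor between a component and the internal reference
#'
#' The relative correction factor (RCF) `f_ks` links component `s` to the
#' internal reference standard (IRS) `k` through the ratio of their
#' mass-normalised responses:
#' `f_ks = (W_k · A_s) / (W_s · A_k)`,
#' where `W` is the injected amount (µg) and `A` the peak area. Once
#' established, the RCF lets the amount of `s` be computed from the IRS
#' calibration alone.
#'
#' @param w_k Amount of the IRS on column (µg).
#' @param a_k Peak area of the IRS.
#' @param w_s Amount of component `s` (µg).
#' @param a_s Peak area of component `s`.
#' @return The dimensionless RCF (vectorised).
#' @examples
#' compute_rcf(w_k = 12.28, a_k = 3571.0, w_s = 9.92, a_s = 3332.7)
#' @export
compute_rcf <- function(w_k, a_k, w_s, a_s) {
  check_positive(w_k, "w_k"); check_positive(a_k, "a_k")
  check_positive(w_s, "w_s"); check_positive(a_s, "a_s")
  (w_k * a_s) / (w_s * a_k)
}

#' Summarise replicate relative correction factors
#'
#' Takes per-replicate RCFs (one row per injection or instrument/column
#' combination, one numeric column per component) and reports the mean and
#' the sample relative standard deviation (n−1 denominator) per component —
#' the durability summary used to judge whether correction factors transfer
#' across injection volumes, instruments and columns.
#'
#' @param data Data frame: optional label column(s) (non-numeric) plus one
#'   numeric column of RCF values per component.
#' @param irs Name of the internal reference standard (stored as attribute).
#' @return A tibble of class `rcf_summary`: `component`, `n`, `mean`, `sd`,
#'   `rsd_pct`.
#' @examples
#' rcf_summary(data.frame(f_A = c(1.62, 1.59, 1.63, 1.61, 1.63, 1.66, 1.66)))
#' @export
rcf_summary <- function(data, irs = NULL) {
  data <- as_tibble(data)
  num <- data[vapply(data, is.numeric, logical(1))]
  if (ncol(num) == 0) stop_format("no numeric RCF columns found.")
  if (nrow(num) < 2) stop_insufficient("need at least 2 replicates.")
  if (anyNA(num)) {
    stop_consistency("replicates do not share the same component set (missing values).")
  }
  for (col in names(num)) check_positive(num[[col]], col)
  out <- tidyr::pivot_longer(num, dplyr::everything(),
                             names_to = "component", values_to = "f") |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$f), sd = sd(.data$f),
                     rsd_pct = 100 * sd(.data$f) / mean(.data$f),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$component, names(num)))
  attr(out, "irs") <- irs
  class(out) <- c("rcf_summary", class(out))
  out
}

#' Replicate summary statistics (mean, SD, RSD%)
#'
#' The workhorse of chromatographic method validation: the sample mean,
#' sample standard deviation (n−1) and relative standard deviation
#' `100·sd/mean` of replicate measurements — precision (repeated injection),
#' repeatability (parallel preparations) and stability (time series) all
#' reduce to this summary.
#'
#' @param values Numeric vector, length ≥ 2.
#' @return One-row tibble: `n`, `mean`, `sd`, `rsd_pct`.
#' @examples
#' replicate_summary(c(3562.5, 3559.8, 3578.2, 3546.3, 3585.6, 3593.4))
#' @export
replicate_summary <- function(values) {
  if (!is.numeric(values) || length(values) < 2) {
    stop_insufficient("need at least 2 values.")
  }
  if (anyNA(values)) stop_domain("`values` must be non-missing.")
  tibble(n = length(values), mean = mean(values), sd = sd(values),
         rsd_pct = 100 * sd(values) / mean(values))
}

#' Content by the external standard method (single point)
#'
#' Classical one-point external standardisation at matched injection volume:
#' the analyte content (% w/w of the sample load) is the area ratio of the
#' sample peak to the reference peak, scaled by the reference mass on column
#' over the sample mass on column.
#'
#' @param a_sample Peak area of the analyte in the sample injection.
#' @param a_ref Peak area of the analyte in the reference injection.
#' @param m_ref_ug Reference mass on column (µg).
#' @param m_sample_ug Sample load on column (µg); the default study design
#'   injects 20 µl of a 20 mg / 10 ml solution, i.e. 40 µg.
#' @return Content in % w/w (vectorised).
#' @export
esm_content <- function(a_sample, a_ref, m_ref_ug, m_sample_ug = 40) {
  check_positive(a_sample, "a_sample"); check_positive(a_ref, "a_ref")
  check_positive(m_ref_ug, "m_ref_ug"); check_positive(m_sample_ug, "m_sample_ug")
  100 * (a_sample / a_ref) * (m_ref_ug / m_sample_ug)
}

#' Content by QAMS (single-marker quantification)
#'
#' Computes the amount of component `s` from the IRS amount and the relative
#' correction factor, `W_s = (W_k · A_s) / (f_ks · A_k)`, then expresses it
#' as % w/w of the sample load. With `s = k` (so `f = 1`, `a_s = a_k`) this
#' reduces to the IRS content itself.
#'
#' @param a_s Peak area of component `s` in the sample injection.
#' @param a_k Peak area of the IRS in the same injection.
#' @param w_k_ug Amount of the IRS in the injection (µg).
#' @param f_ks Relative correction factor linking `s` to the IRS.
#' @param m_sample_ug Sample load on column (µg), default 40.
#' @return Content in % w/w (vectorised).
#' @export
qams_content <- function(a_s, a_k, w_k_ug, f_ks, m_sample_ug = 40) {
  check_positive(a_s, "a_s"); check_positive(a_k, "a_k")
  check_positive(w_k_ug, "w_k_ug"); check_positive(f_ks, "f_ks")
  check_positive(m_sample_ug, "m_sample_ug")
  w_s <- (w_k_ug * a_s) / (f_ks * a_k)
  100 * w_s / m_sample_ug
}

#' Spike recovery
#'
#' Recovery rate of a known addition:
#' `rate = 100 · (measured − content) / added`. Rates above 100% are
#' legitimate (measurement error on the spiked total).
#'
#' @param content_mg Analyte already in the sample (mg).
#' @param added_mg Spiked amount (mg, > 0).
#' @param measured_mg Total found after spiking (mg).
#' @return A tibble: `content_mg`, `added_mg`, `measured_mg`, `rate_pct`
#'   (vectorised, one row per spike).
#' @examples
#' recovery(5.715, 5.700, 11.425)
#' @export
recovery <- function(content_mg, added_mg, measured_mg) {
  check_nonnegative(content_mg, "content_mg")
  check_positive(added_mg, "added_mg")
  check_nonnegative(measured_mg, "measured_mg")
  tibble(content_mg = content_mg, added_mg = added_mg,
         measured_mg = measured_mg,
         rate_pct = 100 * (measured_mg - content_mg) / added_mg)
}

#' Compare QAMS against the external standard method
#'
#' Paired two-sided t-test per marker on batch-wise content pairs. A marker
#' whose batch differences have zero variance cannot be tested by t; it is
#' flagged `degenerate` and reported as the exact shift instead (p = 1 for
#' an all-zero difference, p = 0 for a constant non-zero shift — the
#' limiting t-test behaviour).
#'
#' @param esm,qams Data frames of contents with columns `batch`, `marker`,
#'   `content` (% w/w); both must cover the same batch × marker pairs.
#' @param alpha Significance level for the agreement flag (default 0.05).
#' @return A tibble of class `qams_esm_test`: `marker`, `n`, `mean_diff`,
#'   `t`, `df`, `p`, `degenerate`, `agrees` (TRUE when p > `alpha`).
#' @export
compare_methods <- function(esm, qams, alpha = 0.05) {
  need <- c("batch", "marker", "content")
  for (nm in need) {
    if (!nm %in% names(esm) || !nm %in% names(qams)) {
      stop_format(sprintf("both inputs need column `%s`.", nm))
    }
  }
  joined <- dplyr::inner_join(
    dplyr::select(as_tibble(esm), "batch", "marker", esm = "content"),
    dplyr::select(as_tibble(qams), "batch", "marker", qams = "content"),
    by = c("batch", "marker"))
  if (nrow(joined) != nrow(esm) || nrow(joined) != nrow(qams)) {
    stop_consistency("ESM and QAMS tables do not cover the same batch/marker pairs.")
  }
  out <- joined |>
    dplyr::group_by(.data$marker) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) stop_insufficient("need at least 2 paired batches per marker.")
      d <- df$qams - df$esm
      # zero variance up to floating-point noise cannot be t-tested
      if (sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
        shift <- mean(d)
        tibble(n = nrow(df), mean_diff = shift,
               t = if (shift == 0) 0 else sign(shift) * Inf,
               df = nrow(df) - 1,
               p = if (shift == 0) 1 else 0,
               degenerate = TRUE)
      } else {
        tt <- t.test(df$qams, df$esm, paired = TRUE)
        tibble(n = nrow(df), mean_diff = unname(tt$estimate),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, degenerate = FALSE)
      }
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(agrees = .data$p > alpha)
  class(out) <- c("qams_esm_test", class(out))
  out
}

#' @export
tidy.qams_esm_test <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "qams_esm_test")
  out
}

#' @export
glance.qams_esm_test <- function(x, ...) {
  tibble(n_markers = nrow(x), min_p = min(x$p), all_agree = all(x$agrees))
}
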