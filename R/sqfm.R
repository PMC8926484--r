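# Systematic quantified fingerprint method (SQFM).
#
# A sample fingerprint x (common-peak areas) is judged against a reference
# fingerprint y through three parameters:
#   S_m  macro-qualitative similarity — mean of the congruence (cosine)
#        coefficient and a mean-ratio similarity; 1 iff x is proportional to y
#   P_m  macro-quantitative similarity — mean of the projection content C and
#        the cosine-weighted total-area ratio P, in percent
#   α    fingerprint variation coefficient |1 − P/C|
# Each parameter maps to a grade 1–8; the batch grade is the worst of the
# three ("the lower the grade, the better the quality").

check_profiles <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop_domain("profiles must be numeric.")
  if (length(x) != length(y)) stop_domain("profiles must have the same length.")
  if (length(x) < 1) stop_domain("profiles must be non-empty.")
  if (anyNA(x) || anyNA(y) || any(x <= 0) || any(y <= 0)) {
    stop_domain("all fingerprint areas must be positive; absent peaks are not allowed.")
  }
  invisible(NULL)
}

#' Macro-qualitative similarity between sample and reference fingerprints
#'
#' `S_m = (cos + ratio)/2` where
#' `cos = Σx·y / sqrt(Σx²·Σy²)` (congruence coefficient) and
#' `ratio = Σ(x/y) / sqrt(n·Σ(x/y)²)` (mean-ratio similarity). Both terms lie
#' in (0, 1] by Cauchy–Schwarz and equal 1 exactly when `x ∝ y`, so `S_m` is
#' scale-free and measures the *distribution pattern* of constituents, not
#' their overall amount.
#'
#' @param x Sample fingerprint: positive areas of the common peaks.
#' @param y Reference fingerprint, same length.
#' @return A number in (0, 1].
#' @examples
#' sqfm_sm(c(1, 2, 3), c(3, 2, 1))
#' @export
sqfm_sm <- function(x, y) {
  check_profiles(x, y)
  cosine <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  r <- x / y
  ratio <- sum(r) / sqrt(length(r) * sum(r^2))
  (cosine + ratio) / 2
}

#' Projection content ratio C (%)
#'
#' `C = 100 · Σx·y / Σy²`: the length of the projection of the sample
#' profile onto the reference, relative to the reference — linear in `x`.
#'
#' @inheritParams sqfm_sm
#' @return Percentage (> 0).
#' @export
sqfm_c <- function(x, y) {
  check_profiles(x, y)
  100 * sum(x * y) / sum(y^2)
}

#' Cosine-weighted total-area ratio P (%)
#'
#' `P = 100 · (Σx/Σy) · cos(x, y)`: the total-area ratio discounted by the
#' congruence coefficient, so that pattern disagreement also lowers the
#' apparent content.
#'
#' @inheritParams sqfm_sm
#' @return Percentage (> 0).
#' @export
sqfm_p <- function(x, y) {
  check_profiles(x, y)
  cosine <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  100 * (sum(x) / sum(y)) * cosine
}

#' Macro-quantitative similarity and fingerprint variation coefficient
#'
#' `P_m = (C + P)/2` monitors the overall constituent content;
#' `α = |1 − P/C|` measures how far the two quantitative readings diverge
#' (0 whenever `P = C`, in particular for all proportional profiles).
#'
#' @inheritParams sqfm_sm
#' @return One-row tibble: `c_pct`, `p_pct`, `p_m_pct`, `alpha`.
#' @export
sqfm_pm_alpha <- function(x, y) {
  cc <- sqfm_c(x, y)
  pp <- sqfm_p(x, y)
  tibble(c_pct = cc, p_pct = pp, p_m_pct = (cc + pp) / 2,
         alpha = abs(1 - pp / cc))
}

#' The default eight-grade SQFM quality criteria
#'
#' Grade g (1 best … 8 worst) requires `S_m ≥ s_m_floor[g]`,
#' `P_m ∈ [p_m_low[g], p_m_high[g]]` and `α ≤ alpha_ceiling[g]`; all bounds
#' are inclusive and grade 8 catches everything. The default table:
#'
#' | grade | quality   | S_m ≥ | P_m ∈      | α ≤  |
#' |-------|-----------|-------|------------|------|
#' | 1     | Best      | 0.95  | 95–105     | 0.05 |
#' | 2     | Better    | 0.90  | 90–110     | 0.10 |
#' | 3     | Good      | 0.85  | 85–115     | 0.15 |
#' | 4     | Fine      | 0.80  | 80–120     | 0.20 |
#' | 5     | Moderate  | 0.70  | 70–130     | 0.30 |
#' | 6     | Common    | 0.60  | 60–140     | 0.40 |
#' | 7     | Defective | 0.50  | 50–150     | 0.50 |
#' | 8     | Inferior  | —     | 0–∞        | —    |
#'
#' @return A tibble with columns `grade`, `quality`, `s_m_floor`, `p_m_low`,
#'   `p_m_high`, `alpha_ceiling`.
#' @export
sqfm_grading <- function() {
  tibble(
    grade = 1:8,
    quality = c("Best", "Better", "Good", "Fine", "Moderate", "Common",
                "Defective", "Inferior"),
    s_m_floor = c(0.95, 0.90, 0.85, 0.80, 0.70, 0.60, 0.50, -Inf),
    p_m_low = c(95, 90, 85, 80, 70, 60, 50, 0),
    p_m_high = c(105, 110, 115, 120, 130, 140, 150, Inf),
    alpha_ceiling = c(0.05, 0.10, 0.15, 0.20, 0.30, 0.40, 0.50, Inf))
}

validate_grading <- function(g) {
  need <- c("grade", "quality", "s_m_floor", "p_m_low", "p_m_high", "alpha_ceiling")
  missing_cols <- setdiff(need, names(g))
  if (length(missing_cols) > 0) {
    stop_format(sprintf("grading table missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  if (nrow(g) < 1 || is.unsorted(g$grade)) stop_validation("grades must be ascending.")
  if (any(diff(g$s_m_floor) > 0)) stop_validation("`s_m_floor` must be non-increasing.")
  if (any(diff(g$alpha_ceiling) < 0)) stop_validation("`alpha_ceiling` must be non-decreasing.")
  if (any(diff(g$p_m_low) > 0) || any(diff(g$p_m_high) < 0)) {
    stop_validation("P_m intervals must be nested.")
  }
  g
}

param_grade <- function(ok_matrix, n_grades) {
  # first TRUE per row; last grade catches all
  idx <- apply(ok_matrix, 1, function(r) which(r)[1])
  idx[is.na(idx)] <- n_grades
  idx
}

#' Grade batches from their SQFM parameters
#'
#' Each of the three parameters is mapped to the best (lowest) grade whose
#' criterion it satisfies; the overall grade is the **worst** of the three
#' parameter grades, so a batch is only as good as its weakest aspect.
#'
#' @param s_m Macro-qualitative similarity, in (0, 1] (vectorised).
#' @param p_m_pct Macro-quantitative similarity in percent.
#' @param alpha Fingerprint variation coefficient, ≥ 0.
#' @param grading Grading criteria, default [sqfm_grading()].
#' @return A tibble: `s_m`, `p_m_pct`, `alpha`, `grade_s_m`, `grade_p_m`,
#'   `grade_alpha`, `grade`, `quality`.
#' @examples
#' sqfm_grade(s_m = 0.934, p_m_pct = 54.4, alpha = 0.078)
#' @export
sqfm_grade <- function(s_m, p_m_pct, alpha, grading = sqfm_grading()) {
  grading <- validate_grading(grading)
  if (!is.numeric(s_m) || anyNA(s_m) || any(s_m <= 0) || any(s_m > 1 + 1e-12)) {
    stop_domain("`s_m` must lie in (0, 1].")
  }
  check_positive(p_m_pct, "p_m_pct")
  check_nonnegative(alpha, "alpha")
  n <- max(length(s_m), length(p_m_pct), length(alpha))
  s_m <- rep_len(s_m, n); p_m_pct <- rep_len(p_m_pct, n); alpha <- rep_len(alpha, n)

  g_s <- param_grade(outer(s_m, grading$s_m_floor, `>=`), nrow(grading))
  g_p <- param_grade(outer(p_m_pct, grading$p_m_low, `>=`) &
                       outer(p_m_pct, grading$p_m_high, `<=`), nrow(grading))
  g_a <- param_grade(outer(alpha, grading$alpha_ceiling, `<=`), nrow(grading))
  overall <- pmax(g_s, g_p, g_a)
  tibble(s_m = s_m, p_m_pct = p_m_pct, alpha = alpha,
         grade_s_m = grading$grade[g_s], grade_p_m = grading$grade[g_p],
         grade_alpha = grading$grade[g_a], grade = grading$grade[overall],
         quality = grading$quality[overall])
}

#' Build the reference fingerprint by the average method
#'
#' The reference fingerprint (RFP) is the arithmetic mean profile of the
#' batch fingerprints, peak by peak.
#'
#' @param fm A [fingerprint_matrix()] (≥ 2 batches).
#' @return Named numeric vector of mean areas, one per common peak.
#' @export
build_rfp <- function(fm) {
  fm <- fingerprint_matrix(fm)
  if (nrow(fm) < 2) stop_insufficient("need at least 2 batches to build an RFP.")
  vals <- fm[setdiff(names(fm), "batch_id")]
  colMeans(as.matrix(vals))
}

#' Evaluate batch fingerprints by SQFM
#'
#' Computes `S_m`, `C`, `P`, `P_m` and `α` for every batch against the
#' reference fingerprint (by default the average profile, [build_rfp()]),
#' grades each batch, and appends the reference's self-evaluation row
#' (`S_m = 1`, `P_m = 100`, `α = 0`, grade 1) as the benchmark.
#'
#' @param fm A [fingerprint_matrix()] of common-peak areas.
#' @param rfp Optional reference fingerprint (positive numeric vector, one
#'   entry per common peak); defaults to the batch average.
#' @param grading Grading criteria, default [sqfm_grading()].
#' @return A tibble of class `sqfm_eval`: `batch`, `s_m`, `c_pct`, `p_pct`,
#'   `p_m_pct`, `alpha`, `grade`, `quality` (last row is the RFP itself).
#' @export
sqfm_evaluate <- function(fm, rfp = NULL, grading = sqfm_grading()) {
  fm <- fingerprint_matrix(fm)
  if (is.null(rfp)) rfp <- build_rfp(fm)
  vals <- as.matrix(fm[setdiff(names(fm), "batch_id")])
  if (length(rfp) != ncol(vals)) {
    stop_validation("`rfp` length must equal the number of common peaks.")
  }
  check_positive(rfp, "rfp")

  rows <- purrr::map_dfr(seq_len(nrow(vals)), function(b) {
    x <- vals[b, ]
    pa <- sqfm_pm_alpha(x, rfp)
    dplyr::bind_cols(tibble(batch = fm$batch_id[b], s_m = sqfm_sm(x, rfp)), pa)
  })
  self <- dplyr::bind_cols(tibble(batch = "RFP", s_m = sqfm_sm(rfp, rfp)),
                           sqfm_pm_alpha(rfp, rfp))
  rows <- dplyr::bind_rows(rows, self)
  graded <- sqfm_grade(rows$s_m, rows$p_m_pct, rows$alpha, grading)
  out <- dplyr::bind_cols(rows,
                          graded[c("grade_s_m", "grade_p_m", "grade_alpha",
                                   "grade", "quality")])
  attr(out, "rfp") <- rfp
  class(out) <- c("sqfm_eval", class(out))
  out
}

#' @export
tidy.sqfm_eval <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "sqfm_eval")
  out
}

#' @export
glance.sqfm_eval <- function(x, ...) {
  batches <- x[x$batch != "RFP", ]
  tibble(n_batches = nrow(batches), n_peaks = length(attr(x, "rfp")),
         best_grade = min(batches$grade), worst_grade = max(batches$grade),
         mean_s_m = mean(batches$s_m))
}
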