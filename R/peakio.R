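#' Build a peak table for one injection
#'
#' A peak table is the universal input record of the package: the integrated
#' peaks of a single HPLC injection, one row per peak with an integer label,
#' a retention time in minutes and a positive detector response (peak area).
#' Rows are sorted by retention time; the injection identifier and injected
#' volume travel along as attributes so downstream quantification can convert
#' concentrations to on-column masses.
#'
#' @param peaks Data frame with columns `peak_id`, `rt` (min) and `area`.
#' @param injection_id Character label for the injection.
#' @param volume_ul Injected volume in microlitres (must be > 0).
#'
#' @return A tibble of class `peak_table`, rows ordered by ascending `rt`,
#'   with attributes `injection_id` and `volume_ul`.
#' @examples
#' peak_table(data.frame(peak_id = 1, rt = 12.3, area = 3571),
#'            injection_id = "ref_20ul", volume_ul = 20)
#' @export
peak_table <- function(peaks, injection_id = "injection", volume_ul = 20) {
  need <- c("peak_id", "rt", "area")
  missing_cols <- setdiff(need, names(peaks))
  if (length(missing_cols) > 0) {
    stop_format(sprintf("peak table is missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  peaks <- as_tibble(peaks)[need]
  bad <- which(!is.finite(peaks$area) | peaks$area <= 0)
  if (length(bad) > 0) {
    stop_validation(sprintf("non-positive peak area in row(s): %s",
                            paste(bad, collapse = ", ")))
  }
  check_nonnegative(peaks$rt, "rt")
  if (anyDuplicated(peaks$peak_id)) {
    stop_validation("`peak_id` must be unique within one injection.")
  }
  if (!is.numeric(volume_ul) || length(volume_ul) != 1 || is.na(volume_ul) ||
      volume_ul <= 0) {
    stop_validation("`volume_ul` must be a single positive number.")
  }
  out <- dplyr::arrange(peaks, .data$rt)
  attr(out, "injection_id") <- as.character(injection_id)
  attr(out, "volume_ul") <- volume_ul
  class(out) <- c("peak_table", class(out))
  out
}

#' Read a peak table from a delimited text file
#'
#' Expects a header with columns `peak_id`, `rt` and `area` (tab- or
#' comma-separated). Extra columns are ignored.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"`, `"csv"`, or `"auto"` (default: decide from the
#'   file extension, falling back to tab).
#' @inheritParams peak_table
#' @return A [peak_table()] tibble.
#' @export
read_peak_table <- function(path, dialect = c("auto", "tsv", "csv"),
                            injection_id = NULL, volume_ul = 20) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  reader <- if (dialect == "csv") readr::read_csv else readr::read_tsv
  raw <- suppressWarnings(reader(path, show_col_types = FALSE, progress = FALSE))
  need <- c("peak_id", "rt", "area")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop_format(sprintf("%s: missing column(s): %s", path,
                        paste(missing_cols, collapse = ", ")))
  }
  for (col in c("rt", "area")) {
    if (!is.numeric(raw[[col]])) {
      stop_format(sprintf("%s: column `%s` is not numeric.", path, col))
    }
  }
  if (is.null(injection_id)) {
    injection_id <- sub("\\.[^.]*$", "", basename(path))
  }
  peak_table(raw[need], injection_id = injection_id, volume_ul = volume_ul)
}

#' Write a peak table to a delimited text file
#'
#' @param x A [peak_table()] tibble.
#' @param path Output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  df <- as_tibble(x)[c("peak_id", "rt", "area")]
  if (dialect == "csv") readr::write_csv(df, path) else readr::write_tsv(df, path)
  invisible(path)
}

#' Match common peaks across injections into a fingerprint matrix
#'
#' Pools the peaks of all tables and clusters their retention times by
#' single linkage, cutting at `rt_tolerance`. A cluster is a *common peak*
#' only if every table contributes exactly one peak to it; a table
#' contributing two peaks to one cluster is an ambiguity and raises an
#' error rather than being silently dropped. Columns are ordered by the
#' cluster mean retention time.
#'
#' @param tables List of [peak_table()] objects (at least two). Batch
#'   identifiers are taken from list names, else from `injection_id`.
#' @param rt_tolerance Retention-time tolerance in minutes (default 0.2).
#' @return A fingerprint tibble (see [fingerprint_matrix()]): column
#'   `batch_id` then one positive area column `p1..pN` per common peak, with
#'   the cluster mean retention times in attribute `rt`.
#' @export
match_common_peaks <- function(tables, rt_tolerance = 0.2) {
  if (!is.list(tables) || length(tables) < 2) {
    stop_validation("need at least two peak tables to match common peaks.")
  }
  check_positive(rt_tolerance, "rt_tolerance")
  ids <- names(tables)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- vapply(tables, function(t) {
      id <- attr(t, "injection_id")
      if (is.null(id)) "" else id
    }, character(1))
    if (any(!nzchar(ids))) ids <- paste0("batch", seq_along(tables))
  }

  pooled <- purrr::map2_dfr(tables, ids, function(t, id) {
    tibble(batch = id, rt = t$rt, area = t$area)
  })
  # single-linkage clusters on rt, cut at the tolerance
  if (nrow(pooled) < 2) stop_validation("not enough peaks to match.")
  hc <- hclust(dist(pooled$rt), method = "single")
  pooled$cluster <- cutree(hc, h = rt_tolerance)

  per <- dplyr::group_by(pooled, .data$cluster)
  info <- dplyr::summarise(per,
    mean_rt = mean(.data$rt),
    n_batches = dplyr::n_distinct(.data$batch),
    n_peaks = dplyr::n(),
    .groups = "drop")

  dup <- dplyr::filter(info, .data$n_peaks > .data$n_batches,
                       .data$n_batches == length(tables))
  if (nrow(dup) > 0) {
    rts <- pooled$rt[pooled$cluster %in% dup$cluster]
    stop_ambiguity(sprintf(
      "ambiguous common-peak match: one table has several peaks within %.3g min of rt(s) %s",
      rt_tolerance, paste(sprintf("%.3f", sort(rts)), collapse = ", ")))
  }

  common <- dplyr::filter(info, .data$n_batches == length(tables),
                          .data$n_peaks == length(tables))
  common <- dplyr::arrange(common, .data$mean_rt)
  if (nrow(common) == 0) {
    stop_validation("no common peaks found across all tables.")
  }

  areas <- purrr::map_dfc(seq_len(nrow(common)), function(j) {
    cl <- common$cluster[j]
    sub <- pooled[pooled$cluster == cl, ]
    setNames(tibble(sub$area[match(ids, sub$batch)]), paste0("p", j))
  })
  out <- dplyr::bind_cols(tibble(batch_id = ids), areas)
  fingerprint_matrix(out, rt = common$mean_rt)
}

#' Validate a fingerprint matrix of common-peak areas
#'
#' A fingerprint matrix holds, for each batch, the areas of the peaks common
#' to all batches: a `batch_id` column followed by positive numeric columns
#' `p1..pN` in elution order.
#'
#' @param x Data frame with a `batch_id` column and numeric peak columns.
#' @param rt Optional numeric vector of per-peak retention times (attribute).
#' @return A tibble of class `fingerprint_matrix`.
#' @export
fingerprint_matrix <- function(x, rt = NULL) {
  x <- as_tibble(x)
  if (!"batch_id" %in% names(x)) stop_format("first column must be `batch_id`.")
  x$batch_id <- as.character(x$batch_id)
  vals <- x[setdiff(names(x), "batch_id")]
  if (ncol(vals) == 0) stop_format("fingerprint matrix has no peak columns.")
  ok <- vapply(vals, function(v) is.numeric(v) && !anyNA(v) && all(v > 0), logical(1))
  if (!all(ok)) {
    stop_validation(sprintf("non-positive or non-numeric areas in column(s): %s",
                            paste(names(vals)[!ok], collapse = ", ")))
  }
  if (anyDuplicated(x$batch_id)) stop_validation("duplicate `batch_id`.")
  if (!is.null(rt)) {
    if (length(rt) != ncol(vals)) stop_validation("`rt` length must match peak columns.")
    attr(x, "rt") <- rt
  }
  class(x) <- unique(c("fingerprint_matrix", class(x)))
  x
}

#' Read / write a fingerprint matrix (CSV)
#'
#' CSV layout: first column `batch_id`, then `p1..pN` peak-area columns.
#'
#' @param path File path.
#' @return For `read_fingerprints`, a [fingerprint_matrix()] tibble.
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  fingerprint_matrix(raw)
}

#' @rdname read_fingerprints
#' @param x A [fingerprint_matrix()] tibble.
#' @export
write_fingerprints <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' Read marker definitions
#'
#' Markers are the quantified components: name, reference-solution
#' concentration (mg/ml), position among the common peaks, linear range of
#' injected mass (µg) and, optionally, an expected retention time used for
#' peak assignment. Accepts CSV (columns `name`, `ref_conc_mg_ml`,
#' `common_peak_index`, `linear_low_ug`, `linear_high_ug`, optional `rt`)
#' or YAML (a list of such records).
#'
#' @param path File path (`.csv`, `.yml` or `.yaml`).
#' @return A tibble with one row per marker.
#' @seealso [default_markers()] for the built-in four-saponin panel.
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    lst <- yaml::read_yaml(path)
    df <- purrr::map_dfr(lst, as_tibble)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  validate_markers(df)
}

validate_markers <- function(df) {
  need <- c("name", "ref_conc_mg_ml", "common_peak_index",
            "linear_low_ug", "linear_high_ug")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop_format(sprintf("marker definitions missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)
  check_positive(df$ref_conc_mg_ml, "ref_conc_mg_ml")
  if (any(df$linear_low_ug >= df$linear_high_ug)) {
    stop_validation("`linear_low_ug` must be below `linear_high_ug`.")
  }
  if (anyDuplicated(df$name)) stop_validation("duplicate marker names.")
  df
}

#' Assign peaks of one injection to markers by retention time
#'
#' Each marker with an `rt` field claims the unique peak within
#' `rt_tolerance` of it. No peak in the window is an error (the marker is
#' missing); two peaks in the window is an ambiguity error.
#'
#' @param table A [peak_table()].
#' @param markers Marker tibble (see [read_markers()]) with an `rt` column.
#' @param rt_tolerance Minutes (default 0.2).
#' @return Tibble with columns `marker`, `rt`, `area`.
#' @export
assign_markers <- function(table, markers, rt_tolerance = 0.2) {
  check_positive(rt_tolerance, "rt_tolerance")
  if (!"rt" %in% names(markers)) {
    stop_format("marker definitions need an `rt` column for peak assignment.")
  }
  purrr::map_dfr(seq_len(nrow(markers)), function(i) {
    hits <- which(abs(table$rt - markers$rt[i]) <= rt_tolerance)
    if (length(hits) == 0) {
      stop_validation(sprintf("no peak within %.3g min of marker %s (rt %.2f).",
                              rt_tolerance, markers$name[i], markers$rt[i]))
    }
    if (length(hits) > 1) {
      stop_ambiguity(sprintf(
        "marker %s matches %d peaks (rts %s); tighten `rt_tolerance`.",
        markers$name[i], length(hits),
        paste(sprintf("%.3f", table$rt[hits]), collapse = ", ")))
    }
    tibble(marker = markers$name[i], rt = table$rt[hits], area = table$area[hits])
  })
}
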