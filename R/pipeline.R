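#' Assemble a pipeline configuration
#'
#' Bundles and validates everything [run_pipeline()] needs. File paths are
#' accepted wherever objects are: marker definitions (CSV/YAML), peak tables
#' (TSV/CSV) and fingerprint matrices (CSV) are read with the package's
#' readers.
#'
#' @param markers Marker tibble (see [read_markers()]) or a path.
#' @param irs Name of the internal reference standard; must be a defined
#'   marker.
#' @param reference Named list of reference-injection [peak_table()]s, or a
#'   named character vector of paths with injection volumes encoded via
#'   `reference_volumes_ul`.
#' @param reference_volumes_ul Injection volumes (µl) for `reference` when
#'   paths are given (recycled).
#' @param samples Optional named list of sample [peak_table()]s (or paths);
#'   used for ESM/QAMS content determination.
#' @param sample_conc_ug_ul Sample solution concentration (µg/µl), default 2
#'   (a 20 mg / 10 ml preparation).
#' @param validation Optional named list (e.g. `precision`, `repeatability`,
#'   `stability`), each a list of peak tables (or paths) whose per-marker
#'   area RSDs are reported.
#' @param recovery Optional data frame with columns `marker`, `content_mg`,
#'   `added_mg`, `measured_mg` for spike-recovery reporting.
#' @param fingerprints Optional [fingerprint_matrix()] (or CSV path) for
#'   SQFM and HCA.
#' @param rt_tolerance Peak-assignment tolerance in minutes (default 0.2).
#' @param grading Optional grading-table override (default [sqfm_grading()]).
#' @param hca List of HCA options: `variables` (`"peaks"` or `"pm"`), `k`,
#'   `distance`, `linkage`.
#' @param out_dir Optional output directory for the report bundle.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(markers, irs, reference,
                            reference_volumes_ul = 20,
                            samples = NULL, sample_conc_ug_ul = 2,
                            validation = NULL, recovery = NULL,
                            fingerprints = NULL, rt_tolerance = 0.2,
                            grading = NULL,
                            hca = list(variables = "peaks", k = 2,
                                       distance = "sq_euclidean",
                                       linkage = "average"),
                            out_dir = NULL) {
  if (is.character(markers)) markers <- read_markers(markers)
  markers <- validate_markers(markers)
  if (!is.character(irs) || length(irs) != 1 || !irs %in% markers$name) {
    stop_config("`irs` must name one of the defined markers.")
  }
  reference <- resolve_tables(reference, reference_volumes_ul)
  if (!is.null(samples)) samples <- resolve_tables(samples, 20)
  if (!is.null(validation)) {
    validation <- lapply(validation, resolve_tables, volumes = 20)
  }
  if (!is.null(recovery)) {
    need <- c("marker", "content_mg", "added_mg", "measured_mg")
    if (!all(need %in% names(recovery))) {
      stop_config("`recovery` needs columns marker, content_mg, added_mg, measured_mg.")
    }
  }
  if (is.character(fingerprints)) fingerprints <- read_fingerprints(fingerprints)
  hca <- modifyList(list(variables = "peaks", k = 2,
                         distance = "sq_euclidean", linkage = "average"), hca)
  structure(list(markers = markers, irs = irs, reference = reference,
                 samples = samples, sample_conc_ug_ul = sample_conc_ug_ul,
                 validation = validation, recovery = recovery,
                 fingerprints = fingerprints, rt_tolerance = rt_tolerance,
                 grading = grading, hca = hca, out_dir = out_dir),
            class = "pipeline_config")
}

resolve_tables <- function(x, volumes) {
  if (is.character(x)) {
    volumes <- rep_len(volumes, length(x))
    nms <- names(x) %||% sub("\\.[^.]*$", "", basename(x))
    x <- setNames(purrr::map(seq_along(x), function(i) {
      read_peak_table(x[[i]], injection_id = nms[[i]], volume_ul = volumes[[i]])
    }), nms)
  }
  if (!is.list(x) || !all(vapply(x, inherits, logical(1), "peak_table"))) {
    stop_config("peak tables must be `peak_table` objects or file paths.")
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    names(x) <- vapply(x, function(t) attr(t, "injection_id"), character(1))
  }
  x
}

#' Run the full quality-evaluation pipeline
#'
#' Orchestrates calibrate → RCF → content → validation → SQFM → HCA from one
#' configuration and (optionally) writes a report bundle: `rcf.csv`,
#' `validation.csv`, `contents.csv`, `sqfm.csv`, `hca.json` and a `run.yaml`
#' sidecar with the package version and a hash of the configuration. The
#' pipeline is a pure function of its inputs: identical configurations give
#' byte-identical reports.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a named list of the computed tibbles
#'   (`rcf`, `rcf_summary`, `contents`, `comparison`, `validation`,
#'   `recovery`, `sqfm`, `hca`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  markers <- cfg$markers
  irs <- cfg$irs
  others <- setdiff(markers$name, irs)

  # --- relative correction factors from the reference series
  per_inj <- purrr::imap_dfr(cfg$reference, function(t, nm) {
    hits <- assign_markers(t, markers, cfg$rt_tolerance)
    v <- attr(t, "volume_ul")
    w <- markers$ref_conc_mg_ml[match(hits$marker, markers$name)] * v
    ak <- hits$area[hits$marker == irs]
    wk <- w[hits$marker == irs]
    tibble(injection = nm, volume_ul = v, component = hits$marker,
           f = compute_rcf(wk, ak, w, hits$area))
  })
  rcf_wide <- per_inj |>
    dplyr::filter(.data$component != irs) |>
    dplyr::mutate(component = paste0("f_", irs, "/", .data$component)) |>
    tidyr::pivot_wider(id_cols = c("injection", "volume_ul"),
                       names_from = "component", values_from = "f")
  rcf_sum <- rcf_summary(dplyr::select(rcf_wide, dplyr::starts_with("f_")),
                         irs = irs)

  # --- contents by ESM and QAMS (requires sample injections)
  contents <- NULL; comparison <- NULL
  if (!is.null(cfg$samples)) {
    sample_rows <- purrr::imap_dfr(cfg$samples, function(t, nm) {
      v <- attr(t, "volume_ul")
      refs <- purrr::keep(cfg$reference, function(r) attr(r, "volume_ul") == v)
      if (length(refs) == 0) {
        stop_config(sprintf("no reference injection at the sample volume (%g ul).", v))
      }
      ref_areas <- purrr::map_dfr(refs, assign_markers,
                                  markers = markers,
                                  rt_tolerance = cfg$rt_tolerance) |>
        dplyr::group_by(.data$marker) |>
        dplyr::summarise(a_ref = mean(.data$area), .groups = "drop")
      hits <- assign_markers(t, markers, cfg$rt_tolerance)
      df <- dplyr::left_join(hits, ref_areas, by = "marker")
      m_ref <- markers$ref_conc_mg_ml[match(df$marker, markers$name)] * v
      load_ug <- cfg$sample_conc_ug_ul * v
      esm <- esm_content(df$area, df$a_ref, m_ref, load_ug)
      # IRS mass in the sample injection, then QAMS through the mean RCFs
      ak <- df$area[df$marker == irs]
      wk <- esm[df$marker == irs] / 100 * load_ug
      fks <- setNames(rcf_sum$mean, sub("^f_[^/]+/", "", rcf_sum$component))
      qams <- vapply(seq_len(nrow(df)), function(i) {
        s <- df$marker[i]
        if (s == irs) esm[i]
        else qams_content(df$area[i], ak, wk, fks[[s]], load_ug)
      }, numeric(1))
      tibble(batch = nm, marker = df$marker, esm = esm, qams = qams)
    })
    contents <- sample_rows
    if (length(cfg$samples) >= 2) {
      comparison <- compare_methods(
        dplyr::select(sample_rows, "batch", "marker", content = "esm"),
        dplyr::select(sample_rows, "batch", "marker", content = "qams"))
    }
  }

  # --- validation statistics (per-marker RSDs) and recovery
  validation <- NULL
  if (!is.null(cfg$validation)) {
    validation <- purrr::imap_dfr(cfg$validation, function(tables, kind) {
      areas <- purrr::map_dfr(tables, assign_markers, markers = markers,
                              rt_tolerance = cfg$rt_tolerance)
      areas |>
        dplyr::group_by(.data$marker) |>
        dplyr::group_modify(~ replicate_summary(.x$area)) |>
        dplyr::ungroup() |>
        dplyr::mutate(kind = kind, .before = 1)
    })
  }
  recov <- NULL
  if (!is.null(cfg$recovery)) {
    recov <- dplyr::bind_cols(
      tibble(marker = cfg$recovery$marker),
      recovery(cfg$recovery$content_mg, cfg$recovery$added_mg,
               cfg$recovery$measured_mg))
  }

  # --- SQFM and HCA on the fingerprint matrix
  sqfm <- NULL; hca_out <- NULL
  if (!is.null(cfg$fingerprints)) {
    sqfm <- sqfm_evaluate(cfg$fingerprints,
                          grading = cfg$grading %||% sqfm_grading())
    hdata <- if (identical(cfg$hca$variables, "pm")) {
      batches <- sqfm[sqfm$batch != "RFP", ]
      tibble(batch_id = batches$batch, p_m = batches$p_m_pct)
    } else {
      cfg$fingerprints
    }
    fit <- cluster_batches(hdata, distance = cfg$hca$distance,
                           linkage = cfg$hca$linkage)
    hca_out <- list(fit = fit,
                    assignments = cut_batches(fit, cfg$hca$k))
  }

  results <- list(rcf = rcf_wide, rcf_summary = rcf_sum, contents = contents,
                  comparison = comparison, validation = validation,
                  recovery = recov, sqfm = sqfm, hca = hca_out)

  if (!is.null(cfg$out_dir)) write_report_bundle(results, cfg)
  invisible(results)
}

write_report_bundle <- function(results, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)

  summary_rows <- results$rcf_summary |>
    dplyr::select("component", "mean", "rsd_pct") |>
    tidyr::pivot_longer(c("mean", "rsd_pct"), names_to = "stat") |>
    tidyr::pivot_wider(names_from = "component", values_from = "value") |>
    dplyr::mutate(injection = c("Average value", "RSD (%)"),
                  volume_ul = NA_real_, .before = 1) |>
    dplyr::select(-"stat")
  readr::write_csv(dplyr::bind_rows(results$rcf, summary_rows), out("rcf.csv"))

  if (!is.null(results$validation) || !is.null(results$recovery)) {
    val <- results$validation %||%
      tibble(kind = character(), marker = character(), n = integer(),
             mean = numeric(), sd = numeric(), rsd_pct = numeric())
    if (!is.null(results$recovery)) {
      rec_sum <- results$recovery |>
        dplyr::group_by(.data$marker) |>
        dplyr::group_modify(~ replicate_summary(.x$rate_pct)) |>
        dplyr::ungroup() |>
        dplyr::mutate(kind = "recovery", .before = 1)
      val <- dplyr::bind_rows(val, rec_sum)
    }
    readr::write_csv(val, out("validation.csv"))
  }
  if (!is.null(results$contents)) {
    readr::write_csv(results$contents, out("contents.csv"))
  }
  if (!is.null(results$sqfm)) {
    readr::write_csv(as_tibble(results$sqfm), out("sqfm.csv"))
  }
  if (!is.null(results$hca)) {
    jsonlite::write_json(
      list(merge_history = results$hca$fit$merge_history,
           assignments = results$hca$assignments),
      out("hca.json"), dataframe = "rows", digits = NA, pretty = TRUE)
  }
  meta <- list(
    package = "herbqc",
    version = as.character(utils::packageVersion("herbqc")),
    irs = cfg$irs,
    rt_tolerance = cfg$rt_tolerance,
    hca = cfg$hca[c("variables", "k", "distance", "linkage")],
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]))
  yaml::write_yaml(meta, out("run.yaml"))
  invisible(cfg$out_dir)
}
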