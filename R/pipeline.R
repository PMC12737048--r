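#' Full pipeline configuration
#'
#' Bundles the per-stage settings: generator, windowing, low-pass filter,
#' Welch estimator, model, normalization variant, and an optional feature
#' mask (ablation preset or explicit columns).
#'
#' @param generator A [generator_config()].
#' @param window A [window_spec()].
#' @param filter List with `cutoff` (Hz) and `order`.
#' @param welch List with `segment_length` and `overlap`.
#' @param model A [model_config()].
#' @param normalization `"sum"` or `"mean"`, see [normalize_features()].
#' @param mask Optional ablation preset name or character vector of
#'   feature columns.
#' @param out_dir Optional directory; when set, [run_pipeline()] writes
#'   the study CSVs, the feature tables and the report there.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            window = window_spec(),
                            filter = list(cutoff = 18, order = 4),
                            welch = list(segment_length = 256, overlap = 0.5),
                            model = model_config(),
                            normalization = c("sum", "mean"),
                            mask = NULL,
                            out_dir = NULL) {
  structure(list(generator = generator, window = window, filter = filter,
                 welch = welch, model = model,
                 normalization = match.arg(normalization),
                 mask = mask, out_dir = out_dir),
            class = "pipeline_config")
}

#' Feature matrix of one session
#'
#' Runs the full per-session chain: total acceleration per sensor,
#' zero-phase low-pass filtering, sliding windows, the 19-per-site raw
#' features, effort-report interpolation to the window centers (taken from
#' the first site's windows), and session-baseline normalization.
#'
#' @param session A `fatigue_session` (or anything with `streams` and
#'   `reports` in the same layout).
#' @param window A [window_spec()].
#' @param filter List with `cutoff` and `order`.
#' @param welch List with `segment_length` and `overlap`.
#' @param normalization Passed to [normalize_features()]; `"none"` skips
#'   normalization (used by scale-equivariance checks).
#' @return List of class `feature_matrix`: `session_id`, `features`
#'   (data.frame), `window_index`, `center_time`, `targets`.
#' @export
session_feature_matrix <- function(session,
                                   window = window_spec(),
                                   filter = list(cutoff = 18, order = 4),
                                   welch = list(segment_length = 256,
                                                overlap = 0.5),
                                   normalization = "sum") {
  sites <- names(session$streams)
  site_windows <- list()
  rates <- numeric(0)
  for (site in sites) {
    ser <- compute_total_acceleration(session$streams[[site]], site = site)
    ser <- lowpass_filter(ser, cutoff = filter$cutoff, order = filter$order)
    site_windows[[site]] <- make_windows(ser, window)
    rates[site] <- ser$est_rate
  }
  feats <- assemble_features(site_windows, rates,
                             segment_length = welch$segment_length,
                             overlap = welch$overlap)
  centers <- vapply(site_windows[[1]], `[[`, numeric(1), "center_time")
  trend <- interpolate_effort(session$reports, centers)
  if (normalization != "none") {
    feats <- normalize_features(feats, normalization)
  }
  structure(
    list(session_id = session_id(session),
         features = feats,
         window_index = vapply(site_windows[[1]], `[[`, integer(1), "index"),
         center_time = centers,
         targets = trend$targets),
    class = "feature_matrix"
  )
}

#' Feature matrices for every session of a study
#'
#' @param study A `fatigue_study` (or named list of sessions).
#' @inheritParams session_feature_matrix
#' @return Named list of `feature_matrix` objects.
#' @export
study_feature_matrices <- function(study,
                                   window = window_spec(),
                                   filter = list(cutoff = 18, order = 4),
                                   welch = list(segment_length = 256,
                                                overlap = 0.5),
                                   normalization = "sum") {
  sessions <- if (inherits(study, "fatigue_study")) study$sessions else study
  lapply(sessions, session_feature_matrix, window = window, filter = filter,
         welch = welch, normalization = normalization)
}

#' Run the end-to-end pipeline
#'
#' Generate (or accept) the study, extract per-session normalized feature
#' matrices, run leave-one-session-out selection + forest training, and
#' aggregate the evaluation report. With `config$out_dir` set, the study
#' CSVs, feature tables, a metadata YAML and the report JSON are written
#' there; re-running with an unchanged config reproduces them exactly.
#'
#' @param config A [pipeline_config()].
#' @param study Optional pre-generated `fatigue_study`; by default the
#'   study is generated from `config$generator`.
#' @return An `evaluation_report` (invisibly also written to disk when
#'   `out_dir` is set).
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL) {
  if (is.null(study)) study <- generate_study(config$generator)
  matrices <- study_feature_matrices(
    study, window = config$window, filter = config$filter,
    welch = config$welch, normalization = config$normalization)
  if (!is.null(config$mask)) {
    cols <- if (length(config$mask) == 1 &&
                config$mask %in% c("pelvis_sternum", "pelvis_only", "no_psd")) {
      ablation_columns(names(matrices[[1]]$features), config$mask)
    } else config$mask
    matrices <- lapply(matrices, function(m) {
      list(features = m$features[cols], targets = m$targets)
    })
  }
  results <- run_loso(matrices, config$model)
  report <- evaluation_report(results, config$model)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_study(study, file.path(config$out_dir, "raw"))
    write_feature_tables(matrices, file.path(config$out_dir, "features"),
                         config)
    write_report_json(report, file.path(config$out_dir, "report.json"))
  }
  report
}
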