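#' Write a synthetic study to disk
#'
#' One directory per session (`session_d<day>_w<worker>`) holding one CSV
#' per sensor (`<site>.csv`, columns `timestamp,ax,ay,az`, missing
#' timestamps written as `NaN`) and an `effort.csv` with columns
#' `time_s,effort`; a top-level `manifest.yaml` lists day, worker,
#' duration, seed and file paths per session.
#'
#' @param study A `fatigue_study`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(sessions = list())
  for (id in names(study$sessions)) {
    s <- study$sessions[[id]]
    sdir <- file.path(dir, paste0("session_", id))
    dir.create(sdir, showWarnings = FALSE)
    files <- character(0)
    for (site in names(s$streams)) {
      f <- file.path(sdir, paste0(site, ".csv"))
      utils::write.csv(s$streams[[site]], f, row.names = FALSE, na = "NaN")
      files <- c(files, f)
    }
    ef <- file.path(sdir, "effort.csv")
    utils::write.csv(s$reports, ef, row.names = FALSE)
    manifest$sessions[[id]] <- list(
      day = s$day, worker = s$worker, duration_min = s$duration_min,
      seed = s$seed, directory = basename(sdir),
      sensor_files = basename(files), effort_file = basename(ef))
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read one session directory
#'
#' Accepts any directory following the generator's CSV dialect: one
#' `<site>.csv` per sensor with header `timestamp,ax,ay,az` (missing
#' values as `NaN` or `NA`) and an `effort.csv` with `time_s,effort`.
#'
#' @param sdir Session directory.
#' @param day,worker,duration_min Optional roster metadata (parsed from
#'   the directory name when absent).
#' @return A `fatigue_session`-shaped list usable by
#'   [session_feature_matrix()].
#' @export
read_session <- function(sdir, day = NA_integer_, worker = NA_integer_,
                         duration_min = NA_real_) {
  if (is.na(day)) {
    m <- regmatches(basename(sdir),
                    regexec("d([0-9]+)_w([0-9]+)", basename(sdir)))[[1]]
    if (length(m) == 3) {
      day <- as.integer(m[2]); worker <- as.integer(m[3])
    }
  }
  csvs <- list.files(sdir, pattern = "\\.csv$", full.names = TRUE)
  sensor_csvs <- csvs[basename(csvs) != "effort.csv"]
  streams <- list()
  for (f in sensor_csvs) {
    site <- sub("\\.csv$", "", basename(f))
    streams[[site]] <- utils::read.csv(f, na.strings = c("NA", "NaN"))
  }
  # canonical site order where the standard six are present
  canon <- intersect(fatigue_sites(), names(streams))
  streams <- streams[c(canon, setdiff(names(streams), canon))]
  reports <- utils::read.csv(file.path(sdir, "effort.csv"))
  if (is.na(duration_min)) {
    duration_min <- max(vapply(streams, function(st) {
      max(st$timestamp, na.rm = TRUE)
    }, numeric(1))) / 60
  }
  structure(list(day = day, worker = worker, duration_min = duration_min,
                 streams = streams, reports = reports),
            class = "fatigue_session")
}

#' Read a whole study directory
#'
#' @param dir Directory produced by [write_study()] (a `manifest.yaml`
#'   is used when present, otherwise all `session_*` subdirectories).
#' @return A `fatigue_study`-shaped list.
#' @export
read_study <- function(dir) {
  mf <- file.path(dir, "manifest.yaml")
  sessions <- list()
  if (file.exists(mf)) {
    manifest <- yaml::read_yaml(mf)
    for (id in names(manifest$sessions)) {
      e <- manifest$sessions[[id]]
      sessions[[id]] <- read_session(
        file.path(dir, e$directory), day = e$day, worker = e$worker,
        duration_min = e$duration_min)
    }
  } else {
    for (sdir in list.dirs(dir, recursive = FALSE)) {
      if (!startsWith(basename(sdir), "session_")) next
      s <- read_session(sdir)
      sessions[[sub("^session_", "", basename(sdir))]] <- s
    }
  }
  structure(list(sessions = sessions, config = NULL),
            class = "fatigue_study")
}

#' Validate a study directory
#'
#' Per session: all six standard sensor CSVs present with the expected
#' header, timestamps strictly increasing after dropping missing values,
#' and exactly three effort reports.
#'
#' @param dir Study directory.
#' @return data.frame `session`, `pass`, `reason` (empty string when ok).
#' @export
validate_inputs <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  sdirs <- list.dirs(dir, recursive = FALSE)
  sdirs <- sdirs[startsWith(basename(sdirs), "session_")]
  rows <- lapply(sdirs, function(sdir) {
    id <- sub("^session_", "", basename(sdir))
    fail <- function(reason) data.frame(session = id, pass = FALSE,
                                        reason = reason)
    for (site in fatigue_sites()) {
      f <- file.path(sdir, paste0(site, ".csv"))
      if (!file.exists(f)) return(fail(paste("missing sensor:", site)))
      hd <- names(utils::read.csv(f, nrows = 1))
      if (!identical(hd, c("timestamp", "ax", "ay", "az"))) {
        return(fail(paste("bad header in", basename(f))))
      }
      st <- utils::read.csv(f, na.strings = c("NA", "NaN"))
      tt <- st$timestamp[!is.na(st$timestamp)]
      if (length(tt) < 2) return(fail(paste("empty stream:", site)))
      if (is.unsorted(tt, strictly = TRUE)) {
        return(fail(paste("non-monotone timestamps:", site)))
      }
    }
    ef <- file.path(sdir, "effort.csv")
    if (!file.exists(ef)) return(fail("missing effort.csv"))
    er <- utils::read.csv(ef)
    if (nrow(er) < 3) return(fail("insufficient reports"))
    data.frame(session = id, pass = TRUE, reason = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write per-session feature tables as CSV
#'
#' One `features_<session>.csv` per session (columns `session_id`,
#' `window_index`, `center_time_s`, `target`, then the feature columns)
#' plus a `metadata.yaml` recording the Welch settings, filter, window
#' spec and normalization variant that produced them.
#'
#' @param matrices Named list of feature matrices.
#' @param dir Output directory.
#' @param config The `pipeline_config` used (recorded in the metadata).
#' @return The directory, invisibly.
#' @export
write_feature_tables <- function(matrices, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(matrices)) {
    m <- matrices[[id]]
    meta <- data.frame(
      session_id = id,
      window_index = if (!is.null(m$window_index)) m$window_index
                     else seq_len(nrow(m$features)) - 1L,
      center_time_s = if (!is.null(m$center_time)) m$center_time
                      else NA_real_,
      target = m$targets)
    utils::write.csv(cbind(meta, m$features),
                     file.path(dir, paste0("features_", id, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(config)) {
    yaml::write_yaml(
      list(window = unclass(config$window), filter = config$filter,
           welch = config$welch, normalization = config$normalization,
           model = unclass(config$model)),
      file.path(dir, "metadata.yaml"))
  }
  invisible(dir)
}

#' Write an evaluation report as JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(per_split = report$per_split,
         average_mae = report$average_mae,
         average_mse = report$average_mse,
         average_corr = report$average_corr,
         importance_sums = as.list(report$importance_sums),
         config = unclass(report$config)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
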