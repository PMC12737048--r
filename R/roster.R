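#' Sensor sites monitored by the instrumented work vest
#'
#' Six accelerometer placements, in the canonical order used for feature
#' column layout: both thighs, both upper arms, sternum, pelvis.
#'
#' @return Character vector of six site labels.
#' @export
fatigue_sites <- function() {
  c("left_thigh", "right_thigh", "left_upper_arm", "right_upper_arm",
    "sternum", "pelvis")
}

#' Default hauling-study roster
#'
#' The study roster of the hauling field campaign: 8 worker-day sessions
#' recorded from 5 workers over 5 days. Worker 3 was absent on day 2 and
#' worker 4 recorded a single session, so the roster is not a full
#' worker-by-day grid.
#'
#' @return A data.frame with columns `day`, `worker`, `duration_min`, one
#'   row per recorded session.
#' @examples
#' default_roster()
#' @export
default_roster <- function() {
  data.frame(
    day          = c(1L, 1L, 2L, 3L, 3L, 4L, 4L, 5L),
    worker       = c(1L, 2L, 2L, 1L, 3L, 4L, 5L, 5L),
    duration_min = c(29.2, 15.3, 16.6, 32.2, 26.1, 30.2, 20.4, 33.0)
  )
}

validate_roster <- function(roster) {
  req <- c("day", "worker", "duration_min")
  if (!is.data.frame(roster) || !all(req %in% names(roster))) {
    stop("invalid config field 'roster': need columns day, worker, duration_min")
  }
  if (nrow(roster) == 0) stop("invalid config field 'roster': empty roster")
  if (any(roster$duration_min < 13)) {
    stop("invalid config field 'roster': duration_min must be >= 13 ",
         "(one 12-min window plus slide)")
  }
  key <- paste(roster$day, roster$worker)
  if (anyDuplicated(key)) {
    stop("invalid config field 'roster': duplicate (day, worker) pair")
  }
  invisible(roster)
}
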