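#' Single-animal trajectory
#'
#' A time-stamped centroid path of one animal in arena millimeters, sampled on
#' a uniform grid (default 2 frames/s, i.e. 0.5 s spacing), with an optional
#' per-sample crawling speed and, for simulated animals, ground-truth
#' behavioral state labels.
#'
#' @param worm_id character scalar identifier.
#' @param t numeric vector of times (s), strictly increasing and uniform.
#' @param xy n x 2 numeric matrix of positions (mm).
#' @param speed optional numeric vector of instantaneous speeds (mm/s).
#' @param source one of `"simulated"`, `"tracked"`, `"imported"`.
#' @param state_truth optional character vector of ground-truth states
#'   (`run`, `pause`, `turn`, `pirouette`), same length as `t`.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(worm_id, t, xy, speed = NULL,
                       source = c("imported", "simulated", "tracked"),
                       state_truth = NULL) {
  source <- match.arg(source)
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, nrow(xy) == length(t))
  if (length(t) > 1) {
    dts <- diff(t)
    if (any(dts <= 0)) stop("trajectory times must be strictly increasing")
    if (max(dts) - min(dts) > 1e-6)
      stop("trajectory time grid must be uniform")
  }
  if (!all(is.finite(xy))) stop("trajectory positions must be finite")
  if (!is.null(speed)) {
    stopifnot(length(speed) == length(t))
    if (any(speed < 0)) stop("speed must be non-negative")
  }
  if (!is.null(state_truth)) stopifnot(length(state_truth) == length(t))
  structure(list(worm_id = as.character(worm_id), t = as.numeric(t),
                 xy = unname(xy), speed = speed, source = source,
                 state_truth = state_truth),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> worm %s: %d samples, t = [%.1f, %.1f] s (%s)\n",
              x$worm_id, length(x$t), min(x$t), max(x$t), x$source))
  invisible(x)
}

trajectory_dt <- function(traj) {
  if (length(traj$t) < 2) return(NA_real_)
  (traj$t[length(traj$t)] - traj$t[1]) / (length(traj$t) - 1)
}

#' Instantaneous centroid speed
#'
#' Speed as step displacement over step duration; the first sample duplicates
#' the first interval so speed has the same length as the time grid.
#'
#' @param traj a [trajectory()].
#' @return the trajectory with `$speed` populated.
#' @export
compute_speed <- function(traj) {
  n <- length(traj$t)
  if (n < 2) stop("need at least 2 samples to compute speed")
  d <- sqrt(diff(traj$xy[, 1])^2 + diff(traj$xy[, 2])^2)
  v <- d / diff(traj$t)
  traj$speed <- c(v[1], v)
  traj
}

#' Clip a trajectory to a time window
#'
#' @param traj a [trajectory()].
#' @param t_start,t_end window bounds in s (inclusive).
#' @return the clipped trajectory, or `NULL` if no samples fall inside.
#' @export
clip_trajectory <- function(traj, t_start, t_end) {
  keep <- traj$t >= t_start & traj$t <= t_end
  if (!any(keep)) return(NULL)
  trajectory(traj$worm_id, traj$t[keep], traj$xy[keep, , drop = FALSE],
             speed = if (!is.null(traj$speed)) traj$speed[keep],
             source = traj$source,
             state_truth = if (!is.null(traj$state_truth)) traj$state_truth[keep])
}

#' Analysis window for track selection
#'
#' Defines the interval over which navigation indices are computed. The
#' standard gradient assay analyzes the first 10 min after release and
#' requires at least 5 min of track presence inside the window, which
#' prevents one animal from contributing multiple short tracks. The
#' small-plate (optogenetics-format) preset uses 0--300 s.
#'
#' @param t_start,t_end window bounds (s).
#' @param min_active_s minimum in-window track duration (s).
#' @return an object of class `analysis_window`.
#' @export
analysis_window <- function(t_start = 0, t_end = 600, min_active_s = 300) {
  if (t_end <= t_start) stop("t_end must exceed t_start")
  if (min_active_s > t_end - t_start)
    stop("min_active_s cannot exceed the window length")
  structure(list(t_start = t_start, t_end = t_end, min_active_s = min_active_s),
            class = "analysis_window")
}
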