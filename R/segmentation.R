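#' Behavioral segmentation parameters
#'
#' Thresholds for the rule-based state labeling. Defaults follow the standard
#' centroid-based segmentation of crawling C. elegans: a sample is a pause
#' when speed stays below 0.01 mm/s for more than half of a 10 s sliding
#' window; a turn core is a vertex angle below 80 degrees between the track
#' points 0.3 mm behind and ahead, extended forward while speed stays below
#' 0.1 mm/s (reversals and omega turns are both recognized as turns); turns
#' separated by less than 3.8 s bundle into a pirouette; the klinotaxis rule
#' scores the first 5 s of each post-reorientation run.
#'
#' @param pause_speed pause speed threshold (mm/s).
#' @param pause_window_s sliding window length (s).
#' @param turn_arc_mm along-path arc distance to the angle reference points.
#' @param turn_angle_deg vertex angle threshold (deg, strict `<`).
#' @param postturn_speed post-turn extension speed threshold (mm/s).
#' @param pirouette_gap_s maximum gap between turns bundled into a pirouette.
#' @param klino_stretch_s run stretch scored by the klinotaxis index.
#' @param angle_convention `"vertex"` measures the geometric angle at the
#'   track point between the back- and ahead-vectors (straight path ~180
#'   degrees); `"complement"` uses the angle between the back-to-point and
#'   point-to-ahead displacement vectors instead.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(pause_speed = 0.01, pause_window_s = 10,
                                turn_arc_mm = 0.3, turn_angle_deg = 80,
                                postturn_speed = 0.1, pirouette_gap_s = 3.8,
                                klino_stretch_s = 5,
                                angle_convention = c("vertex", "complement")) {
  angle_convention <- match.arg(angle_convention)
  stopifnot(pause_speed > 0, pause_window_s > 0, turn_arc_mm > 0,
            turn_angle_deg > 0, turn_angle_deg < 180, postturn_speed > 0,
            pirouette_gap_s > 0, klino_stretch_s > 0,
            pause_speed < postturn_speed)
  structure(list(pause_speed = pause_speed, pause_window_s = pause_window_s,
                 turn_arc_mm = turn_arc_mm, turn_angle_deg = turn_angle_deg,
                 postturn_speed = postturn_speed,
                 pirouette_gap_s = pirouette_gap_s,
                 klino_stretch_s = klino_stretch_s,
                 angle_convention = angle_convention),
            class = "segmentation_params")
}

#' Label pause samples
#'
#' Sample `t` is a pause iff strictly more than half of the samples in the
#' window `[t - W/2, t + W/2]` (intersected with the track) have speed below
#' `pause_speed`; truncated windows at track ends use the available samples.
#'
#' @param traj a [trajectory()] with speed populated.
#' @param sp a [segmentation_params()].
#' @return logical vector, one element per sample.
#' @export
label_pauses <- function(traj, sp) {
  stopifnot(!is.null(traj$speed))
  n <- length(traj$t)
  dt <- trajectory_dt(traj)
  half_n <- as.integer(floor(sp$pause_window_s / 2 / dt + 1e-9))
  slow <- as.integer(traj$speed < sp$pause_speed)
  cs <- cumsum(slow)
  i <- seq_len(n)
  lo <- pmax(1L, i - half_n)
  hi <- pmin(n, i + half_n)
  cnt <- cs[hi] - c(0, cs)[lo]
  nwin <- hi - lo + 1L
  cnt * 2L > nwin
}

## first sample indices at >= arc mm along-path distance backward/forward;
## NA where the track end is reached first
arc_reference_points <- function(xy, arc) {
  n <- nrow(xy)
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  s <- c(0, cumsum(seg))
  back <- rep(NA_integer_, n)
  fwd <- rep(NA_integer_, n)
  j <- 1L
  for (i in seq_len(n)) {
    # largest j with s[i] - s[j] >= arc (first crossing walking backward)
    while (j < i && s[i] - s[j + 1] >= arc) j <- j + 1L
    if (s[i] - s[j] >= arc) back[i] <- j
  }
  k <- n
  for (i in rev(seq_len(n))) {
    while (k > i && s[k - 1] - s[i] >= arc) k <- k - 1L
    if (s[k] - s[i] >= arc) fwd[i] <- k
  }
  list(back = back, fwd = fwd)
}

#' Label turn samples
#'
#' A turn core is any sample whose vertex angle -- between the vectors from
#' the sample to the track points at least `turn_arc_mm` behind and ahead
#' along the path -- is strictly below `turn_angle_deg` (a straight path
#' gives about 180 degrees). Samples where either reference point is
#' unreachable (track ends) are not evaluable. Each core is then extended
#' forward over contiguous samples with speed below `postturn_speed`.
#'
#' @inheritParams label_pauses
#' @return logical vector, one element per sample.
#' @export
label_turns <- function(traj, sp) {
  stopifnot(!is.null(traj$speed))
  n <- length(traj$t)
  refs <- arc_reference_points(traj$xy, sp$turn_arc_mm)
  turn <- rep(FALSE, n)
  ok <- which(!is.na(refs$back) & !is.na(refs$fwd))
  if (length(ok)) {
    b <- refs$back[ok]; f <- refs$fwd[ok]
    vb <- traj$xy[b, , drop = FALSE] - traj$xy[ok, , drop = FALSE]
    vf <- traj$xy[f, , drop = FALSE] - traj$xy[ok, , drop = FALSE]
    if (sp$angle_convention == "complement") vb <- -vb
    dotp <- vb[, 1] * vf[, 1] + vb[, 2] * vf[, 2]
    nb <- sqrt(vb[, 1]^2 + vb[, 2]^2)
    nf <- sqrt(vf[, 1]^2 + vf[, 2]^2)
    ang <- acos(pmin(pmax(dotp / (nb * nf), -1), 1)) * 180 / pi
    turn[ok] <- nb > 0 & nf > 0 & ang < sp$turn_angle_deg
  }
  # forward-only post-turn extension while speed < postturn_speed
  i <- 1L
  while (i <= n) {
    if (turn[i]) {
      while (i < n && turn[i + 1]) i <- i + 1L
      j <- i + 1L
      while (j <= n && !turn[j] && traj$speed[j] < sp$postturn_speed) {
        turn[j] <- TRUE
        j <- j + 1L
      }
      i <- j
    } else i <- i + 1L
  }
  turn
}

## maximal TRUE intervals as (start_idx, end_idx) rows
bool_intervals <- function(b) {
  n <- length(b)
  if (!any(b)) return(matrix(integer(0), ncol = 2))
  d <- diff(c(FALSE, b, FALSE))
  cbind(which(d == 1), which(d == -1) - 1L)
}

#' Bundle turn intervals into pirouettes
#'
#' Chains of turn intervals whose successive gaps are strictly shorter than
#' `pirouette_gap_s` merge into one pirouette spanning first start to last
#' end; isolated turns keep kind `"turn"`.
#'
#' @param turn_iv matrix of turn intervals (rows of start/end sample index).
#' @param t time grid of the trajectory.
#' @param sp a [segmentation_params()].
#' @return data frame with `start_idx`, `end_idx`, `kind`, `n_turns`.
#' @export
bundle_pirouettes <- function(turn_iv, t, sp) {
  if (nrow(turn_iv) == 0)
    return(data.frame(start_idx = integer(0), end_idx = integer(0),
                      kind = character(0), n_turns = integer(0)))
  groups <- cumsum(c(1, (t[turn_iv[-1, 1]] - t[turn_iv[-nrow(turn_iv), 2]]) >=
                          sp$pirouette_gap_s))
  out <- lapply(split(seq_len(nrow(turn_iv)), groups), function(ix) {
    data.frame(start_idx = turn_iv[ix[1], 1],
               end_idx = turn_iv[ix[length(ix)], 2],
               kind = if (length(ix) > 1) "pirouette" else "turn",
               n_turns = length(ix))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Segment a trajectory into behavioral states
#'
#' Applies the pause and turn rules, bundles pirouettes, and resolves
#' overlaps with the precedence turn/pirouette > pause > run. Runs are the
#' maximal remaining intervals; each run's direction is the sign of its net
#' displacement along the gradient axis (`up`, `down`, or `tie` at exactly
#' zero). Reorientations are the maximal turn-or-pirouette intervals.
#'
#' @param traj a [trajectory()] with speed populated.
#' @param sp a [segmentation_params()].
#' @param g a [gradient_spec()] (defines "up-gradient" for run directions).
#' @return a `behavior_annotation`: list with `worm_id`, `t`, `state`
#'   (character per sample), `runs` (data frame `start_idx`, `end_idx`,
#'   `start_s`, `end_s`, `direction`), `reorientations` (data frame with
#'   `kind`), and `params_used`.
#' @export
segment_trajectory <- function(traj, sp = segmentation_params(),
                               g = gradient_spec()) {
  stopifnot(!is.null(traj$speed))
  n <- length(traj$t)
  pause <- label_pauses(traj, sp)
  turn <- label_turns(traj, sp)
  events <- bundle_pirouettes(bool_intervals(turn), traj$t, sp)
  state <- rep("run", n)
  state[pause] <- "pause"
  for (r in seq_len(nrow(events)))
    state[events$start_idx[r]:events$end_idx[r]] <- events$kind[r]
  s_ax <- axis_coord(g, traj$xy)
  run_iv <- bool_intervals(state == "run")
  runs <- data.frame(start_idx = run_iv[, 1], end_idx = run_iv[, 2])
  if (nrow(runs)) {
    runs$start_s <- traj$t[runs$start_idx]
    runs$end_s <- traj$t[runs$end_idx]
    net <- s_ax[runs$end_idx] - s_ax[runs$start_idx]
    runs$direction <- ifelse(net > 0, "up", ifelse(net < 0, "down", "tie"))
  } else {
    runs$start_s <- runs$end_s <- numeric(0)
    runs$direction <- character(0)
  }
  reo <- events
  if (nrow(reo)) {
    reo$start_s <- traj$t[reo$start_idx]
    reo$end_s <- traj$t[reo$end_idx]
  } else {
    reo$start_s <- reo$end_s <- numeric(0)
  }
  structure(list(worm_id = traj$worm_id, t = traj$t, state = state,
                 runs = runs, reorientations = reo, params_used = sp,
                 axis_coord = s_ax),
            class = "behavior_annotation")
}

#' @export
print.behavior_annotation <- function(x, ...) {
  cat(sprintf("<behavior_annotation> worm %s: %d samples, %d runs, %d reorientations\n",
              x$worm_id, length(x$t), nrow(x$runs), nrow(x$reorientations)))
  print(round(table(x$state) / length(x$state), 3))
  invisible(x)
}
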