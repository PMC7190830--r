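#' Locomotion parameters for the run-and-tumble simulator
#'
#' Parameterizes a centroid-level worm locomotion model with two independent
#' gradient-navigation biases: a biased-random-walk bias `brw_bias` (run
#' termination is suppressed while heading up-gradient, so up-gradient runs
#' last longer) and a klinotaxis bias `klinotaxis_bias` (the heading chosen
#' after a reorientation points into the up-gradient half-circle with
#' probability (1 + kappa)/2). With both biases zero the motion is an
#' unbiased run-and-tumble walk.
#'
#' @param speed_mean,speed_sd run crawling speed (mm/s): one truncated-normal
#'   draw per run (truncated at zero).
#' @param run_rate_hz baseline run-termination rate lambda0 (1/s).
#' @param brw_bias beta in `[-1, 1]`; per-step run-termination probability is
#'   `lambda0 * dt * (1 - beta * cos(phi))` clamped to `[0, 1]`, `phi` the
#'   angle between heading and the up-gradient axis.
#' @param klinotaxis_bias kappa in `[-1, 1]`; post-reorientation heading is
#'   drawn uniformly from the up-gradient half-circle with probability
#'   `(1 + kappa)/2`, otherwise from the down half.
#' @param pirouette_prob probability that a reorientation is a multi-turn
#'   pirouette (2--4 turns separated by gaps shorter than 3.8 s).
#' @param pause_rate_hz,pause_mean_s Poisson pause initiation rate during
#'   runs and mean (exponential) pause duration.
#' @param turn_dwell_s duration of the stationary turn core.
#' @param heading_noise_deg per-step wrapped-Gaussian heading jitter (deg)
#'   during runs.
#' @return an object of class `locomotion_params`.
#' @export
locomotion_params <- function(speed_mean = 0.12, speed_sd = 0.01,
                              run_rate_hz = 0.05, brw_bias = 0,
                              klinotaxis_bias = 0, pirouette_prob = 0.25,
                              pause_rate_hz = 0.005, pause_mean_s = 12,
                              turn_dwell_s = 1.5, heading_noise_deg = 5) {
  stopifnot(speed_mean > 0, speed_sd >= 0, run_rate_hz > 0,
            abs(brw_bias) <= 1, abs(klinotaxis_bias) <= 1,
            pirouette_prob >= 0, pirouette_prob <= 1,
            pause_rate_hz >= 0, pause_mean_s > 0,
            turn_dwell_s > 0, heading_noise_deg >= 0)
  structure(list(speed_mean = speed_mean, speed_sd = speed_sd,
                 run_rate_hz = run_rate_hz, brw_bias = brw_bias,
                 klinotaxis_bias = klinotaxis_bias,
                 pirouette_prob = pirouette_prob,
                 pause_rate_hz = pause_rate_hz, pause_mean_s = pause_mean_s,
                 turn_dwell_s = turn_dwell_s,
                 heading_noise_deg = heading_noise_deg),
            class = "locomotion_params")
}

draw_run_speed <- function(p) {
  repeat {
    v <- stats::rnorm(1, p$speed_mean, p$speed_sd)
    if (v > 0) return(v)
  }
}

## heading after a reorientation: up-gradient half-circle w.p. (1+kappa)/2
draw_post_turn_heading <- function(p, axis_angle) {
  up <- stats::runif(1) < (1 + p$klinotaxis_bias) / 2
  offset <- stats::runif(1, -pi / 2, pi / 2)
  if (up) axis_angle + offset else axis_angle + pi + offset
}

#' Simulate one worm on a gradient
#'
#' Discrete-time (2 Hz) run-and-tumble state machine; see
#' [locomotion_params()] for the model. Ground-truth state labels (`run`,
#' `pause`, `turn`, `pirouette`) are retained on the returned trajectory; a
#' sample's label is the state that generated the step ending at that sample.
#'
#' @param params a [locomotion_params()].
#' @param g a [gradient_spec()].
#' @param duration_s simulated duration (s).
#' @param start_xy numeric(2) initial position (mm).
#' @param arena `c(xmin, xmax, ymin, ymax)` bounds (mm).
#' @param boundary `"reflect"` (default) mirrors the worm back into the
#'   arena; `"truncate"` ends the trajectory at the first boundary contact,
#'   emulating a tracker that terminates tracks at the arena edge.
#' @param worm_id identifier for the returned trajectory.
#' @param dt sample spacing (s).
#' @return a [trajectory()] with `speed` and `state_truth` populated.
#' @export
simulate_worm <- function(params, g, duration_s, start_xy,
                          arena = c(0, 120, 0, 120),
                          boundary = c("reflect", "truncate"),
                          worm_id = "w1", dt = 0.5) {
  boundary <- match.arg(boundary)
  p <- params
  n_int <- round(duration_s / dt)
  stopifnot(n_int >= 1)
  if (p$run_rate_hz * dt * (1 + abs(p$brw_bias)) > 1)
    warning("run termination probability clamps at 1: rates too high for the time grid")
  axis_angle <- atan2(g$axis[2], g$axis[1])
  dwell_n <- max(1L, as.integer(round(p$turn_dwell_s / dt)))
  noise_sd <- p$heading_noise_deg * pi / 180

  u_pause <- stats::runif(n_int)
  u_term <- stats::runif(n_int)
  eps <- stats::rnorm(n_int, 0, noise_sd)

  x <- numeric(n_int + 1); y <- numeric(n_int + 1)
  state <- character(n_int)
  x[1] <- start_xy[1]; y[1] <- start_xy[2]
  heading <- stats::runif(1, 0, 2 * pi)
  run_speed <- draw_run_speed(p)
  mode <- "run"
  turn_left <- 0L; gap_left <- 0L; pause_left <- 0L
  turns_remaining <- 0L; in_burst <- FALSE
  gap_speed <- run_speed
  n_kept <- n_int + 1L

  for (k in seq_len(n_int)) {
    step <- c(0, 0)
    if (mode == "turn") {
      state[k] <- if (in_burst) "pirouette" else "turn"
      turn_left <- turn_left - 1L
      if (turn_left == 0L) {
        heading <- draw_post_turn_heading(p, axis_angle)
        if (turns_remaining > 0L) {
          mode <- "gap"
          gap_left <- max(1L, as.integer(round(stats::runif(1, 0.5, 3.5) / dt)))
          gap_speed <- draw_run_speed(p)
        } else {
          mode <- "run"
          run_speed <- draw_run_speed(p)
          in_burst <- FALSE
        }
      }
    } else if (mode == "gap") {
      state[k] <- "pirouette"
      heading <- heading + eps[k]
      step <- gap_speed * dt * c(cos(heading), sin(heading))
      gap_left <- gap_left - 1L
      if (gap_left == 0L) {
        mode <- "turn"
        turn_left <- dwell_n
        turns_remaining <- turns_remaining - 1L
      }
    } else if (mode == "pause") {
      state[k] <- "pause"
      pause_left <- pause_left - 1L
      if (pause_left == 0L) mode <- "run"
    } else { # run
      if (u_pause[k] < p$pause_rate_hz * dt) {
        mode <- "pause"
        pause_left <- max(1L, as.integer(round(stats::rexp(1, 1 / p$pause_mean_s) / dt)))
        state[k] <- "pause"
        pause_left <- pause_left - 1L
        if (pause_left == 0L) mode <- "run"
      } else {
        p_term <- p$run_rate_hz * dt *
          (1 - p$brw_bias * cos(heading - axis_angle))
        p_term <- min(max(p_term, 0), 1)
        if (u_term[k] < p_term) {
          in_burst <- stats::runif(1) < p$pirouette_prob
          turns_remaining <- if (in_burst) sample(2:4, 1) - 1L else 0L
          mode <- "turn"
          turn_left <- dwell_n
          state[k] <- if (in_burst) "pirouette" else "turn"
          turn_left <- turn_left - 1L
          if (turn_left == 0L) { # single-sample dwell
            heading <- draw_post_turn_heading(p, axis_angle)
            if (turns_remaining > 0L) {
              mode <- "gap"
              gap_left <- max(1L, as.integer(round(stats::runif(1, 0.5, 3.5) / dt)))
              gap_speed <- draw_run_speed(p)
            } else {
              mode <- "run"
              run_speed <- draw_run_speed(p)
              in_burst <- FALSE
            }
          }
        } else {
          state[k] <- "run"
          heading <- heading + eps[k]
          step <- run_speed * dt * c(cos(heading), sin(heading))
        }
      }
    }
    nx <- x[k] + step[1]; ny <- y[k] + step[2]
    if (nx < arena[1] || nx > arena[2] || ny < arena[3] || ny > arena[4]) {
      if (boundary == "truncate") { n_kept <- k; break }
      while (nx < arena[1] || nx > arena[2]) {
        if (nx < arena[1]) nx <- 2 * arena[1] - nx else nx <- 2 * arena[2] - nx
        heading <- pi - heading
      }
      while (ny < arena[3] || ny > arena[4]) {
        if (ny < arena[3]) ny <- 2 * arena[3] - ny else ny <- 2 * arena[4] - ny
        heading <- -heading
      }
    }
    x[k + 1] <- nx; y[k + 1] <- ny
  }

  idx <- seq_len(n_kept)
  labels <- c(state[1], state)[idx]
  tr <- trajectory(worm_id, (idx - 1) * dt, cbind(x[idx], y[idx]),
                   source = "simulated", state_truth = labels)
  compute_speed(tr)
}

#' Simulate a worm population on a gradient
#'
#' Each worm is an independent [simulate_worm()] realization. Reproducibility
#' uses a documented counter scheme: worm `i` runs under its own RNG seed
#' `(seed + i * 10007) mod (2^31 - 1)`, so populations are bitwise
#' reproducible and invariant to reordering.
#'
#' @inheritParams simulate_worm
#' @param n_worms number of animals (>= 1).
#' @param seed master seed (integer).
#' @param release_xy release point (mm); defaults to the arena center, which
#'   for the default plate geometry sits at the gradient midpoint.
#' @param start_jitter_mm uniform scatter of start positions around the
#'   release point (mm, each coordinate).
#' @return list of [trajectory()] objects with ground-truth state labels.
#' @export
simulate_population <- function(params, g, n_worms, duration_s, seed,
                                arena = c(0, 120, 0, 120),
                                release_xy = c(mean(arena[1:2]), mean(arena[3:4])),
                                start_jitter_mm = 3,
                                boundary = "reflect", dt = 0.5) {
  stopifnot(n_worms >= 1, duration_s >= 60)
  lapply(seq_len(n_worms), function(i) {
    set.seed((as.integer(seed) + i * 10007L) %% 2147483647L)
    start <- release_xy + stats::runif(2, -start_jitter_mm, start_jitter_mm)
    start[1] <- min(max(start[1], arena[1]), arena[2])
    start[2] <- min(max(start[2], arena[3]), arena[4])
    simulate_worm(params, g, duration_s, start, arena = arena,
                  boundary = boundary, worm_id = sprintf("sim%03d", i), dt = dt)
  })
}
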