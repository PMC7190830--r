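# Fixture builders used across test files. All fixtures are generated in
# code; nothing is read from disk.

default_gradient <- function() wormnav::gradient_spec()

# trajectory from an explicit position matrix on a uniform 0.5 s grid
make_traj <- function(xy, dt = 0.5, worm_id = "fx") {
  tr <- wormnav::trajectory(worm_id, seq(0, by = dt, length.out = nrow(xy)), xy)
  wormnav::compute_speed(tr)
}

# constant-velocity straight track: start, heading (rad), speed (mm/s)
straight_traj <- function(n, start = c(10, 10), heading = pi / 2,
                          speed = 0.1, dt = 0.5, worm_id = "straight") {
  steps <- speed * dt * c(cos(heading), sin(heading))
  xy <- cbind(start[1] + (0:(n - 1)) * steps[1],
              start[2] + (0:(n - 1)) * steps[2])
  make_traj(xy, dt, worm_id)
}

# piecewise-constant-heading track: one row per leg (heading rad, n steps)
legs_traj <- function(legs, start = c(20, 20), speed = 0.1, dt = 0.5,
                      worm_id = "legs") {
  xy <- matrix(start, 1, 2)
  pos <- start
  for (r in seq_len(nrow(legs))) {
    h <- legs[r, 1]
    for (k in seq_len(legs[r, 2])) {
      pos <- pos + speed * dt * c(cos(h), sin(h))
      xy <- rbind(xy, pos)
    }
  }
  make_traj(xy, dt, worm_id)
}

# quick noisy random-walk track for property tests
random_traj <- function(n, seed, step_sd = 0.06, start = c(40, 40),
                        worm_id = paste0("rnd", seed)) {
  set.seed(seed)
  xy <- cbind(start[1] + cumsum(c(0, rnorm(n - 1, 0, step_sd))),
              start[2] + cumsum(c(0, rnorm(n - 1, 0, step_sd))))
  make_traj(xy, worm_id = worm_id)
}

# simulated tracks of mixed regimes for oracle/antisymmetry suites
simulated_test_tracks <- function(n_tracks, duration_s, seed) {
  g <- default_gradient()
  out <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    set.seed(seed + i)
    p <- wormnav::locomotion_params(
      speed_mean = runif(1, 0.08, 0.18),
      run_rate_hz = runif(1, 0.03, 0.12),
      brw_bias = runif(1, -0.6, 0.6),
      klinotaxis_bias = runif(1, -0.6, 0.6),
      pirouette_prob = runif(1, 0, 0.5),
      pause_rate_hz = runif(1, 0, 0.02),
      heading_noise_deg = runif(1, 0, 15))
    out[[i]] <- wormnav::simulate_population(p, g, 1, duration_s,
                                             seed = seed * 1000 + i)[[1]]
    out[[i]]$worm_id <- sprintf("mix%03d", i)
  }
  out
}

# low-variance regime where simulated states are well separated, so pipeline
# labels can be compared against ground truth
clean_regime_params <- function() {
  wormnav::locomotion_params(speed_mean = 0.12, speed_sd = 0.005,
                             run_rate_hz = 0.05, pirouette_prob = 0,
                             pause_rate_hz = 0.004, pause_mean_s = 15,
                             heading_noise_deg = 3)
}
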