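#' Foraging analysis parameters
#'
#' @param bin_s averaging interval for speed and angular speed (default 10 s).
#' @param line_slope roaming/dwelling separation line in speed--angular-speed
#'   space, `Speed = Curvature / 450`: slope in (mm/s) per (deg/s).
#' @param min_track_s_on_food minimum on-food track duration (default 20 min).
#' @param offfood_duration_s standard off-food local-search assay duration.
#' @return an object of class `foraging_params`.
#' @export
foraging_params <- function(bin_s = 10, line_slope = 1 / 450,
                            min_track_s_on_food = 1200,
                            offfood_duration_s = 900) {
  stopifnot(bin_s > 0, line_slope > 0)
  structure(list(bin_s = bin_s, line_slope = line_slope,
                 min_track_s_on_food = min_track_s_on_food,
                 offfood_duration_s = offfood_duration_s),
            class = "foraging_params")
}

#' Bin speed and angular speed over fixed intervals
#'
#' Heading is taken from successive displacements of the (smoothed) path;
#' angular speed is the absolute wrapped heading change per unit time in
#' deg/s. Both are averaged over consecutive non-overlapping `bin_s` bins
#' aligned to the track start; an incomplete trailing bin is dropped.
#' Static samples have no defined heading and are skipped within their bin's
#' angular-speed average.
#'
#' @param traj a [trajectory()] with speed populated.
#' @param fp a [foraging_params()].
#' @return data frame with `bin`, `t_mid`, `speed`, `ang_speed` (deg/s;
#'   `NaN` when no angular sample in the bin was defined).
#' @export
bin_speed_curvature <- function(traj, fp = foraging_params()) {
  stopifnot(!is.null(traj$speed))
  n <- length(traj$t)
  dt <- trajectory_dt(traj)
  per_bin <- as.integer(round(fp$bin_s / dt))
  if (n < per_bin) stop("track shorter than one full bin")
  dx <- diff(traj$xy[, 1]); dy <- diff(traj$xy[, 2])
  moving <- (dx^2 + dy^2) > 0
  heading <- rep(NA_real_, n - 1)
  heading[moving] <- atan2(dy[moving], dx[moving])
  dh <- heading[-1] - heading[-(n - 1)]
  dh <- atan2(sin(dh), cos(dh)) # wrap to (-pi, pi]
  # angular-speed sample i corresponds to trajectory sample i + 1
  ang <- c(NA_real_, abs(dh) * 180 / pi / dt, NA_real_)
  bin_of <- pmin((seq_len(n) - 1L) %/% per_bin + 1L, .Machine$integer.max)
  n_bins <- n %/% per_bin
  out <- lapply(seq_len(n_bins), function(b) {
    ix <- which(bin_of == b)
    a <- ang[ix]
    data.frame(bin = b,
               t_mid = mean(traj$t[ix]),
               speed = mean(traj$speed[ix]),
               ang_speed = if (any(!is.na(a))) mean(a, na.rm = TRUE) else NaN)
  })
  do.call(rbind, out)
}

#' Classify bins as roaming or dwelling
#'
#' A bin is roaming iff its mean speed lies strictly above the separation
#' line, `speed > ang_speed * line_slope`; points on the line (including
#' fully static bins) are dwelling.
#'
#' @param bins output of [bin_speed_curvature()].
#' @param fp a [foraging_params()].
#' @return character vector (`"roaming"`/`"dwelling"`), one per bin.
#' @export
classify_roaming_dwelling <- function(bins, fp = foraging_params()) {
  ang <- ifelse(is.nan(bins$ang_speed), 0, bins$ang_speed)
  ifelse(bins$speed > ang * fp$line_slope, "roaming", "dwelling")
}

#' Per-animal foraging summary (on food)
#'
#' Fractions of time roaming and dwelling (summing to 1) and the mean speed
#' within each state (undefined when a state is absent).
#'
#' @param labels output of [classify_roaming_dwelling()].
#' @param bins output of [bin_speed_curvature()].
#' @return one-row data frame with `frac_roaming`, `frac_dwelling`,
#'   `speed_roaming`, `speed_dwelling`, `n_bins`.
#' @export
foraging_summary <- function(labels, bins) {
  stopifnot(length(labels) == nrow(bins), nrow(bins) >= 1)
  roam <- labels == "roaming"
  data.frame(frac_roaming = mean(roam), frac_dwelling = mean(!roam),
             speed_roaming = if (any(roam)) mean(bins$speed[roam]) else NA_real_,
             speed_dwelling = if (any(!roam)) mean(bins$speed[!roam]) else NA_real_,
             n_bins = nrow(bins))
}

#' Per-animal local-search summary (off food)
#'
#' Fraction of time spent in each behavioral state (pause, run, turn,
#' pirouette; fractions sum to 1) plus the mean speed over the whole track,
#' pause samples included.
#'
#' @param ann a `behavior_annotation` from [segment_trajectory()].
#' @param traj the corresponding [trajectory()] with speed populated.
#' @return one-row data frame with `frac_run`, `frac_pause`, `frac_turn`,
#'   `frac_pirouette`, `mean_speed`, `n_samples`.
#' @export
local_search_summary <- function(ann, traj) {
  stopifnot(length(ann$state) == length(traj$t))
  n <- length(ann$state)
  data.frame(frac_run = sum(ann$state == "run") / n,
             frac_pause = sum(ann$state == "pause") / n,
             frac_turn = sum(ann$state == "turn") / n,
             frac_pirouette = sum(ann$state == "pirouette") / n,
             mean_speed = mean(traj$speed),
             n_samples = n)
}
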