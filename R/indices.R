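#' Select tracks for index analysis
#'
#' Clips each trajectory to the analysis window and keeps tracks whose
#' in-window presence is at least `min_active_s`, which prevents several
#' short tracks of one animal from entering the analysis. When several
#' surviving tracks share a `worm_id` (possible for simulated ground truth),
#' only the longest is kept.
#'
#' @param trajs list of [trajectory()] objects, time-aligned to release at
#'   t = 0.
#' @param w an [analysis_window()].
#' @return list of clipped trajectories (possibly empty, with a warning).
#' @export
select_analysis_tracks <- function(trajs, w = analysis_window()) {
  clipped <- list()
  for (tr in trajs) {
    ct <- clip_trajectory(tr, w$t_start, w$t_end)
    if (is.null(ct) || length(ct$t) < 2) next
    if (ct$t[length(ct$t)] - ct$t[1] >= w$min_active_s)
      clipped <- c(clipped, list(ct))
  }
  if (length(clipped) > 1) {
    ids <- vapply(clipped, `[[`, "", "worm_id")
    keep <- rep(TRUE, length(clipped))
    for (id in unique(ids[duplicated(ids)])) {
      ix <- which(ids == id)
      spans <- vapply(clipped[ix], function(x) diff(range(x$t)), numeric(1))
      keep[ix[-which.max(spans)]] <- FALSE
    }
    clipped <- clipped[keep]
  }
  if (!length(clipped)) warning("no tracks survive the analysis window")
  clipped
}

#' Chemotactic index of one trajectory
#'
#' Ratio of the mean signed velocity along the gradient direction to the mean
#' crawling speed, `<v_g>/<s>`; +1 means straight up-gradient, -1 straight
#' down. The per-sample signed velocity mirrors the speed convention (step
#' differences with the first sample duplicated), so `|index| <= 1` holds
#' pointwise.
#'
#' @param traj a [trajectory()] with speed populated, clipped to the window.
#' @param g a [gradient_spec()].
#' @return scalar in `[-1, 1]`, or `NA` (zero mean speed) with a `"reason"`
#'   attribute.
#' @export
chemotactic_index <- function(traj, g) {
  stopifnot(!is.null(traj$speed))
  s_ax <- axis_coord(g, traj$xy)
  vg_step <- diff(s_ax) / diff(traj$t)
  vg <- c(vg_step[1], vg_step)
  ms <- mean(traj$speed)
  if (ms == 0)
    return(structure(NA_real_, reason = "zero mean speed"))
  mean(vg) / ms
}

#' Biased-random-walk index from a behavior annotation
#'
#' Fractional difference of the mean run duration up- versus down-gradient,
#' `(<len run_up> - <len run_down>) / (<len run_up> + <len run_down>)`.
#' Runs are clipped to the window bounds and contribute their in-window
#' duration; ties (zero net axis displacement) count for neither direction.
#' A direction with no runs contributes mean 0, so a one-sided animal scores
#' +/-1; with no (non-tie) runs at all the index is undefined.
#'
#' @param ann a `behavior_annotation` from [segment_trajectory()].
#' @param w optional [analysis_window()]; `NULL` uses the whole annotation.
#' @return scalar in `[-1, 1]`, or `NA` with a `"reason"` attribute.
#' @export
brw_index <- function(ann, w = NULL) {
  runs <- ann$runs
  if (!is.null(w)) {
    runs <- runs[runs$end_s >= w$t_start & runs$start_s <= w$t_end, , drop = FALSE]
    if (nrow(runs)) {
      runs$start_s <- pmax(runs$start_s, w$t_start)
      runs$end_s <- pmin(runs$end_s, w$t_end)
    }
  }
  runs <- runs[runs$direction %in% c("up", "down"), , drop = FALSE]
  if (nrow(runs) == 0)
    return(structure(NA_real_, reason = "no directed runs in window"))
  dur <- runs$end_s - runs$start_s
  mu_up <- if (any(runs$direction == "up")) mean(dur[runs$direction == "up"]) else 0
  mu_dn <- if (any(runs$direction == "down")) mean(dur[runs$direction == "down"]) else 0
  if (mu_up + mu_dn == 0)
    return(structure(NA_real_, reason = "zero run durations"))
  (mu_up - mu_dn) / (mu_up + mu_dn)
}

#' Klinotaxis index from a behavior annotation
#'
#' Fractional difference in the probability that the run following a
#' reorientation event (turn or pirouette) initiates up- versus down-gradient,
#' `(N_up - N_down)/(N_up + N_down)`. Only runs starting immediately after a
#' reorientation qualify; a run is classified by the sign of its net axis
#' displacement over its first `klino_stretch_s` seconds and is discarded if
#' another behavior starts within that stretch.
#'
#' @param ann a `behavior_annotation` from [segment_trajectory()].
#' @param sp a [segmentation_params()] (supplies `klino_stretch_s`).
#' @param w optional [analysis_window()] restricting the reorientation events
#'   scored (by their end time).
#' @return scalar in `[-1, 1]`, or `NA` with a `"reason"` attribute.
#' @export
klinotaxis_index <- function(ann, sp = ann$params_used, w = NULL) {
  runs <- ann$runs
  reo <- ann$reorientations
  if (!is.null(w))
    reo <- reo[reo$end_s >= w$t_start & reo$end_s <= w$t_end, , drop = FALSE]
  if (nrow(reo) == 0 || nrow(runs) == 0)
    return(structure(NA_real_, reason = "no qualifying post-reorientation runs"))
  n_up <- 0L; n_dn <- 0L
  for (r in seq_len(nrow(reo))) {
    nxt <- which(runs$start_idx == reo$end_idx[r] + 1L)
    if (length(nxt) != 1) next
    run <- runs[nxt, ]
    if (run$end_s - run$start_s < sp$klino_stretch_s) next
    t_stop <- run$start_s + sp$klino_stretch_s
    in_stretch <- which(ann$t >= run$start_s & ann$t <= t_stop)
    net <- ann$axis_coord[in_stretch[length(in_stretch)]] -
      ann$axis_coord[in_stretch[1]]
    if (net > 0) n_up <- n_up + 1L else if (net < 0) n_dn <- n_dn + 1L
  }
  if (n_up + n_dn == 0)
    return(structure(NA_real_, reason = "no qualifying post-reorientation runs"))
  (n_up - n_dn) / (n_up + n_dn)
}

#' Per-animal navigation indices over an analysis window
#'
#' Runs [select_analysis_tracks()], [segment_trajectory()] and the three
#' index computations over a set of trajectories and collects per-animal
#' results.
#'
#' @param trajs list of [trajectory()] objects with speed populated.
#' @param g a [gradient_spec()].
#' @param w an [analysis_window()].
#' @param sp a [segmentation_params()].
#' @return data frame with one row per surviving track: `worm_id`,
#'   `chemotactic`, `brw`, `klinotaxis`, `mean_pos_mm` (mean axis coordinate
#'   relative to the release point), and run/reorientation counts.
#' @export
navigation_indices <- function(trajs, g = gradient_spec(),
                               w = analysis_window(),
                               sp = segmentation_params()) {
  kept <- select_analysis_tracks(trajs, w)
  rows <- lapply(kept, function(tr) {
    ann <- segment_trajectory(tr, sp, g)
    runs <- ann$runs[ann$runs$direction %in% c("up", "down"), , drop = FALSE]
    reo_dirs <- integer(0)
    data.frame(worm_id = tr$worm_id,
               chemotactic = as.numeric(chemotactic_index(tr, g)),
               brw = as.numeric(brw_index(ann)),
               klinotaxis = as.numeric(klinotaxis_index(ann, sp)),
               mean_pos_mm = mean(axis_coord(g, tr$xy)) - g$release_mm,
               n_runs_up = sum(runs$direction == "up"),
               n_runs_down = sum(runs$direction == "down"),
               n_reorient = nrow(ann$reorientations))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(worm_id = character(), chemotactic = numeric(),
                      brw = numeric(), klinotaxis = numeric(),
                      mean_pos_mm = numeric(), n_runs_up = integer(),
                      n_runs_down = integer(), n_reorient = integer())
  out
}

#' Population mean position on the gradient through time
#'
#' At each grid time, the mean over active tracks of the axis coordinate
#' relative to the release point, with the S.E.M. over tracks (undefined for
#' fewer than two tracks).
#'
#' @param trajs list of [trajectory()] objects.
#' @param g a [gradient_spec()].
#' @param grid numeric vector of times (s); defaults to the union grid.
#' @return data frame with `t`, `mean_pos_mm`, `sem_mm`, `n`.
#' @export
mean_position_trace <- function(trajs, g = gradient_spec(), grid = NULL) {
  if (is.null(grid))
    grid <- sort(unique(unlist(lapply(trajs, `[[`, "t"))))
  pos <- lapply(trajs, function(tr) {
    m <- match(round(grid, 6), round(tr$t, 6))
    s <- rep(NA_real_, length(grid))
    ok <- !is.na(m)
    s[ok] <- axis_coord(g, tr$xy[m[ok], , drop = FALSE]) - g$release_mm
    s
  })
  mat <- do.call(cbind, pos)
  n <- rowSums(!is.na(mat))
  mu <- ifelse(n > 0, rowMeans(mat, na.rm = TRUE), NA_real_)
  sem <- vapply(seq_along(grid), function(i) {
    v <- mat[i, !is.na(mat[i, ])]
    if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1))
  data.frame(t = grid, mean_pos_mm = mu, sem_mm = sem, n = n)
}

#' Quadrant-assay chemotaxis index
#'
#' `(n_A - n_C)/(n_A + n_C)` where `n_A` counts animals in the NaCl quadrants
#' and `n_C` in the control quadrants.
#'
#' @param n_A,n_C non-negative integer counts.
#' @return scalar in `[-1, 1]`, or `NA` if both counts are zero.
#' @export
quadrant_index <- function(n_A, n_C) {
  stopifnot(n_A >= 0, n_C >= 0)
  if (n_A + n_C == 0)
    return(structure(NA_real_, reason = "no animals counted"))
  (n_A - n_C) / (n_A + n_C)
}
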