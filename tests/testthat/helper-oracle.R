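# Independent brute-force re-evaluation of the behavioral segmentation
# rules: every window, arc walk and angle is recomputed per sample with
# naive loops and its own distance accumulation -- no cumulative sums, no
# pointers -- so it shares no code path with the package implementation.

oracle_pause <- function(traj, sp) {
  n <- length(traj$t)
  out <- logical(n)
  for (i in seq_len(n)) {
    win <- which(traj$t >= traj$t[i] - sp$pause_window_s / 2 - 1e-9 &
                 traj$t <= traj$t[i] + sp$pause_window_s / 2 + 1e-9)
    out[i] <- sum(traj$speed[win] < sp$pause_speed) > length(win) / 2
  }
  out
}

oracle_turn_core <- function(traj, sp) {
  n <- length(traj$t)
  xy <- traj$xy
  out <- logical(n)
  for (i in seq_len(n)) {
    d <- 0; j <- i; bi <- NA_integer_
    while (j > 1) {
      d <- d + sqrt(sum((xy[j, ] - xy[j - 1, ])^2))
      j <- j - 1
      if (d >= sp$turn_arc_mm) { bi <- j; break }
    }
    d <- 0; k <- i; fi <- NA_integer_
    while (k < n) {
      d <- d + sqrt(sum((xy[k + 1, ] - xy[k, ])^2))
      k <- k + 1
      if (d >= sp$turn_arc_mm) { fi <- k; break }
    }
    if (is.na(bi) || is.na(fi)) next
    vb <- xy[bi, ] - xy[i, ]
    vf <- xy[fi, ] - xy[i, ]
    nb <- sqrt(sum(vb^2)); nf <- sqrt(sum(vf^2))
    if (nb == 0 || nf == 0) next
    ang <- acos(min(max(sum(vb * vf) / (nb * nf), -1), 1)) * 180 / pi
    out[i] <- ang < sp$turn_angle_deg
  }
  out
}

oracle_states <- function(traj, sp) {
  n <- length(traj$t)
  turn <- oracle_turn_core(traj, sp)
  # forward-only extension of each turn block while speed < postturn_speed
  i <- 1
  while (i <= n) {
    if (turn[i]) {
      while (i < n && turn[i + 1]) i <- i + 1
      j <- i + 1
      while (j <= n && !turn[j] && traj$speed[j] < sp$postturn_speed) {
        turn[j] <- TRUE
        j <- j + 1
      }
      i <- j
    } else i <- i + 1
  }
  # turn intervals
  iv <- NULL
  i <- 1
  while (i <= n) {
    if (turn[i]) {
      j <- i
      while (j < n && turn[j + 1]) j <- j + 1
      iv <- rbind(iv, c(i, j))
      i <- j + 1
    } else i <- i + 1
  }
  state <- rep("run", n)
  state[oracle_pause(traj, sp)] <- "pause"
  if (!is.null(iv)) {
    # bundle chains with gaps < pirouette_gap_s
    grp <- 1
    groups <- numeric(nrow(iv))
    groups[1] <- 1
    if (nrow(iv) > 1)
      for (r in 2:nrow(iv)) {
        if (traj$t[iv[r, 1]] - traj$t[iv[r - 1, 2]] >= sp$pirouette_gap_s)
          grp <- grp + 1
        groups[r] <- grp
      }
    for (gi in unique(groups)) {
      rows <- which(groups == gi)
      a <- iv[rows[1], 1]; b <- iv[rows[length(rows)], 2]
      state[a:b] <- if (length(rows) > 1) "pirouette" else "turn"
    }
  }
  state
}
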