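#' Tracking parameters
#'
#' Controls the video-to-trajectory conversion: average-background
#' subtraction, Gaussian smoothing of the foreground, intensity thresholding,
#' size-gated blob extraction, frame-to-frame nearest-neighbor linking,
#' rejection of short tracks, coordinate smoothing and speed computation.
#'
#' @param gaussian_sigma_px smoothing sigma applied to the foreground image.
#' @param threshold intensity cut on the smoothed background-subtracted image.
#' @param area_min_px,area_max_px single-animal blob size gate (px).
#' @param link_max_px maximum centroid displacement between adjacent frames.
#' @param min_track_s minimum track duration retained (default 300 s = 5 min).
#' @param smooth_window_s centered moving-average window applied to
#'   coordinates before speed computation (default 1.5 s).
#' @param px_per_mm pixel scale.
#' @param fps frame rate (frames/s).
#' @param border_margin_px tracks whose centroid comes within this margin of
#'   the frame edge are terminated (roughly two blob radii).
#' @param polarity `"dark"` for dark worms on a bright arena (foreground =
#'   background - frame), `"bright"` for the opposite.
#' @return an object of class `tracking_params`.
#' @export
tracking_params <- function(gaussian_sigma_px = 1, threshold = 0.1,
                            area_min_px = 3, area_max_px = 80,
                            link_max_px = 5, min_track_s = 300,
                            smooth_window_s = 1.5, px_per_mm = 2, fps = 2,
                            border_margin_px = 4,
                            polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  stopifnot(gaussian_sigma_px >= 0, threshold > 0,
            area_min_px < area_max_px, link_max_px > 0,
            min_track_s >= 0, smooth_window_s >= 0, px_per_mm > 0, fps > 0,
            border_margin_px >= 0)
  structure(list(gaussian_sigma_px = gaussian_sigma_px, threshold = threshold,
                 area_min_px = area_min_px, area_max_px = area_max_px,
                 link_max_px = link_max_px, min_track_s = min_track_s,
                 smooth_window_s = smooth_window_s, px_per_mm = px_per_mm,
                 fps = fps, border_margin_px = border_margin_px,
                 polarity = polarity),
            class = "tracking_params")
}

#' Detect worm blobs in a frame stack
#'
#' Foreground = per-pixel average background minus frame (for dark worms),
#' clipped at zero, Gaussian-smoothed and thresholded. Connected components
#' within the single-animal size gate are kept; the centroid is the
#' intensity-weighted center of mass of the smoothed foreground component,
#' in continuous pixel coordinates (pixel `(i, j)` center at
#' `(i - 0.5, j - 0.5)`).
#'
#' @param frames list of numeric matrices (one per frame, common size), or
#'   a path readable by [read_frames()].
#' @param tp a [tracking_params()].
#' @param background optional explicit background image; by default the
#'   per-pixel mean over the whole stack is used.
#' @return list (one element per frame) of data frames with `x_px`, `y_px`,
#'   `area_px`.
#' @export
detect_blobs <- function(frames, tp, background = NULL) {
  if (is.character(frames)) frames <- read_frames(frames)
  stopifnot(length(frames) >= 2 || !is.null(background))
  nx <- nrow(frames[[1]]); ny <- ncol(frames[[1]])
  if (is.null(background)) {
    background <- Reduce(`+`, frames) / length(frames)
  }
  if (max(vapply(frames, function(f) max(abs(f - background)), numeric(1))) < 1e-12)
    warning("constant frame stack: no foreground, empty detections")
  ci <- seq_len(nx) - 0.5
  cj <- seq_len(ny) - 0.5
  lapply(frames, function(fr) {
    fg <- if (tp$polarity == "dark") background - fr else fr - background
    fg[fg < 0] <- 0
    if (tp$gaussian_sigma_px > 0)
      fg <- EBImage::gblur(fg, sigma = tp$gaussian_sigma_px)
    mask <- fg > tp$threshold
    if (!any(mask))
      return(data.frame(x_px = numeric(0), y_px = numeric(0),
                        area_px = numeric(0)))
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    lab <- EBImage::imageData(lab)
    ids <- seq_len(max(lab))
    out <- lapply(ids, function(id) {
      sel <- lab == id
      area <- sum(sel)
      if (area < tp$area_min_px || area > tp$area_max_px) return(NULL)
      w <- fg * sel
      tot <- sum(w)
      data.frame(x_px = sum(w * matrix(ci, nx, ny)) / tot,
                 y_px = sum(w * matrix(cj, nx, ny, byrow = TRUE)) / tot,
                 area_px = area)
    })
    out <- do.call(rbind, out)
    if (is.null(out)) out <- data.frame(x_px = numeric(0), y_px = numeric(0),
                                        area_px = numeric(0))
    out
  })
}

#' Link per-frame detections into raw tracks
#'
#' Greedy nearest-neighbor assignment between adjacent frames under
#' `link_max_px`. A track terminates when its detection disappears, when two
#' tracks claim the same detection (a collision), when two candidate
#' detections are equidistant (ambiguity terminates rather than guesses), or
#' when the centroid enters the border margin of the frame. Unmatched
#' detections start new tracks; there is no gap bridging.
#'
#' @param detections output of [detect_blobs()].
#' @param tp a [tracking_params()].
#' @param frame_size_px `c(nx, ny)`; if `NULL` the border rule is skipped.
#' @return list of raw tracks: data frames with `frame`, `x_px`, `y_px`,
#'   `area_px`.
#' @export
link_tracks <- function(detections, tp, frame_size_px = NULL) {
  finished <- list()
  active <- list() # each: data.frame(frame, x_px, y_px, area_px)
  near_border <- function(d) {
    if (is.null(frame_size_px)) return(rep(FALSE, nrow(d)))
    m <- tp$border_margin_px
    d$x_px < m | d$x_px > frame_size_px[1] - m |
      d$y_px < m | d$y_px > frame_size_px[2] - m
  }
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    n_act <- length(active)
    n_det <- nrow(det)
    linked_det <- rep(FALSE, n_det)
    keep <- logical(n_act)
    claim <- rep(NA_integer_, n_act)
    if (n_act > 0 && n_det > 0) {
      for (a in seq_len(n_act)) {
        hd <- active[[a]][nrow(active[[a]]), ]
        dd <- sqrt((det$x_px - hd$x_px)^2 + (det$y_px - hd$y_px)^2)
        ok <- which(dd <= tp$link_max_px)
        if (length(ok) == 0) next
        best <- ok[which.min(dd[ok])]
        # ambiguity: two detections exactly equidistant -> terminate
        if (sum(abs(dd[ok] - dd[best]) < 1e-9) > 1) next
        claim[a] <- best
      }
      tab <- table(claim[!is.na(claim)])
      contested <- as.integer(names(tab)[tab > 1])
      for (a in seq_len(n_act)) {
        if (!is.na(claim[a]) && !(claim[a] %in% contested)) {
          active[[a]] <- rbind(active[[a]],
                               data.frame(frame = f, x_px = det$x_px[claim[a]],
                                          y_px = det$y_px[claim[a]],
                                          area_px = det$area_px[claim[a]]))
          linked_det[claim[a]] <- TRUE
          keep[a] <- TRUE
        }
      }
    }
    finished <- c(finished, active[!keep])
    active <- active[keep]
    # border termination after linking
    if (length(active)) {
      heads <- do.call(rbind, lapply(active, function(a) a[nrow(a), ]))
      on_border <- near_border(heads)
      finished <- c(finished, active[on_border])
      active <- active[!on_border]
    }
    # unmatched detections start new tracks (unless already on the border)
    if (n_det > 0) {
      for (d in which(!linked_det)) {
        row <- data.frame(frame = f, x_px = det$x_px[d], y_px = det$y_px[d],
                          area_px = det$area_px[d])
        if (!near_border(row)) active <- c(active, list(row))
      }
    }
  }
  c(finished, active)
}

#' Convert a raw pixel track to a preprocessed trajectory
#'
#' Pixel coordinates are converted to mm and frame indices to seconds; tracks
#' shorter than `min_track_s` are rejected (returns `NULL`). Coordinates are
#' smoothed with a centered moving average over `smooth_window_s` (3 samples
#' at 2 Hz); the `(window - 1)/2` edge samples on each side are trimmed so
#' the smoothing is exact on affine paths, then instantaneous speed is
#' computed on the smoothed path.
#'
#' @param track raw track from [link_tracks()].
#' @param tp a [tracking_params()].
#' @param worm_id identifier for the trajectory.
#' @return a [trajectory()] with speed populated, or `NULL` if rejected.
#' @export
preprocess_track <- function(track, tp, worm_id = "track") {
  n <- nrow(track)
  dt <- 1 / tp$fps
  duration <- (n - 1) * dt
  if (duration < tp$min_track_s) return(NULL)
  w <- max(1L, as.integer(round(tp$smooth_window_s / dt)))
  if (w %% 2 == 0) w <- w + 1L
  if (n < w + 1) return(NULL)
  x <- track$x_px / tp$px_per_mm
  y <- track$y_px / tp$px_per_mm
  if (w > 1) {
    kern <- rep(1 / w, w)
    xs <- stats::filter(x, kern, sides = 2)
    ys <- stats::filter(y, kern, sides = 2)
    half <- (w - 1L) / 2L
    idx <- (half + 1L):(n - half)
    x <- as.numeric(xs[idx]); y <- as.numeric(ys[idx])
    frames <- track$frame[idx]
  } else frames <- track$frame
  tr <- trajectory(worm_id, (frames - 1) * dt, cbind(x, y), source = "tracked")
  compute_speed(tr)
}

#' Track a frame stack end to end
#'
#' Convenience wrapper: [detect_blobs()], [link_tracks()] and
#' [preprocess_track()] applied in sequence.
#'
#' @inheritParams detect_blobs
#' @return list of [trajectory()] objects (short tracks dropped).
#' @export
track_frames <- function(frames, tp, background = NULL) {
  if (is.character(frames)) frames <- read_frames(frames)
  det <- detect_blobs(frames, tp, background = background)
  raw <- link_tracks(det, tp, frame_size_px = dim(frames[[1]]))
  out <- list()
  for (i in seq_along(raw)) {
    tr <- preprocess_track(raw[[i]], tp, worm_id = sprintf("track%03d", i))
    if (!is.null(tr)) out <- c(out, list(tr))
  }
  out
}
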