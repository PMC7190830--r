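#' Rendering parameters for synthetic worm video
#'
#' Dark Gaussian blobs on a bright background, emulating worms illuminated in
#' trans on an assay plate.
#'
#' @param px_per_mm pixel scale.
#' @param worm_blob_sigma_px Gaussian blob sigma (px).
#' @param worm_intensity peak intensity removed from the background by one
#'   worm (image scale `[0, 1]`).
#' @param background_level background intensity in `[0, 1]`.
#' @param noise_sd additive Gaussian noise sd.
#' @param frame_size_px `c(nx, ny)` frame size in pixels.
#' @return an object of class `render_params`.
#' @export
render_params <- function(px_per_mm = 2, worm_blob_sigma_px = 1.2,
                          worm_intensity = 0.5, background_level = 0.9,
                          noise_sd = 0, frame_size_px = c(240, 240)) {
  stopifnot(px_per_mm > 0, worm_blob_sigma_px > 0,
            worm_intensity > 0, worm_intensity <= 1,
            background_level >= 0, background_level <= 1,
            noise_sd >= 0, length(frame_size_px) == 2, frame_size_px >= 1)
  structure(list(px_per_mm = px_per_mm,
                 worm_blob_sigma_px = worm_blob_sigma_px,
                 worm_intensity = worm_intensity,
                 background_level = background_level,
                 noise_sd = noise_sd,
                 frame_size_px = as.integer(frame_size_px)),
            class = "render_params")
}

## additive Gaussian blob stamped on a local patch (4 sigma radius)
stamp_blob <- function(frame, cx, cy, sigma, amplitude) {
  nx <- nrow(frame); ny <- ncol(frame)
  r <- ceiling(4 * sigma)
  i0 <- max(1L, floor(cx - r)); i1 <- min(nx, ceiling(cx + r))
  j0 <- max(1L, floor(cy - r)); j1 <- min(ny, ceiling(cy + r))
  if (i0 > i1 || j0 > j1) return(frame)
  ii <- i0:i1; jj <- j0:j1
  gx <- exp(-((ii - 0.5) - cx)^2 / (2 * sigma^2))
  gy <- exp(-((jj - 0.5) - cy)^2 / (2 * sigma^2))
  frame[ii, jj] <- frame[ii, jj] - amplitude * outer(gx, gy)
  frame
}

#' Render trajectories into a synthetic frame stack
#'
#' Converts worm positions (mm) into pixel coordinates (`px = mm * px_per_mm`;
#' pixel `(i, j)` has its center at `(i - 0.5, j - 0.5)` px) and renders each
#' worm as a dark Gaussian blob on a bright background with optional additive
#' Gaussian noise. Overlapping worms merge additively, which is a tracker
#' test case rather than an error. All trajectories must share one time grid.
#'
#' @param trajs list of [trajectory()] objects (positions in mm).
#' @param rp a [render_params()].
#' @param seed RNG seed for the noise.
#' @param path optional file path; if given, the stack is written as a
#'   multi-page TIFF.
#' @return list with `frames` (list of nx x ny matrices in `[0, 1]`),
#'   `truth` (data frame `frame`, `worm_id`, `x_px`, `y_px`) and `path`.
#' @export
render_frames <- function(trajs, rp, seed = 1, path = NULL) {
  stopifnot(length(trajs) >= 0)
  if (length(trajs)) {
    n_t <- length(trajs[[1]]$t)
    for (tr in trajs)
      if (length(tr$t) != n_t || max(abs(tr$t - trajs[[1]]$t)) > 1e-9)
        stop("all trajectories must share one time grid for rendering")
  } else n_t <- 1L
  nx <- rp$frame_size_px[1]; ny <- rp$frame_size_px[2]
  set.seed(as.integer(seed))
  frames <- vector("list", n_t)
  truth <- vector("list", n_t)
  for (f in seq_len(n_t)) {
    fr <- matrix(rp$background_level, nx, ny)
    rows <- NULL
    if (length(trajs)) {
      px <- vapply(trajs, function(tr) tr$xy[f, 1] * rp$px_per_mm, numeric(1))
      py <- vapply(trajs, function(tr) tr$xy[f, 2] * rp$px_per_mm, numeric(1))
      if (any(px < 0 | px > nx | py < 0 | py > ny))
        stop("trajectory positions fall outside the rendered frame")
      for (w in seq_along(trajs))
        fr <- stamp_blob(fr, px[w], py[w], rp$worm_blob_sigma_px,
                         rp$worm_intensity)
      rows <- data.frame(frame = f,
                         worm_id = vapply(trajs, `[[`, "", "worm_id"),
                         x_px = px, y_px = py)
    }
    if (rp$noise_sd > 0)
      fr <- fr + matrix(stats::rnorm(nx * ny, 0, rp$noise_sd), nx, ny)
    frames[[f]] <- pmin(pmax(fr, 0), 1)
    truth[[f]] <- rows
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth))
    truth <- data.frame(frame = integer(), worm_id = character(),
                        x_px = numeric(), y_px = numeric())
  if (!is.null(path)) tiff::writeTIFF(frames, path)
  list(frames = frames, truth = truth, path = path)
}

#' Read a frame stack from a multi-page TIFF
#'
#' @param path TIFF file.
#' @return list of numeric matrices in `[0, 1]`.
#' @export
read_frames <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  lapply(frames, function(f) {
    if (length(dim(f)) == 3) f <- f[, , 1]
    f
  })
}
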