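clean_bg <- function(rp) matrix(rp$background_level, rp$frame_size_px[1],
                                rp$frame_size_px[2])

test_that("a rendered static worm is detected at its ground-truth centroid", {
  rp <- render_params(px_per_mm = 2, frame_size_px = c(24, 24), noise_sd = 0)
  tr <- make_traj(matrix(rep(c(5.3, 6.1), 10), ncol = 2, byrow = TRUE))
  rf <- render_frames(list(tr), rp, seed = 1)
  tp <- tracking_params()
  det <- detect_blobs(rf$frames, tp, background = clean_bg(rp))
  expect_true(all(vapply(det, nrow, integer(1)) == 1))
  err <- vapply(seq_along(det), function(f)
    sqrt((det[[f]]$x_px - rf$truth$x_px[f])^2 +
         (det[[f]]$y_px - rf$truth$y_px[f])^2), numeric(1))
  expect_lt(max(err), 0.5)
})

test_that("a moving worm is detected against the average background", {
  g <- gradient_spec(length_mm = 10)
  set.seed(3)
  tr <- simulate_worm(locomotion_params(), g, 120, c(7, 7),
                      arena = c(2, 12, 2, 12))
  rp <- render_params(px_per_mm = 2, frame_size_px = c(28, 28), noise_sd = 0)
  rf <- render_frames(list(tr), rp, seed = 1)
  tp <- tracking_params()
  det <- detect_blobs(rf$frames, tp) # default mean-over-stack background
  expect_true(all(vapply(det, nrow, integer(1)) == 1))
  err <- vapply(seq_along(det), function(f)
    sqrt((det[[f]]$x_px - rf$truth$x_px[f])^2 +
         (det[[f]]$y_px - rf$truth$y_px[f])^2), numeric(1))
  expect_lt(sqrt(mean(err^2)), 0.5)
})

test_that("an empty arena yields no detections and a constant-stack warning", {
  rp <- render_params(frame_size_px = c(16, 16), noise_sd = 0)
  rf <- render_frames(list(), rp, seed = 1)
  frames <- rf$frames[rep(1, 5)]
  tp <- tracking_params()
  expect_warning(det <- detect_blobs(frames, tp), "constant")
  expect_true(all(vapply(det, nrow, integer(1)) == 0))
})

test_that("merged (overlapping) worms exceed the size gate and are dropped", {
  rp <- render_params(px_per_mm = 2, frame_size_px = c(24, 24), noise_sd = 0)
  # two worms closer than a blob diameter -> one big component
  a <- make_traj(matrix(rep(c(5, 6), 4), ncol = 2, byrow = TRUE), worm_id = "a")
  b <- make_traj(matrix(rep(c(5.8, 6), 4), ncol = 2, byrow = TRUE), worm_id = "b")
  rf <- render_frames(list(a, b), rp, seed = 1)
  tp_wide <- tracking_params(area_max_px = 500)
  det_wide <- detect_blobs(rf$frames, tp_wide, background = clean_bg(rp))
  expect_equal(nrow(det_wide[[1]]), 1) # merged into one component
  area_merged <- det_wide[[1]]$area_px[1]
  tp <- tracking_params(area_max_px = area_merged - 1)
  det <- detect_blobs(rf$frames, tp, background = clean_bg(rp))
  expect_equal(nrow(det[[1]]), 0) # gated out
})

test_that("continuous detections link into one full-length track", {
  det <- lapply(1:20, function(f)
    data.frame(x_px = 5 + 0.5 * f, y_px = 10, area_px = 10))
  tp <- tracking_params()
  tracks <- link_tracks(det, tp)
  expect_length(tracks, 1)
  expect_equal(nrow(tracks[[1]]), 20)
  expect_equal(tracks[[1]]$frame, 1:20)
})

test_that("a single dropped frame splits the track (no gap bridging)", {
  det <- lapply(1:20, function(f) {
    if (f == 10) return(data.frame(x_px = numeric(0), y_px = numeric(0),
                                   area_px = numeric(0)))
    data.frame(x_px = 5 + 0.5 * f, y_px = 10, area_px = 10)
  })
  tracks <- link_tracks(det, tracking_params())
  expect_length(tracks, 2)
  expect_setequal(vapply(tracks, nrow, integer(1)), c(9, 10))
})

test_that("two tracks claiming one detection both terminate (collision)", {
  # two detections converge to a single point at frame 6
  det <- lapply(1:10, function(f) {
    if (f < 6)
      data.frame(x_px = c(4 + f, 16 - f), y_px = c(10, 10), area_px = c(10, 10))
    else if (f == 6)
      data.frame(x_px = 10, y_px = 10, area_px = 10)
    else
      data.frame(x_px = c(9, 11), y_px = c(10, 10), area_px = c(10, 10))
  })
  tracks <- link_tracks(det, tracking_params(link_max_px = 3))
  # the two pre-collision tracks end at frame 5
  pre <- Filter(function(tr) tr$frame[1] == 1, tracks)
  expect_length(pre, 2)
  expect_true(all(vapply(pre, function(tr) max(tr$frame), numeric(1)) == 5))
})

test_that("no track contains two detections from one frame", {
  set.seed(8)
  det <- lapply(1:40, function(f)
    data.frame(x_px = runif(3, 5, 25), y_px = runif(3, 5, 25),
               area_px = rep(10, 3)))
  tracks <- link_tracks(det, tracking_params(link_max_px = 6))
  for (tr in tracks) expect_false(anyDuplicated(tr$frame) > 0)
})

test_that("short tracks are rejected and affine paths keep exact speed", {
  tp <- tracking_params(px_per_mm = 2, min_track_s = 300)
  # 4-minute track -> rejected
  short <- data.frame(frame = 1:480, x_px = 1:480 * 0.1, y_px = 0,
                      area_px = 10)
  expect_null(preprocess_track(short, tp))
  # 6-minute constant-velocity track -> constant speed, exact
  n <- 721
  raw <- data.frame(frame = 1:n, x_px = (1:n) * 0.12, y_px = (1:n) * 0.05,
                    area_px = 10)
  tr <- preprocess_track(raw, tp)
  true_speed <- sqrt(0.12^2 + 0.05^2) / 2 / 0.5 # px/frame -> mm/s
  expect_lt(max(abs(tr$speed - true_speed)), 1e-9)
  expect_equal(length(tr$t), n - 2) # one trimmed sample per end
})

test_that("coordinate smoothing damps jitter on a noisy static track", {
  set.seed(4)
  n <- 801
  raw <- data.frame(frame = 1:n, x_px = 20 + rnorm(n, 0, 0.3),
                    y_px = 20 + rnorm(n, 0, 0.3), area_px = 10)
  tp <- tracking_params(px_per_mm = 2, min_track_s = 300)
  tr <- preprocess_track(raw, tp)
  unsmoothed <- compute_speed(trajectory("u", (raw$frame - 1) * 0.5,
                                         cbind(raw$x_px, raw$y_px) / 2))
  expect_lt(mean(tr$speed), mean(unsmoothed$speed))
})

test_that("clean video of simulated worms is recovered with sub-pixel error", {
  # non-colliding by construction: each worm in its own spatial cell
  g <- gradient_spec(length_mm = 10)
  p <- locomotion_params()
  cells <- cbind(c(0, 14, 28), c(0, 0, 0))
  trajs <- lapply(1:3, function(i) {
    set.seed(30 + i)
    tr <- simulate_worm(p, g, 180, c(7, 7), arena = c(2.5, 11.5, 2.5, 11.5),
                        worm_id = sprintf("gt%d", i))
    tr$xy[, 1] <- tr$xy[, 1] + cells[i, 1]
    tr
  })
  rp <- render_params(px_per_mm = 2, frame_size_px = c(84, 28), noise_sd = 0)
  rf <- render_frames(trajs, rp, seed = 1)
  tp <- tracking_params(min_track_s = 150)
  tracks <- track_frames(rf$frames, tp)
  expect_length(tracks, 3)
  # match each track to a ground-truth worm and check error in px
  for (tr in tracks) {
    mid <- tr$xy[round(length(tr$t) / 2), ]
    i <- which.min(vapply(trajs, function(gt)
      min((gt$xy[, 1] - mid[1])^2 + (gt$xy[, 2] - mid[2])^2), numeric(1)))
    gt <- trajs[[i]]
    m <- match(round(tr$t, 6), round(gt$t, 6))
    err_px <- sqrt((tr$xy[, 1] - gt$xy[m, 1])^2 +
                   (tr$xy[, 2] - gt$xy[m, 2])^2) * tp$px_per_mm
    expect_lt(sqrt(mean(err_px^2)), 0.5)
  }
})
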