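test_that("chemotactic index matches its defining ratio", {
  g <- default_gradient()
  # straight up-gradient at constant speed -> +1 exactly
  up <- straight_traj(100, heading = pi / 2, speed = 0.1)
  expect_equal(chemotactic_index(up, g), 1)
  # straight down -> -1
  dn <- straight_traj(100, heading = -pi / 2, speed = 0.1)
  expect_equal(chemotactic_index(dn, g), -1)
  # perpendicular motion -> 0
  perp <- straight_traj(100, heading = 0, speed = 0.1)
  expect_equal(chemotactic_index(perp, g), 0)
  # 6 min up then 4 min down at 0.1 mm/s -> 0.02 / 0.1 = +0.2, up to the
  # one-sample edge effect of the duplicated first step (order 1/n)
  updown <- legs_traj(rbind(c(pi / 2, 720), c(-pi / 2, 480)), speed = 0.1,
                      start = c(30, 20))
  # discrete hand computation: 720 up steps + duplicated first, 480 down
  expect_equal(chemotactic_index(updown, g), (721 - 480) / 1201)
  expect_equal(chemotactic_index(updown, g), 0.2, tolerance = 0.005)
  # zero motion -> undefined
  still <- make_traj(matrix(rep(c(10, 10), 20), ncol = 2, byrow = TRUE))
  ci <- chemotactic_index(still, g)
  expect_true(is.na(ci))
  expect_match(attr(ci, "reason"), "zero mean speed")
})

test_that("chemotactic index is bounded by 1 in magnitude", {
  g <- default_gradient()
  for (tr in simulated_test_tracks(8, 240, seed = 101))
    expect_lte(abs(chemotactic_index(tr, g)), 1)
})

test_that("BRW index follows the run-duration formula with its conventions", {
  mk_ann <- function(up, down) {
    runs <- data.frame(
      start_idx = seq_along(c(up, down)), end_idx = seq_along(c(up, down)),
      start_s = cumsum(c(0, head(c(up, down), -1))) ,
      end_s = cumsum(c(up, down)),
      direction = rep(c("up", "down"), c(length(up), length(down))))
    runs$start_s <- runs$end_s - c(up, down)
    list(runs = runs)
  }
  expect_equal(brw_index(mk_ann(c(30, 30), c(20, 20))), 0.2)
  expect_equal(brw_index(mk_ann(c(25, 35), numeric(0))), 1)  # only up
  expect_equal(brw_index(mk_ann(c(10, 20), c(20, 10))), 0)   # equal means
  na <- brw_index(list(runs = data.frame(start_s = numeric(0),
                                         end_s = numeric(0),
                                         direction = character(0))))
  expect_true(is.na(na))
})

test_that("klinotaxis index counts qualifying post-reorientation runs", {
  g <- default_gradient()
  # build a track alternating sharp hairpins with long/short runs
  # 6 up-starting and 2 down-starting qualifying runs -> +0.5
  legs <- NULL
  dirs <- c(1, 1, 1, -1, 1, 1, -1, 1) # post-turn run directions
  for (d in dirs) {
    legs <- rbind(legs, c(ifelse(d > 0, pi / 2, -pi / 2), 24)) # 12 s run
    legs <- rbind(legs, c(0, 1)) # sharp kink (heading change >= 100 deg)
  }
  # hand-built annotation instead: qualifying counts are what matters
  ann <- list(
    runs = data.frame(start_idx = (0:7) * 20 + 11, end_idx = (0:7) * 20 + 30,
                      start_s = (0:7) * 10 + 5, end_s = (0:7) * 10 + 15,
                      direction = ifelse(dirs > 0, "up", "down")),
    reorientations = data.frame(start_idx = (0:7) * 20 + 8,
                                end_idx = (0:7) * 20 + 10,
                                kind = "turn",
                                start_s = (0:7) * 10 + 3.5,
                                end_s = (0:7) * 10 + 4.5),
    t = seq(0, 100, by = 0.5),
    axis_coord = rep(0, 201),
    params_used = segmentation_params())
  # axis coordinate: rises during up runs, falls during down runs
  s <- numeric(201)
  for (r in 1:8) {
    ix <- (ann$runs$start_idx[r]):(ann$runs$end_idx[r])
    s[ix] <- s[max(1, ix[1] - 1)] + cumsum(rep(0.05 * dirs[r], length(ix)))
    if (max(ix) < 201) s[(max(ix) + 1):201] <- s[max(ix)]
  }
  ann$axis_coord <- s
  expect_equal(klinotaxis_index(ann), 0.5)
})

test_that("short post-reorientation runs are discarded by the 5 s rule", {
  ann <- list(
    runs = data.frame(start_idx = c(11, 31), end_idx = c(18, 70),
                      start_s = c(5, 15), end_s = c(8.5, 34.5),
                      direction = c("up", "up")),
    reorientations = data.frame(start_idx = c(8, 28), end_idx = c(10, 30),
                                kind = "turn", start_s = c(3.5, 13.5),
                                end_s = c(4.5, 14.5)),
    t = seq(0, 40, by = 0.5), axis_coord = seq(0, 10, length.out = 81),
    params_used = segmentation_params())
  # first run lasts 3.5 s -> discarded; only the second counts (up)
  expect_equal(klinotaxis_index(ann), 1)
})

test_that("quadrant index reproduces its worked cases", {
  expect_equal(quadrant_index(150, 50), 0.5)
  expect_equal(quadrant_index(100, 100), 0)
  expect_equal(quadrant_index(120, 0), 1)
  expect_equal(quadrant_index(0, 80), -1)
  expect_true(is.na(quadrant_index(0, 0)))
  expect_error(quadrant_index(-1, 5))
})

test_that("track selection enforces window presence and deduplication", {
  w <- analysis_window(0, 600, 300)
  long <- straight_traj(1201, speed = 0.05)           # 0-600 s
  short <- straight_traj(481, speed = 0.05)           # 0-240 s
  short$worm_id <- "short"
  kept <- suppressWarnings(select_analysis_tracks(list(long, short), w))
  expect_length(kept, 1)
  expect_equal(kept[[1]]$worm_id, "straight")
  # two tracks of one worm: only the longer survives
  a <- straight_traj(721, speed = 0.05, worm_id = "dup")   # 0-360 s
  b <- straight_traj(1201, speed = 0.05, worm_id = "dup")  # 0-600 s
  kept2 <- select_analysis_tracks(list(a, b), w)
  expect_length(kept2, 1)
  expect_equal(length(kept2[[1]]$t), 1201)
  # empty survivor set warns
  expect_warning(select_analysis_tracks(list(short), w), "no tracks")
})

test_that("mean position trace averages active tracks relative to release", {
  g <- default_gradient()
  still <- lapply(1:3, function(i) {
    tr <- make_traj(matrix(rep(c(60, 60), 21), ncol = 2, byrow = TRUE),
                    worm_id = paste0("s", i))
    tr
  })
  mp <- mean_position_trace(still, g)
  expect_true(all(mp$mean_pos_mm == 0))
  expect_true(all(mp$n == 3))
  # single worm: trace equals its own coordinate, sem undefined
  one <- straight_traj(21, heading = pi / 2, speed = 0.1, worm_id = "solo")
  mp1 <- mean_position_trace(list(one), g)
  expect_equal(mp1$mean_pos_mm, axis_coord(g, one$xy) - g$release_mm)
  expect_true(all(is.na(mp1$sem_mm)))
})

test_that("all three indices negate exactly under gradient reversal", {
  g <- default_gradient()
  g_rev <- reverse_gradient(g)
  sp <- segmentation_params()
  tracks <- simulated_test_tracks(20, 420, seed = 111)
  for (tr in tracks) {
    expect_identical(as.numeric(chemotactic_index(tr, g)),
                     -as.numeric(chemotactic_index(tr, g_rev)))
    ann_f <- segment_trajectory(tr, sp, g)
    ann_r <- segment_trajectory(tr, sp, g_rev)
    b_f <- as.numeric(brw_index(ann_f)); b_r <- as.numeric(brw_index(ann_r))
    k_f <- as.numeric(klinotaxis_index(ann_f))
    k_r <- as.numeric(klinotaxis_index(ann_r))
    if (is.na(b_f)) expect_true(is.na(b_r)) else expect_identical(b_f, -b_r)
    if (is.na(k_f)) expect_true(is.na(k_r)) else expect_identical(k_f, -k_r)
  }
})

test_that("index sign agrees with net population displacement under bias", {
  g <- default_gradient()
  p <- locomotion_params(brw_bias = 0.5)
  pop <- simulate_population(p, g, 40, 900, seed = 121)
  idx <- navigation_indices(pop, g, analysis_window(0, 900, 450))
  mp <- mean_position_trace(pop, g)
  final_mean <- mp$mean_pos_mm[nrow(mp)]
  expect_identical(sign(mean(idx$chemotactic)), sign(final_mean))
  expect_gt(mean(idx$chemotactic), 0)
})
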