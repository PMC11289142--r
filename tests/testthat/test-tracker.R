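# Vision pipeline: colour mask, opening, blobs, selection, smoothing.

test_that("colour mask handles the all-in and all-out extremes", {
  spec <- marker_color_spec()
  black <- array(0, c(16, 16, 3))
  expect_false(any(color_mask(black, spec)))
  red <- array(0, c(16, 16, 3))
  red[, , 1] <- 200; red[, , 2] <- 30; red[, , 3] <- 30
  expect_true(all(color_mask(red, spec)))
})

test_that("colour mask agrees exactly with the per-pixel oracle", {
  set.seed(11)
  sc <- scene_config(image_width_px = 64L, image_height_px = 64L,
                     body_axes_px = c(12, 6), marker_radius_px = 4,
                     noise_sigma = 0, n_frames = 1L)
  specs <- list(marker_color_spec(),
                color_spec("RGB", lower = c(120, 0, 0),
                           upper = c(255, 90, 90)))
  for (spec in specs) {
    fr <- render_frame(sc, runif(2, 0.03, 0.17))$frame
    fr <- add_salt_pepper(fr, 0.05)
    expect_identical(color_mask(fr, spec), oracle_color_mask(fr, spec))
  }
})

test_that("HSV conversion in the mask matches grDevices::rgb2hsv", {
  set.seed(12)
  fr <- array(sample(0:255, 24 * 24 * 3, replace = TRUE), c(24, 24, 3))
  spec <- color_spec("HSV", lower = c(40, 0.2, 0.1), upper = c(200, 0.9, 0.8))
  expect_identical(color_mask(fr, spec), oracle_color_mask(fr, spec))
})

test_that("malformed colour bounds are rejected", {
  expect_error(color_spec("HSV", lower = c(10, 0, 0), upper = c(5, 1, 1)),
               "lower")
  expect_error(color_spec("RGB", lower = c(0, 0), upper = c(1, 1)), "3")
})

test_that("opening at radius 0 is the identity", {
  set.seed(21)
  m <- random_mask()
  expect_identical(morphological_clean(m, 0L), m)
})

test_that("an isolated pixel vanishes under opening at radius 1", {
  m <- matrix(FALSE, 32, 32)
  m[15, 20] <- TRUE
  expect_false(any(morphological_clean(m, 1L)))
})

test_that("opening matches the sliding-window min/max oracle", {
  set.seed(22)
  for (k in 1:3) {
    m <- random_mask(48, 40, p = 0.3)
    expect_identical(morphological_clean(m, 2L), oracle_opening(m, 2L))
  }
  # disk structuring element, not a square: radius 1 is a cross
  m <- matrix(FALSE, 16, 16); m[6:10, 6:10] <- TRUE
  expect_identical(morphological_clean(m, 1L), oracle_opening(m, 1L))
})

test_that("opening is anti-extensive and idempotent", {
  set.seed(23)
  for (k in 1:20) {
    m <- random_mask(40, 40, p = runif(1, 0.05, 0.6))
    r <- sample(0:3, 1)
    o <- morphological_clean(m, r)
    expect_true(all(!o | m))                        # output subset of input
    expect_identical(morphological_clean(o, r), o)  # idempotent
  }
})

test_that("negative opening radius is rejected", {
  expect_error(morphological_clean(matrix(FALSE, 4, 4), -1), "radius")
})

test_that("blob extraction handles point, rectangle and empty cases", {
  expect_equal(nrow(extract_blobs(matrix(FALSE, 8, 8))), 0)
  m <- matrix(FALSE, 64, 64)
  m[21, 11] <- TRUE   # v = 20, u = 10
  b <- extract_blobs(m)
  expect_equal(nrow(b), 1)
  expect_equal(c(b$centroid_u, b$centroid_v), c(10, 20))
  m <- matrix(FALSE, 32, 32)
  m[4:10, 3:7] <- TRUE  # v in [3,9], u in [2,6]
  b <- extract_blobs(m)
  expect_equal(c(b$centroid_u, b$centroid_v), c(4, 6))
  expect_equal(b$pixel_count, 35L)
  expect_equal(c(b$u_min, b$u_max, b$v_min, b$v_max), c(2, 6, 3, 9))
})

test_that("blob partition and centroids match the label-propagation oracle", {
  set.seed(31)
  for (k in 1:5) {
    m <- random_mask(32, 32, p = 0.25)
    blobs <- extract_blobs(m)
    lab <- oracle_label(m)
    expect_equal(nrow(blobs), max(lab))
    idx <- which(lab > 0)
    centroids <- vapply(seq_len(max(lab)), function(l) {
      pix <- which(lab == l)
      c(mean((pix - 1) %/% 32), mean((pix - 1) %% 32), length(pix))
    }, numeric(3))
    got <- blobs[order(blobs$centroid_v, blobs$centroid_u), ]
    ord <- order(centroids[2, ], centroids[1, ])
    expect_equal(got$centroid_u, centroids[1, ord], tolerance = 1e-12)
    expect_equal(got$centroid_v, centroids[2, ord], tolerance = 1e-12)
    expect_equal(got$pixel_count, as.integer(centroids[3, ord]))
  }
})

test_that("blobs are sorted by size with deterministic tie-breaking", {
  m <- matrix(FALSE, 32, 32)
  m[2:3, 2:3] <- TRUE     # 4 px at top-left
  m[20:22, 20:22] <- TRUE # 9 px
  m[2:3, 28:29] <- TRUE   # 4 px, same size as first, larger u
  b <- extract_blobs(m)
  expect_equal(b$pixel_count, c(9L, 4L, 4L))
  expect_lt(b$centroid_u[2], b$centroid_u[3])
})

test_that("target selection follows the size/gate/proximity rules", {
  params <- tracker_params(min_blob_px = 5, max_jump_px = 30)
  expect_null(select_target(extract_blobs(matrix(FALSE, 4, 4)), NULL, params))
  blobs <- tibble::tibble(pixel_count = c(50L, 20L),
                          centroid_u = c(10, 40), centroid_v = c(10, 40),
                          u_min = 0L, u_max = 0L, v_min = 0L, v_max = 0L)
  expect_equal(select_target(blobs, NULL, params)$pixel_count, 50L)
  # all blobs under the size floor -> none
  small <- dplyr::mutate(blobs, pixel_count = c(2L, 3L))
  expect_null(select_target(small, NULL, params))
  # equal sizes at 5 px and 50 px from the previous centroid -> nearer wins
  prev <- update_track(NULL, blobs[1, ], params, 0L)
  eq <- tibble::tibble(pixel_count = c(30L, 30L),
                       centroid_u = c(10 + 5, 10 + 50),
                       centroid_v = c(10, 10),
                       u_min = 0L, u_max = 0L, v_min = 0L, v_max = 0L)
  expect_equal(select_target(eq, prev, params)$centroid_u, 15)
  # none within the gate -> fall back to the largest survivor
  far <- tibble::tibble(pixel_count = c(10L, 25L),
                        centroid_u = c(200, 300), centroid_v = c(200, 300),
                        u_min = 0L, u_max = 0L, v_min = 0L, v_max = 0L)
  expect_equal(select_target(far, prev, params)$pixel_count, 25L)
})

test_that("track update smooths, holds, then reports the target absent", {
  blob <- function(u, v) tibble::tibble(pixel_count = 20L, centroid_u = u,
                                        centroid_v = v, u_min = 0L,
                                        u_max = 0L, v_min = 0L, v_max = 0L)
  # alpha = 1: smoothing is a pass-through
  p1 <- tracker_params(ema_alpha = 1)
  st <- update_track(NULL, blob(3, 4), p1, 0L)
  st <- update_track(st, blob(7, 9), p1, 1L)
  expect_equal(st$smoothed, st$raw)
  # alpha = 0.5 arithmetic
  p <- tracker_params(ema_alpha = 0.5, hold_frames = 2)
  st <- update_track(NULL, blob(0, 0), p, 0L)
  st <- update_track(st, blob(10, 10), p, 1L)
  expect_equal(st$smoothed, c(5, 5))
  # hold for hold_frames misses, absent afterwards
  for (k in 1:2) {
    st <- update_track(st, NULL, p, 1L + k)
    expect_false(st$found)
    expect_equal(st$smoothed, c(5, 5))
    expect_equal(st$hold_counter, k)
  }
  st <- update_track(st, NULL, p, 4L)
  expect_null(st$smoothed)
  expect_equal(st$hold_counter, 3L)
})

test_that("tracked centroids match ground truth on noise-free frames", {
  sc <- test_scene(n_frames = 30L, seed = 5L)
  set.seed(sc$seed)
  traj <- beamtrack:::simulate_trajectory(sc, motion_params())
  frames <- list(); truth_u <- truth_v <- numeric(30)
  for (i in 1:30) {
    fr <- render_frame(sc, traj[[i]]$pos, body_angle_rad = traj[[i]]$angle)
    frames[[i]] <- fr$frame
    truth_u[i] <- fr$truth$marker_u_px
    truth_v[i] <- fr$truth$marker_v_px
  }
  out <- track_sequence(frames, fps = sc$fps)
  expect_true(all(out$found))
  expect_lt(max(abs(out$raw_u_px - truth_u)), 0.5)
  expect_lt(max(abs(out$raw_v_px - truth_v)), 0.5)
  expect_equal(out$time_s, (0:29) / sc$fps)
})

test_that("an all-dark sequence reports the target absent throughout", {
  frames <- replicate(5, array(0, c(32, 32, 3)), simplify = FALSE)
  out <- track_sequence(frames)
  expect_false(any(out$found))
  expect_true(all(is.na(out$raw_u_px)))
})

test_that("an occlusion gap shorter than hold_frames keeps the smoothed track", {
  sc <- test_scene(n_frames = 20L, seed = 6L,
                   occlusion_intervals = list(c(8, 12)))
  set.seed(sc$seed)
  traj <- beamtrack:::simulate_trajectory(sc, motion_params())
  frames <- lapply(1:20, function(i)
    render_frame(sc, traj[[i]]$pos, occluded = frame_occluded_test(sc, i - 1),
                 body_angle_rad = traj[[i]]$angle)$frame)
  out <- track_sequence(frames, params = tracker_params(hold_frames = 10))
  expect_false(any(is.na(out$smooth_u_px)))
  expect_equal(out$found, !(0:19 %in% 8:11))
})

test_that("integer translation of a frame translates the centroid exactly", {
  sc <- test_scene()
  fr <- render_frame(sc, c(0.08, 0.11))$frame
  du <- 7L; dv <- -4L
  shifted <- array(sc$background_gray, dim(fr))
  H <- dim(fr)[1]; W <- dim(fr)[2]
  shifted[(1 + max(0, dv)):(H + min(0, dv)), (1 + max(0, du)):(W + min(0, du)), ] <-
    fr[(1 - min(0, dv)):(H - max(0, dv)), (1 - min(0, du)):(W - max(0, du)), ]
  b0 <- extract_blobs(color_mask(fr, marker_color_spec()))
  b1 <- extract_blobs(color_mask(shifted, marker_color_spec()))
  expect_equal(b1$centroid_u[1], b0$centroid_u[1] + du, tolerance = 1e-12)
  expect_equal(b1$centroid_v[1], b0$centroid_v[1] + dv, tolerance = 1e-12)
})

test_that("track_sequence reads a frame directory and reports bad frames", {
  sc <- test_scene(n_frames = 4L)
  d <- withr::local_tempdir()
  generate_dataset(sc, motion_params(), d)
  out <- track_sequence(d, fps = sc$fps)
  expect_equal(nrow(out), 4)
  expect_true(all(out$found))
  # corrupt one frame on disk
  writeLines("not a png", file.path(d, "frame_000002.png"))
  expect_error(track_sequence(d), "frame index 2")
})
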