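# Synthetic overhead-camera scenes: a dark cage floor, a grey mouse-like
# body, a coloured circular marker on its back, sensor noise and scripted
# occlusion intervals, with exact per-frame ground truth.

#' Scene configuration for the synthetic overhead camera
#'
#' Describes one simulated cage scene: a dark floor imaged by a fixed
#' overhead camera, a grey elliptical body carrying a coloured circular
#' marker, Gaussian sensor noise, and optional occlusion intervals during
#' which the marker is not drawn. Defaults emulate a 20 x 20 cm cage floor
#' seen at 640 x 640 px (32 px/cm) with a red pen mark of ~5 mm radius.
#'
#' Pixel conventions: pixel centers sit at integer coordinates, 0-based,
#' origin at the top-left, `u` rightward (columns), `v` downward (rows).
#' Arena coordinates are metres with the origin at the image's top-left
#' floor corner, x along `u` and y along `v`.
#'
#' @param arena_width_m,arena_height_m Cage floor size in metres.
#' @param image_width_px,image_height_px Image size in pixels.
#' @param background_gray Floor grey level, 0-255.
#' @param body_axes_px Length-2: ellipse semi-axes of the body in pixels.
#' @param body_gray Body grey level, 0-255.
#' @param marker_radius_px Marker disk radius in pixels (>= 1).
#' @param marker_rgb Length-3 marker colour, 0-255 per channel.
#' @param noise_sigma Gaussian sensor noise s.d. in grey levels (>= 0).
#' @param occlusion_intervals List of half-open `[start, end)` frame-index
#'   pairs during which the marker is hidden.
#' @param fps Frames per second.
#' @param n_frames Number of frames.
#' @param seed Integer seed driving motion and noise.
#' @return A validated `scene_config` list.
#' @export
scene_config <- function(arena_width_m = 0.20, arena_height_m = 0.20,
                         image_width_px = 640L, image_height_px = 640L,
                         background_gray = 20, body_axes_px = c(110, 55),
                         body_gray = 110, marker_radius_px = 16,
                         marker_rgb = c(200, 30, 30), noise_sigma = 2,
                         occlusion_intervals = list(), fps = 20,
                         n_frames = 200L, seed = 1L) {
  check_scalar_number(arena_width_m, "arena_width_m", 0, strict_lower = TRUE)
  check_scalar_number(arena_height_m, "arena_height_m", 0, strict_lower = TRUE)
  check_scalar_number(image_width_px, "image_width_px", 8)
  check_scalar_number(image_height_px, "image_height_px", 8)
  check_scalar_number(background_gray, "background_gray", 0, 255)
  check_scalar_number(body_gray, "body_gray", 0, 255)
  check_scalar_number(marker_radius_px, "marker_radius_px", 1)
  check_scalar_number(noise_sigma, "noise_sigma", 0)
  check_scalar_number(fps, "fps", 0, strict_lower = TRUE)
  check_scalar_number(n_frames, "n_frames", 1)
  check_scalar_number(seed, "seed")
  if (length(body_axes_px) != 2L || any(body_axes_px <= 0))
    stop_invalid("body_axes_px must be two positive semi-axes")
  if (length(marker_rgb) != 3L || any(marker_rgb < 0) || any(marker_rgb > 255))
    stop_invalid("marker_rgb must be three values in [0, 255]")
  if (!is.list(occlusion_intervals))
    stop_invalid("occlusion_intervals must be a list of [start, end) pairs")
  for (iv in occlusion_intervals) {
    if (length(iv) != 2L || iv[1] < 0 || iv[2] > n_frames || iv[1] >= iv[2])
      stop_invalid("occlusion interval must satisfy 0 <= start < end <= n_frames")
  }
  structure(
    list(arena_width_m = arena_width_m, arena_height_m = arena_height_m,
         image_width_px = as.integer(image_width_px),
         image_height_px = as.integer(image_height_px),
         background_gray = background_gray, body_axes_px = body_axes_px,
         body_gray = body_gray, marker_radius_px = marker_radius_px,
         marker_rgb = marker_rgb, noise_sigma = noise_sigma,
         occlusion_intervals = occlusion_intervals, fps = fps,
         n_frames = as.integer(n_frames), seed = as.integer(seed)),
    class = "scene_config")
}

#' Bounded random-motion parameters
#'
#' Parameters of the reflected Ornstein-Uhlenbeck process used to move the
#' marker around the arena: velocity relaxes toward zero with the given
#' relaxation time while being driven by white noise scaled so that the
#' stationary root-mean-square speed equals `speed_scale_m_per_s`; the
#' position integrates the velocity and reflects off the walls, keeping the
#' trajectory inside the arena minus `boundary_margin_m`.
#'
#' @param speed_scale_m_per_s Stationary RMS speed, m/s.
#' @param relaxation_time_s Velocity relaxation time, s.
#' @param boundary_margin_m Reflective margin kept from the walls, m.
#' @return A validated `motion_params` list.
#' @export
motion_params <- function(speed_scale_m_per_s = 0.05, relaxation_time_s = 1,
                          boundary_margin_m = 0.02) {
  check_scalar_number(speed_scale_m_per_s, "speed_scale_m_per_s", 0)
  check_scalar_number(relaxation_time_s, "relaxation_time_s", 0,
                      strict_lower = TRUE)
  check_scalar_number(boundary_margin_m, "boundary_margin_m", 0,
                      strict_lower = TRUE)
  structure(list(speed_scale_m_per_s = speed_scale_m_per_s,
                 relaxation_time_s = relaxation_time_s,
                 boundary_margin_m = boundary_margin_m),
            class = "motion_params")
}

# Fold a coordinate into [lo, hi] by reflection; returns the folded value
# and whether an odd number of reflections occurred (velocity flips).
reflect_coord <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  flipped <- y > span
  list(x = lo + ifelse(flipped, 2 * span - y, y), flipped = flipped)
}

#' Advance the bounded Ornstein-Uhlenbeck motion by one step
#'
#' Exact-discretisation OU update of the velocity followed by an Euler
#' position step and reflective handling at the arena margins. Uses the
#' global RNG; seed it (`set.seed`) for reproducible trajectories.
#'
#' @param state List with `pos` (x, y in metres) and `vel` (m/s).
#' @param params A [motion_params()] object.
#' @param dt Time step in seconds (> 0).
#' @param arena_width_m,arena_height_m Arena size in metres.
#' @return Updated state list.
#' @export
step_motion <- function(state, params, dt,
                        arena_width_m = 0.20, arena_height_m = 0.20) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop_invalid("dt must be a single positive number")
  m <- params$boundary_margin_m
  if (any(state$pos < c(m, m)) ||
      any(state$pos > c(arena_width_m - m, arena_height_m - m)))
    stop_invalid("state position outside arena margins")
  tau <- params$relaxation_time_s
  sigma1 <- params$speed_scale_m_per_s / sqrt(2)  # per-axis stationary s.d.
  a <- exp(-dt / tau)
  vel <- state$vel * a + sigma1 * sqrt(1 - a^2) * rnorm(2)
  pos <- state$pos + vel * dt
  rx <- reflect_coord(pos[1], m, arena_width_m - m)
  ry <- reflect_coord(pos[2], m, arena_height_m - m)
  list(pos = c(rx$x, ry$x),
       vel = c(ifelse(rx$flipped, -vel[1], vel[1]),
               ifelse(ry$flipped, -vel[2], vel[2])))
}

#' Camera model implied by a synthetic scene
#'
#' The simulated camera images the whole floor with square pixels and no
#' distortion, so the pixel-to-arena map is the affine homography
#' `x = (u + 0.5) * arena_width / image_width` (and likewise for y/v),
#' placing pixel centers at integer coordinates with pixel (0, 0) covering
#' the arena corner.
#'
#' @param scene A [scene_config()].
#' @return A [camera_model()] mapping pixels to arena metres.
#' @export
scene_camera <- function(scene) {
  sx <- scene$arena_width_m / scene$image_width_px
  sy <- scene$arena_height_m / scene$image_height_px
  camera_model(matrix(c(sx, 0, 0.5 * sx,
                        0, sy, 0.5 * sy,
                        0, 0, 1), 3, 3, byrow = TRUE))
}

# Project arena metres to sub-pixel image coordinates for a scene.
scene_project <- function(scene, xy) {
  c(u = xy[1] * scene$image_width_px / scene$arena_width_m - 0.5,
    v = xy[2] * scene$image_height_px / scene$arena_height_m - 0.5)
}

#' Render one synthetic frame
#'
#' Draws the floor, the body ellipse centred on the marker, and (unless
#' occluded) the marker disk, then adds Gaussian sensor noise and clips to
#' 8-bit range. Rasterisation is pixel-center-in-shape membership at the
#' sub-pixel marker position. The body is drawn before the marker so the
#' marker is only hidden through explicit occlusion.
#'
#' @param scene A [scene_config()].
#' @param marker_pos Length-2 marker position in arena metres.
#' @param occluded If `TRUE` the marker disk is not drawn.
#' @param body_angle_rad Orientation of the body ellipse's major axis.
#' @param frame_index,time_s Metadata copied into the ground-truth record.
#' @return List with `frame` (H x W x 3 array, integer grey levels 0-255)
#'   and `truth` (one-row tibble of the ground-truth record).
#' @export
render_frame <- function(scene, marker_pos, occluded = FALSE,
                         body_angle_rad = 0, frame_index = 0L, time_s = 0) {
  if (any(marker_pos < 0) || marker_pos[1] > scene$arena_width_m ||
      marker_pos[2] > scene$arena_height_m)
    stop_invalid("marker position outside arena")
  W <- scene$image_width_px
  H <- scene$image_height_px
  uv <- scene_project(scene, marker_pos)
  img <- array(scene$background_gray, dim = c(H, W, 3))

  # Paint `value[ch]` on pixels of the shape, rasterising only within the
  # shape's bounding box (pixel-center membership).
  paint <- function(img, member, ext_u, ext_v, value) {
    u0 <- max(0, floor(uv[["u"]] - ext_u)); u1 <- min(W - 1, ceiling(uv[["u"]] + ext_u))
    v0 <- max(0, floor(uv[["v"]] - ext_v)); v1 <- min(H - 1, ceiling(uv[["v"]] + ext_v))
    if (u0 > u1 || v0 > v1) return(img)
    us <- u0:u1; vs <- v0:v1
    du <- matrix(us - uv[["u"]], length(vs), length(us), byrow = TRUE)
    dv <- matrix(vs - uv[["v"]], length(vs), length(us))
    m <- member(du, dv)
    for (ch in 1:3) {
      sub <- img[vs + 1, us + 1, ch]
      sub[m] <- value[ch]
      img[vs + 1, us + 1, ch] <- sub
    }
    img
  }
  ca <- cos(body_angle_rad); sa <- sin(body_angle_rad)
  ax <- scene$body_axes_px
  img <- paint(img,
               function(du, dv) ((du * ca + dv * sa) / ax[1])^2 +
                                ((-du * sa + dv * ca) / ax[2])^2 <= 1,
               ext_u = sqrt((ax[1] * ca)^2 + (ax[2] * sa)^2),
               ext_v = sqrt((ax[1] * sa)^2 + (ax[2] * ca)^2),
               value = rep(scene$body_gray, 3))
  if (!occluded) {
    r <- scene$marker_radius_px
    img <- paint(img, function(du, dv) du^2 + dv^2 <= r^2,
                 ext_u = r, ext_v = r, value = scene$marker_rgb)
  }
  if (scene$noise_sigma > 0) {
    img <- img + rnorm(length(img), sd = scene$noise_sigma)
    img <- round(clamp(img, 0, 255))
  }
  truth <- tibble(frame_index = as.integer(frame_index), time_s = time_s,
                  marker_x_m = marker_pos[1], marker_y_m = marker_pos[2],
                  marker_u_px = uv[["u"]], marker_v_px = uv[["v"]],
                  occluded = occluded)
  list(frame = img, truth = truth)
}

frame_occluded <- function(scene, i) {
  for (iv in scene$occlusion_intervals)
    if (i >= iv[1] && i < iv[2]) return(TRUE)
  FALSE
}

# Simulate the full trajectory for a scene: one row of state per frame.
# The marker starts at rest at the arena centre.
simulate_trajectory <- function(scene, motion) {
  state <- list(pos = c(scene$arena_width_m / 2, scene$arena_height_m / 2),
                vel = c(0, 0))
  dt <- 1 / scene$fps
  out <- vector("list", scene$n_frames)
  angle <- 0
  for (i in seq_len(scene$n_frames)) {
    if (i > 1L)
      state <- step_motion(state, motion, dt,
                           scene$arena_width_m, scene$arena_height_m)
    spd <- sqrt(sum(state$vel^2))
    if (spd > 1e-9) angle <- atan2(state$vel[2], state$vel[1])
    out[[i]] <- list(pos = state$pos, vel = state$vel, angle = angle)
  }
  out
}

#' Write a synthetic dataset to disk
#'
#' Generates `n_frames` PNG frames (`frame_%06d.png`) plus
#' `ground_truth.csv` with one record per frame. Fully reproducible from
#' the scene seed.
#'
#' @param scene A [scene_config()].
#' @param motion A [motion_params()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the ground-truth tibble.
#' @export
generate_dataset <- function(scene, motion = motion_params(), out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_invalid("cannot create output directory ", out_dir)
  set.seed(scene$seed)
  traj <- simulate_trajectory(scene, motion)
  truths <- vector("list", scene$n_frames)
  for (i in seq_len(scene$n_frames)) {
    idx <- i - 1L
    occ <- frame_occluded(scene, idx)
    fr <- render_frame(scene, traj[[i]]$pos, occluded = occ,
                       body_angle_rad = traj[[i]]$angle,
                       frame_index = idx, time_s = idx / scene$fps)
    path <- file.path(out_dir, sprintf("frame_%06d.png", idx))
    atomic_write(path, function(tmp) png::writePNG(fr$frame / 255, tmp))
    truths[[i]] <- fr$truth
  }
  truth <- dplyr::bind_rows(truths)
  write_csv_atomic(truth, file.path(out_dir, "ground_truth.csv"))
  invisible(truth)
}

#' Corrupt a frame with salt-and-pepper noise
#'
#' Sets a fraction of pixels (all three channels) to pure black or pure
#' white, emulating impulsive sensor/compression artefacts. Uses the global
#' RNG.
#'
#' @param frame H x W x 3 array, grey levels 0-255.
#' @param fraction Fraction of pixels to corrupt.
#' @return The corrupted frame.
#' @export
add_salt_pepper <- function(frame, fraction = 0.01) {
  d <- dim(frame)
  n <- d[1] * d[2]
  k <- round(fraction * n)
  if (k == 0) return(frame)
  idx <- sample.int(n, k)
  val <- ifelse(runif(k) < 0.5, 0, 255)
  for (ch in 1:3) {
    plane <- frame[, , ch]
    plane[idx] <- val
    frame[, , ch] <- plane
  }
  frame
}

#' Read one PNG frame as an 8-bit RGB array
#'
#' @param path PNG file path.
#' @return H x W x 3 array of grey levels 0-255.
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) stop_invalid("cannot read frame ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}
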