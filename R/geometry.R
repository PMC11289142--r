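# Pixel -> arena-floor -> gimbal-angle geometry: planar homography
# calibration (DLT), projective application, pan/tilt pointing and the
# laser ray's intersection with the floor plane.

#' Camera model: planar homography from pixels to the arena floor
#'
#' Wraps an invertible 3 x 3 projective map taking image pixel coordinates
#' `(u, v)` to arena-floor metres `(x, y)`. The overhead camera views the
#' planar cage floor, so a homography captures the full mapping; lens
#' distortion is out of scope.
#'
#' @param H 3 x 3 numeric matrix, non-singular; stored normalised so the
#'   bottom-right element is 1 when it is non-zero.
#' @return A `camera_model`.
#' @export
camera_model <- function(H) {
  if (!is.matrix(H) || any(dim(H) != c(3L, 3L)) || !all(is.finite(H)))
    stop_invalid("H must be a finite 3 x 3 matrix")
  if (abs(det(H)) < 1e-14)
    stop_invalid("homography is singular")
  if (abs(H[3, 3]) > 1e-12) H <- H / H[3, 3]
  structure(list(H = H), class = "camera_model")
}

# Apply a homography to an n x 2 matrix of points.
apply_homography <- function(H, pts) {
  pts <- matrix(pts, ncol = 2)
  ph <- cbind(pts, 1) %*% t(H)
  w <- ph[, 3]
  if (any(abs(w) < 1e-12))
    stop_invalid("point maps to the plane at infinity (w ~ 0)")
  cbind(ph[, 1] / w, ph[, 2] / w)
}

# Hartley normalisation: translate centroid to origin, scale mean distance
# to sqrt(2). Returns the 3 x 3 similarity transform.
normalising_transform <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  s <- if (mean(d) > 1e-12) sqrt(2) / mean(d) else 1
  matrix(c(s, 0, -s * ctr[1],
           0, s, -s * ctr[2],
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Calibrate the pixel-to-arena homography
#'
#' Direct linear transform from at least four pixel/arena correspondences,
#' solved in least squares via SVD for more than four, with Hartley
#' normalisation for conditioning. Matches the device's calibration step in
#' which a marker of known position is imaged at reference points.
#'
#' @param pixel_points n x 2 matrix (or data frame with columns u, v) of
#'   pixel coordinates.
#' @param arena_points n x 2 matrix of matching arena metres.
#' @return A [camera_model()].
#' @export
calibrate_homography <- function(pixel_points, arena_points) {
  px <- as.matrix(pixel_points)[, 1:2, drop = FALSE]
  ar <- as.matrix(arena_points)[, 1:2, drop = FALSE]
  storage.mode(px) <- "double"; storage.mode(ar) <- "double"
  n <- nrow(px)
  if (n < 4L || nrow(ar) != n)
    stop_invalid("need >= 4 matching correspondences")
  Tp <- normalising_transform(px)
  Ta <- normalising_transform(ar)
  pn <- apply_homography(Tp, px)
  an <- apply_homography(Ta, ar)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    u <- pn[i, 1]; v <- pn[i, 2]; x <- an[i, 1]; y <- an[i, 2]
    A[2 * i - 1, ] <- c(-u, -v, -1, 0, 0, 0, u * x, v * x, x)
    A[2 * i, ]     <- c(0, 0, 0, -u, -v, -1, u * y, v * y, y)
  }
  sv <- svd(A, nu = 0, nv = 9)
  # Rank check: a unique homography needs rank 8.
  if (sv$d[8] < max(sv$d) * 1e-9)
    stop_invalid("degenerate correspondence configuration (rank-deficient)")
  h <- sv$v[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(Ta) %*% Hn %*% Tp
  camera_model(H)
}

#' Map pixel coordinates to arena metres
#'
#' Projective application of the camera homography with homogeneous
#' normalisation.
#'
#' @param model A [camera_model()].
#' @param u,v Pixel coordinates (vectorised).
#' @return Tibble with columns `x_m`, `y_m`.
#' @export
pixel_to_arena <- function(model, u, v) {
  xy <- apply_homography(model$H, cbind(u, v))
  tibble(x_m = xy[, 1], y_m = xy[, 2])
}

#' Map arena metres to pixel coordinates
#'
#' Inverse of [pixel_to_arena()].
#'
#' @param model A [camera_model()].
#' @param x,y Arena coordinates in metres (vectorised).
#' @return Tibble with columns `u_px`, `v_px`.
#' @export
arena_to_pixel <- function(model, x, y) {
  uv <- apply_homography(solve(model$H), cbind(x, y))
  tibble(u_px = uv[, 1], v_px = uv[, 2])
}

#' Gimbal mount model
#'
#' Geometry and kinematic limits of the two-axis laser mount above the
#' arena floor. Pan is measured counter-clockwise (viewed from above) from
#' the `pan_zero_deg` reference axis — the frame-parallel direction used to
#' fix the yaw reference — and tilt is the angle of the laser ray from
#' straight down (nadir), so tilt must stay in [0, 90) degrees for the ray
#' to hit the floor.
#'
#' @param mount_x_m,mount_y_m Mount position over the floor, metres.
#' @param mount_z_m Mount height above the floor, metres (> 0).
#' @param pan_zero_deg Direction of the pan reference axis, degrees CCW
#'   from +x.
#' @param max_slew_deg_per_s Per-axis maximum angular speed, degrees/s.
#' @param pan_limits_deg,tilt_limits_deg Closed angle intervals.
#' @return A `gimbal_model`.
#' @export
gimbal_model <- function(mount_x_m = 0.10, mount_y_m = 0.10, mount_z_m = 0.33,
                         pan_zero_deg = 0, max_slew_deg_per_s = 300,
                         pan_limits_deg = c(-180, 180),
                         tilt_limits_deg = c(0, 60)) {
  check_scalar_number(mount_z_m, "mount_z_m", 0, strict_lower = TRUE)
  check_scalar_number(max_slew_deg_per_s, "max_slew_deg_per_s", 0,
                      strict_lower = TRUE)
  if (length(pan_limits_deg) != 2L || pan_limits_deg[1] >= pan_limits_deg[2])
    stop_invalid("pan_limits_deg must be a non-empty interval")
  if (length(tilt_limits_deg) != 2L || tilt_limits_deg[1] >= tilt_limits_deg[2] ||
      tilt_limits_deg[1] < 0 || tilt_limits_deg[2] >= 90)
    stop_invalid("tilt_limits_deg must lie within [0, 90)")
  structure(list(mount_x_m = mount_x_m, mount_y_m = mount_y_m,
                 mount_z_m = mount_z_m, pan_zero_deg = pan_zero_deg,
                 max_slew_deg_per_s = max_slew_deg_per_s,
                 pan_limits_deg = pan_limits_deg,
                 tilt_limits_deg = tilt_limits_deg),
            class = "gimbal_model")
}

#' Gimbal pose
#'
#' @param pan_deg Pan angle, degrees CCW from the model's reference axis.
#' @param tilt_deg Tilt from nadir, degrees in [0, 90).
#' @param out_of_range `TRUE` when the pose was clamped to the model limits.
#' @return A `gimbal_pose`.
#' @export
gimbal_pose <- function(pan_deg, tilt_deg, out_of_range = FALSE) {
  structure(list(pan_deg = pan_deg, tilt_deg = tilt_deg,
                 out_of_range = out_of_range),
            class = "gimbal_pose")
}

#' Point the gimbal at an arena-floor target
#'
#' Converts a floor position to pan/tilt via trigonometry: with horizontal
#' offset `d` from the mount, `tilt = atan(d / mount_z)` and pan is the
#' planar bearing of the target from the reference axis, reported in
#' (-180, 180]. Directly beneath the mount (`d = 0`) the bearing is
#' undefined and the previous pan is kept, so trajectories through nadir
#' produce no pan jump. Out-of-limit targets are clamped and flagged
#' rather than rejected, since a moving animal may transiently leave the
#' reachable cone.
#'
#' @param model A [gimbal_model()].
#' @param x,y Target position on the floor, metres.
#' @param prev_pan_deg Pan angle held when the target is at nadir.
#' @return A [gimbal_pose()].
#' @export
arena_to_gimbal <- function(model, x, y, prev_pan_deg = 0) {
  dx <- x - model$mount_x_m
  dy <- y - model$mount_y_m
  d <- sqrt(dx^2 + dy^2)
  tilt <- atan(d / model$mount_z_m) * 180 / pi
  pan <- if (d < 1e-12) prev_pan_deg
         else wrap_deg(atan2(dy, dx) * 180 / pi - model$pan_zero_deg)
  cl_pan <- clamp(pan, model$pan_limits_deg[1], model$pan_limits_deg[2])
  cl_tilt <- clamp(tilt, model$tilt_limits_deg[1], model$tilt_limits_deg[2])
  gimbal_pose(cl_pan, cl_tilt, out_of_range = (cl_pan != pan || cl_tilt != tilt))
}

#' Laser spot on the arena floor
#'
#' Intersects the laser ray, leaving the mount with direction
#' `(sin tilt cos pan, sin tilt sin pan, -cos tilt)` (pan taken about the
#' model's reference axis), with the floor plane `z = 0`:
#' `spot = mount_xy + mount_z * tan(tilt) * (cos pan, sin pan)`.
#'
#' @param model A [gimbal_model()].
#' @param pose A [gimbal_pose()].
#' @return Named numeric `c(x_m, y_m)`.
#' @export
laser_spot <- function(model, pose) {
  if (pose$tilt_deg >= 90 || pose$tilt_deg < 0)
    stop_invalid("tilt must lie in [0, 90) for the ray to hit the floor")
  ang <- (pose$pan_deg + model$pan_zero_deg) * pi / 180
  r <- model$mount_z_m * tan(pose$tilt_deg * pi / 180)
  c(x_m = model$mount_x_m + r * cos(ang),
    y_m = model$mount_y_m + r * sin(ang))
}

#' Read a calibration correspondence table
#'
#' CSV with header `u_px,v_px,x_m,y_m`, one correspondence per row.
#'
#' @param path CSV path.
#' @return Tibble of correspondences.
#' @export
read_calibration_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("calibration file not found: ", path)
  df <- read.csv(path)
  need <- c("u_px", "v_px", "x_m", "y_m")
  if (!all(need %in% names(df)))
    stop_invalid("calibration CSV must have columns ", paste(need, collapse = ","))
  as_tibble(df[, need])
}

#' Serialise camera and gimbal models to JSON
#'
#' @param path Output JSON path.
#' @param camera Optional [camera_model()].
#' @param gimbal Optional [gimbal_model()].
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(path, camera = NULL, gimbal = NULL) {
  out <- list()
  if (!is.null(camera))
    out$homography <- lapply(1:3, function(i) camera$H[i, ])
  if (!is.null(gimbal))
    out$gimbal <- unclass(gimbal)
  atomic_write(path, function(tmp) {
    jsonlite::write_json(out, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  invisible(path)
}

#' Read camera/gimbal models from JSON
#'
#' @param path JSON path written by [write_model_json()].
#' @return List with `camera` ([camera_model()] or `NULL`) and `gimbal`
#'   ([gimbal_model()] or `NULL`).
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop_invalid("model file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera <- if (!is.null(raw$homography)) {
    H <- raw$homography
    if (is.list(H)) H <- do.call(rbind, H)
    camera_model(matrix(as.numeric(t(H)), 3, 3, byrow = TRUE))
  }
  gimbal <- if (!is.null(raw$gimbal)) do.call(gimbal_model, as.list(raw$gimbal))
  list(camera = camera, gimbal = gimbal)
}
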