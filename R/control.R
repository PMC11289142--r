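# Closed loop: illumination scheduling with exact dose arithmetic, a
# slew-rate-limited servo standing in for the PID-stabilised gimbal, and
# the full per-frame render -> track -> point -> illuminate simulation
# with summary metrics.

#' Illumination schedule
#'
#' Describes the light regime: continuously on, off (dark control), or an
#' alternating light/dark cycle such as the 12 h / 12 h day-night regime
#' used for long induction experiments. Light intervals are half-open
#' `[on-start, off-start)`.
#'
#' @param mode `"CYCLE"`, `"CONTINUOUS_ON"` or `"OFF"`.
#' @param cycle_on_h,cycle_off_h Cycle on/off durations in hours (> 0 for
#'   `CYCLE`).
#' @param phase_h Phase offset of the cycle in hours.
#' @param irradiance_uW_cm2 Delivered irradiance in microwatts per cm^2.
#' @param start_time_s Schedule start time in seconds.
#' @return A `light_schedule`.
#' @export
light_schedule <- function(mode = c("CYCLE", "CONTINUOUS_ON", "OFF"),
                           cycle_on_h = 12, cycle_off_h = 12, phase_h = 0,
                           irradiance_uW_cm2 = 100, start_time_s = 0) {
  mode <- match.arg(mode)
  check_scalar_number(irradiance_uW_cm2, "irradiance_uW_cm2", 0)
  check_scalar_number(start_time_s, "start_time_s")
  if (mode == "CYCLE") {
    check_scalar_number(cycle_on_h, "cycle_on_h", 0, strict_lower = TRUE)
    check_scalar_number(cycle_off_h, "cycle_off_h", 0, strict_lower = TRUE)
  }
  structure(list(mode = mode, cycle_on_h = cycle_on_h,
                 cycle_off_h = cycle_off_h, phase_h = phase_h,
                 irradiance_uW_cm2 = irradiance_uW_cm2,
                 start_time_s = start_time_s),
            class = "light_schedule")
}

#' Is the light scheduled on at time t?
#'
#' For a cycle, on iff `((t - start - phase) mod (on + off)) < on`, all in
#' seconds, with half-open light intervals.
#'
#' @param schedule A [light_schedule()].
#' @param t Time(s) in seconds, each `>= start_time_s`.
#' @return Logical vector.
#' @export
is_light_on <- function(schedule, t) {
  if (any(t < schedule$start_time_s))
    stop_invalid("t must be >= schedule start time")
  switch(schedule$mode,
    CONTINUOUS_ON = rep(TRUE, length(t)),
    OFF = rep(FALSE, length(t)),
    CYCLE = {
      on_s <- schedule$cycle_on_h * 3600
      period <- on_s + schedule$cycle_off_h * 3600
      ((t - schedule$start_time_s - schedule$phase_h * 3600) %% period) < on_s
    })
}

#' Cumulative irradiance dose over an interval
#'
#' Irradiance times total scheduled on-time in `[t0, t1)`, computed exactly
#' by interval arithmetic (no quadrature), in joules per cm^2.
#'
#' @param schedule A [light_schedule()].
#' @param t0,t1 Interval bounds in seconds, `t0 <= t1`, both at or after
#'   the schedule start.
#' @return Dose in J cm^-2.
#' @export
cumulative_dose <- function(schedule, t0, t1) {
  schedule$irradiance_uW_cm2 * 1e-6 * schedule_on_time(schedule, t0, t1)
}

#' Scheduled on-time over an interval
#'
#' Total seconds of light in `[t0, t1)`, by exact interval arithmetic:
#' whole cycles contribute exactly `n * cycle_on` seconds.
#'
#' @inheritParams cumulative_dose
#' @return On-time in seconds.
#' @export
schedule_on_time <- function(schedule, t0, t1) {
  if (t1 < t0) stop_invalid("reversed interval: t1 must be >= t0")
  if (t0 < schedule$start_time_s)
    stop_invalid("t0 must be >= schedule start time")
  switch(schedule$mode,
    CONTINUOUS_ON = t1 - t0,
    OFF = 0,
    CYCLE = {
      on_s <- schedule$cycle_on_h * 3600
      period <- on_s + schedule$cycle_off_h * 3600
      # F(x) = on-time accumulated from the cycle origin to x.
      F <- function(x) floor(x / period) * on_s + pmin(x %% period, on_s)
      origin <- schedule$start_time_s + schedule$phase_h * 3600
      F(t1 - origin) - F(t0 - origin)
    })
}

#' Servo state
#'
#' @param pose A [gimbal_pose()].
#' @param laser_on Logical.
#' @return A `servo_state`.
#' @export
servo_state <- function(pose, laser_on = FALSE) {
  structure(list(pose = pose, laser_on = laser_on), class = "servo_state")
}

#' Advance the rate-limited servo one step
#'
#' Each axis moves independently toward its target by at most
#' `max_slew_deg_per_s * dt`, reaching the target exactly when within that
#' bound. Pan moves along the shorter wrapped direction and the result is
#' clamped into the model limits. This abstracts the device's
#' PID-stabilised brushless gimbal to the property that matters for
#' pointing: bounded angular velocity.
#'
#' @param model A [gimbal_model()].
#' @param state A [servo_state()].
#' @param target A [gimbal_pose()].
#' @param dt Time step in seconds (> 0).
#' @return Updated `servo_state`.
#' @export
servo_step <- function(model, state, target, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop_invalid("dt must be a single positive number")
  max_step <- model$max_slew_deg_per_s * dt
  pan_err <- wrap_deg(target$pan_deg - state$pose$pan_deg)
  pan <- state$pose$pan_deg + clamp(pan_err, -max_step, max_step)
  pan <- clamp(wrap_deg(pan), model$pan_limits_deg[1], model$pan_limits_deg[2])
  tilt_err <- target$tilt_deg - state$pose$tilt_deg
  tilt <- state$pose$tilt_deg + clamp(tilt_err, -max_step, max_step)
  tilt <- clamp(tilt, model$tilt_limits_deg[1], model$tilt_limits_deg[2])
  servo_state(gimbal_pose(pan, tilt, target$out_of_range), state$laser_on)
}

check_loop_geometry <- function(scene, cam) {
  corners <- cbind(c(0, scene$image_width_px - 1, scene$image_width_px - 1, 0),
                   c(0, 0, scene$image_height_px - 1, scene$image_height_px - 1))
  xy <- apply_homography(cam$H, corners)
  tol_x <- 0.05 * scene$arena_width_m
  tol_y <- 0.05 * scene$arena_height_m
  if (any(xy[, 1] < -tol_x | xy[, 1] > scene$arena_width_m + tol_x |
          xy[, 2] < -tol_y | xy[, 2] > scene$arena_height_m + tol_y))
    stop_invalid("camera model and scene geometry are inconsistent: ",
                 "image corners do not map onto the arena floor")
}

#' Run the closed tracking-and-illumination loop
#'
#' Simulates the full device cycle frame by frame: render the scene at the
#' current ground-truth marker position, run the tracking pipeline, convert
#' the smoothed centroid to arena coordinates and a gimbal target, advance
#' the rate-limited servo, intersect the laser ray with the floor, and
#' apply the illumination schedule with lost-target gating (the laser is
#' off whenever the schedule says off or the tracker reports the target
#' absent). The servo acts on the centroid of the current frame, i.e. on
#' one-frame-old information at spot time — a conservative latency model.
#' Deterministic given the scene seed.
#'
#' @param scene A [scene_config()].
#' @param motion A [motion_params()].
#' @param spec A [color_spec()].
#' @param tparams A [tracker_params()].
#' @param cam A [camera_model()]; defaults to the scene's exact camera.
#' @param gimbal A [gimbal_model()].
#' @param schedule A [light_schedule()].
#' @param time_scale Simulated seconds of experiment clock per camera-frame
#'   interval unit; 1 means real time, larger values compress long
#'   light/dark schedules into desk-scale runs.
#' @return A `closed_loop` object with `$log` (per-frame tibble) and
#'   `$metrics` (summary list); see [glance.closed_loop()].
#' @export
run_closed_loop <- function(scene, motion = motion_params(),
                            spec = marker_color_spec(),
                            tparams = tracker_params(),
                            cam = scene_camera(scene),
                            gimbal = gimbal_model(),
                            schedule = light_schedule("CONTINUOUS_ON"),
                            time_scale = 1) {
  check_loop_geometry(scene, cam)
  set.seed(scene$seed)
  traj <- simulate_trajectory(scene, motion)
  dt_sim <- time_scale / scene$fps
  marker_radius_m <- scene$marker_radius_px *
    scene$arena_width_m / scene$image_width_px

  st <- NULL
  ctr <- c(scene$arena_width_m / 2, scene$arena_height_m / 2)
  servo <- servo_state(arena_to_gimbal(gimbal, ctr[1], ctr[2]), FALSE)
  rows <- vector("list", scene$n_frames)
  for (i in seq_len(scene$n_frames)) {
    idx <- i - 1L
    t_sim <- schedule$start_time_s + idx * dt_sim
    occ <- frame_occluded(scene, idx)
    fr <- render_frame(scene, traj[[i]]$pos, occluded = occ,
                       body_angle_rad = traj[[i]]$angle,
                       frame_index = idx, time_s = t_sim)
    st <- track_step(fr$frame, st, spec, tparams, frame_index = idx)

    if (!is.null(st$smoothed)) {
      xy <- apply_homography(cam$H, matrix(st$smoothed, 1, 2))
      target <- arena_to_gimbal(gimbal, xy[1], xy[2],
                                prev_pan_deg = servo$pose$pan_deg)
    } else {
      xy <- matrix(c(NA_real_, NA_real_), 1, 2)
      target <- servo$pose  # hold position while the target is absent
    }
    servo <- servo_step(gimbal, servo, target, dt_sim)
    light <- is_light_on(schedule, t_sim)
    laser_on <- light && !is.null(st$smoothed)
    servo$laser_on <- laser_on
    if (laser_on) {
      spot <- laser_spot(gimbal, servo$pose)
      err <- sqrt(sum((spot - traj[[i]]$pos)^2))
    } else {
      spot <- c(x_m = NA_real_, y_m = NA_real_)
      err <- NA_real_
    }
    rows[[i]] <- tibble(
      frame_index = idx, time_s = t_sim, found = st$found,
      smooth_u_px = if (is.null(st$smoothed)) NA_real_ else st$smoothed[1],
      smooth_v_px = if (is.null(st$smoothed)) NA_real_ else st$smoothed[2],
      x_m = xy[1], y_m = xy[2],
      pan_deg = servo$pose$pan_deg, tilt_deg = servo$pose$tilt_deg,
      laser_on = laser_on, spot_x_m = spot[["x_m"]], spot_y_m = spot[["y_m"]],
      error_m = err,
      on_target = laser_on && !occ && err <= marker_radius_m,
      truth_x_m = traj[[i]]$pos[1], truth_y_m = traj[[i]]$pos[2],
      occluded = occ, scheduled_on = light)
  }
  log <- dplyr::bind_rows(rows)
  eligible <- log$laser_on & !log$occluded
  metrics <- list(
    n_frames = nrow(log),
    frames_found = sum(log$found),
    frames_laser_on = sum(log$laser_on),
    on_target_fraction = if (any(eligible))
      sum(log$on_target[eligible]) / sum(eligible) else 0,
    mean_pointing_error_m = if (any(eligible))
      mean(log$error_m[eligible]) else NA_real_,
    max_pointing_error_m = if (any(eligible))
      max(log$error_m[eligible]) else NA_real_,
    marker_radius_m = marker_radius_m)
  structure(list(log = log, metrics = metrics, scene = scene,
                 gimbal = gimbal, schedule = schedule),
            class = "closed_loop")
}

#' @export
print.closed_loop <- function(x, ...) {
  m <- x$metrics
  cat("Closed-loop tracking-and-illumination run\n")
  cat(sprintf("  frames: %d (found %d, laser on %d)\n",
              m$n_frames, m$frames_found, m$frames_laser_on))
  cat(sprintf("  on-target fraction: %.3f (marker radius %.1f mm)\n",
              m$on_target_fraction, 1000 * m$marker_radius_m))
  if (is.finite(m$mean_pointing_error_m))
    cat(sprintf("  pointing error: mean %.2f mm, max %.2f mm\n",
                1000 * m$mean_pointing_error_m,
                1000 * m$max_pointing_error_m))
  invisible(x)
}

#' Tidy the per-frame log of a closed-loop run
#'
#' @param x A `closed_loop` object.
#' @param ... Unused.
#' @return The per-frame log tibble.
#' @method tidy closed_loop
#' @export
tidy.closed_loop <- function(x, ...) x$log

#' One-row summary of a closed-loop run
#'
#' @param x A `closed_loop` object.
#' @param ... Unused.
#' @return One-row tibble of the summary metrics.
#' @method glance closed_loop
#' @export
glance.closed_loop <- function(x, ...) as_tibble(x$metrics)

#' Plot a closed-loop run
#'
#' Ground-truth marker path with the laser spot positions coloured by
#' whether they fell within the marker radius.
#'
#' @param object A `closed_loop` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot closed_loop
#' @export
autoplot.closed_loop <- function(object, ...) {
  log <- object$log
  ggplot2::ggplot(log, ggplot2::aes(x = .data$truth_x_m, y = .data$truth_y_m)) +
    ggplot2::geom_path(colour = "grey40") +
    ggplot2::geom_point(
      data = log[log$laser_on, ],
      ggplot2::aes(x = .data$spot_x_m, y = .data$spot_y_m,
                   colour = .data$on_target), size = 0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac",
                                            `FALSE` = "#b2182b")) +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "on target",
                  title = "Marker path and laser spots")
}

#' Write the closed-loop per-frame log CSV
#'
#' Canonical columns: `frame_index,time_s,found,smooth_u_px,smooth_v_px,
#' x_m,y_m,pan_deg,tilt_deg,laser_on,spot_x_m,spot_y_m,error_m,on_target`.
#'
#' @param loop A `closed_loop` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_track_log <- function(loop, path) {
  cols <- c("frame_index", "time_s", "found", "smooth_u_px", "smooth_v_px",
            "x_m", "y_m", "pan_deg", "tilt_deg", "laser_on",
            "spot_x_m", "spot_y_m", "error_m", "on_target")
  write_csv_atomic(loop$log[, cols], path)
  invisible(path)
}

#' Write the closed-loop metrics JSON
#'
#' @param loop A `closed_loop` object.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_metrics_json <- function(loop, path) {
  write_json_atomic(loop$metrics, path)
  invisible(path)
}
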