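# JSON run configuration: defaults, validation with key-path reporting,
# and round-trippable serialisation.

default_config_list <- function() {
  list(
    seed = 1L,
    time_scale = 1,
    scene = list(
      arena_width_m = 0.20, arena_height_m = 0.20,
      image_width_px = 640L, image_height_px = 640L,
      background_gray = 20, body_axes_px = c(110, 55), body_gray = 110,
      marker_radius_px = 16, marker_rgb = c(200, 30, 30), noise_sigma = 2,
      occlusion_intervals = list(), fps = 20, n_frames = 200L, seed = 1L),
    motion = list(speed_scale_m_per_s = 0.05, relaxation_time_s = 1,
                  boundary_margin_m = 0.02),
    color = list(space = "HSV",
                 lower = rbind(c(0, 0.35, 0.15), c(335, 0.35, 0.15)),
                 upper = rbind(c(25, 1, 1), c(360, 1, 1))),
    tracker = list(opening_radius_px = 2L, min_blob_px = 10L,
                   max_jump_px = 50, ema_alpha = 0.5, hold_frames = 15L),
    camera = NULL,    # NULL -> exact scene camera
    gimbal = list(mount_x_m = 0.10, mount_y_m = 0.10, mount_z_m = 0.33,
                  pan_zero_deg = 0, max_slew_deg_per_s = 300,
                  pan_limits_deg = c(-180, 180), tilt_limits_deg = c(0, 60)),
    schedule = list(mode = "CONTINUOUS_ON", cycle_on_h = 12, cycle_off_h = 12,
                    phase_h = 0, irradiance_uW_cm2 = 100, start_time_s = 0))
}

# Overlay user values onto defaults, recursively for named lists.
merge_config <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults) || is.null(names(defaults))) return(user)
  for (nm in names(user)) {
    defaults[[nm]] <- if (nm %in% names(defaults) && is.list(defaults[[nm]]) &&
                          !is.null(names(defaults[[nm]])))
      merge_config(defaults[[nm]], user[[nm]]) else user[[nm]]
  }
  defaults
}

# Build the typed objects from a plain config list, collecting every
# invariant violation with its offending key path.
build_run_config <- function(cfg, base_dir = ".") {
  issues <- character()
  grab <- function(prefix, ctor, args) {
    tryCatch(do.call(ctor, args),
             error = function(e) {
               issues <<- c(issues, paste0(prefix, ": ", conditionMessage(e)))
               NULL
             })
  }
  scene_args <- cfg$scene
  oi <- scene_args$occlusion_intervals
  if (is.matrix(oi)) oi <- lapply(seq_len(nrow(oi)), function(i) oi[i, ])
  scene_args$occlusion_intervals <- lapply(oi, as.numeric)
  scene <- grab("scene", scene_config, scene_args)
  motion <- grab("motion", motion_params, cfg$motion)
  color_args <- cfg$color
  for (f in c("lower", "upper"))
    if (is.list(color_args[[f]]))
      color_args[[f]] <- do.call(rbind, lapply(color_args[[f]], as.numeric))
  color <- grab("color", color_spec, color_args)
  tracker <- grab("tracker", tracker_params, cfg$tracker)
  gimbal_args <- cfg$gimbal
  for (f in c("pan_limits_deg", "tilt_limits_deg"))
    gimbal_args[[f]] <- as.numeric(gimbal_args[[f]])
  gimbal <- grab("gimbal", gimbal_model, gimbal_args)
  schedule <- grab("schedule", light_schedule, cfg$schedule)

  camera <- NULL
  if (!is.null(cfg$camera)) {
    if (!is.null(cfg$camera$calibration_csv)) {
      path <- cfg$camera$calibration_csv
      if (!file.exists(path)) path <- file.path(base_dir, cfg$camera$calibration_csv)
      if (!file.exists(path)) {
        issues <- c(issues, paste0("camera.calibration_csv: file not found: ",
                                   cfg$camera$calibration_csv))
      } else {
        pts <- read_calibration_csv(path)
        camera <- grab("camera", calibrate_homography,
                       list(pixel_points = as.matrix(pts[, c("u_px", "v_px")]),
                            arena_points = as.matrix(pts[, c("x_m", "y_m")])))
      }
    } else if (!is.null(cfg$camera$homography)) {
      H <- cfg$camera$homography
      if (is.list(H)) H <- do.call(rbind, lapply(H, as.numeric))
      camera <- grab("camera.homography", camera_model,
                     list(H = matrix(as.numeric(t(H)), 3, 3, byrow = TRUE)))
    } else {
      issues <- c(issues,
                  "camera: must provide homography or calibration_csv (or null)")
    }
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    issues <- c(issues, "seed: must be a single integer")
  if (!is.numeric(cfg$time_scale) || cfg$time_scale <= 0)
    issues <- c(issues, "time_scale: must be a positive number")
  if (length(issues) > 0L)
    stop_invalid("invalid configuration:\n  ",
                 paste(issues, collapse = "\n  "))
  if (is.null(camera)) camera <- scene_camera(scene)
  structure(list(seed = as.integer(cfg$seed), time_scale = cfg$time_scale,
                 scene = scene, motion = motion, color = color,
                 tracker = tracker, camera = camera, gimbal = gimbal,
                 schedule = schedule),
            class = "run_config")
}

#' Load, default and validate a run configuration
#'
#' Reads a JSON configuration, fills unspecified fields with package
#' defaults, and validates every nested invariant; all violations are
#' reported together, each prefixed with the offending key path. A minimal
#' configuration (even `{}` or just a seed) yields a fully defaulted run.
#'
#' @param path JSON configuration path.
#' @return A `run_config` with constructed scene/motion/colour/tracker/
#'   camera/gimbal/schedule objects.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- merge_config(default_config_list(), user)
  # A scene-level seed follows the top-level one unless set explicitly.
  if (!is.null(user$seed) && is.null(user$scene$seed))
    cfg$scene$seed <- cfg$seed
  build_run_config(cfg, base_dir = dirname(path))
}

run_config_to_list <- function(config) {
  list(seed = config$seed, time_scale = config$time_scale,
       scene = unclass(config$scene),
       motion = unclass(config$motion),
       color = list(space = config$color$space,
                    lower = apply(config$color$lower, 1, identity,
                                  simplify = FALSE),
                    upper = apply(config$color$upper, 1, identity,
                                  simplify = FALSE)),
       tracker = unclass(config$tracker),
       camera = list(homography = lapply(1:3, function(i) config$camera$H[i, ])),
       gimbal = unclass(config$gimbal),
       schedule = unclass(config$schedule))
}

#' Save a run configuration to JSON
#'
#' Serialises a `run_config` so that [load_config()] reproduces an equal
#' configuration (the camera is stored as its homography rows).
#'
#' @param config A `run_config` from [load_config()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(config, path) {
  atomic_write(path, function(tmp) {
    jsonlite::write_json(run_config_to_list(config), tmp, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  })
  invisible(path)
}
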