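# Scheduler arithmetic, the rate-limited servo, and the closed loop.

test_that("light/dark cycle switches at the cycle boundaries", {
  s <- light_schedule("CYCLE", cycle_on_h = 12, cycle_off_h = 12)
  h <- 3600
  expect_true(is_light_on(s, 6 * h))
  expect_false(is_light_on(s, 18 * h))
  expect_true(is_light_on(s, 0))           # half-open: on at the on-start
  expect_false(is_light_on(s, 12 * h))     # off at the off-start
  expect_true(is_light_on(s, 24 * h))
  expect_true(all(is_light_on(light_schedule("CONTINUOUS_ON"),
                              c(0, 1, 1e6))))
  expect_false(any(is_light_on(light_schedule("OFF"), c(0, 1e6))))
  expect_error(is_light_on(light_schedule("OFF", start_time_s = 10), 5),
               "start")
})

test_that("phase shifts the cycle as specified", {
  s <- light_schedule("CYCLE", cycle_on_h = 12, cycle_off_h = 12, phase_h = 6)
  h <- 3600
  expect_false(is_light_on(s, 4 * h))   # still in the shifted dark tail
  expect_true(is_light_on(s, 7 * h))
})

test_that("continuous 100 uW/cm2 for 48 h delivers 17.28 J/cm2", {
  s <- light_schedule("CONTINUOUS_ON", irradiance_uW_cm2 = 100)
  expect_equal(cumulative_dose(s, 0, 48 * 3600), 17.28)
  expect_equal(cumulative_dose(light_schedule("OFF"), 0, 1e7), 0)
})

test_that("a 12/12 cycle delivers exactly half the continuous dose", {
  cyc <- light_schedule("CYCLE", irradiance_uW_cm2 = 100)
  con <- light_schedule("CONTINUOUS_ON", irradiance_uW_cm2 = 100)
  expect_identical(cumulative_dose(cyc, 0, 24 * 3600),
                   cumulative_dose(con, 0, 24 * 3600) / 2)
})

test_that("on-time over whole cycles is exactly n x cycle_on", {
  s <- light_schedule("CYCLE", cycle_on_h = 12, cycle_off_h = 12)
  period <- 24 * 3600
  for (n in c(1, 3, 10, 37)) {
    expect_identical(schedule_on_time(s, 0, n * period), n * 12 * 3600)
  }
})

test_that("dose is additive over arbitrary split points", {
  set.seed(51)
  s <- light_schedule("CYCLE", cycle_on_h = 5, cycle_off_h = 7, phase_h = 2)
  for (k in 1:20) {
    ts <- sort(runif(3, 0, 40 * 3600))
    whole <- cumulative_dose(s, ts[1], ts[3])
    split <- cumulative_dose(s, ts[1], ts[2]) + cumulative_dose(s, ts[2], ts[3])
    expect_equal(split, whole, tolerance = 1e-12)
  }
  expect_error(cumulative_dose(s, 10, 5), "reversed")
})

test_that("the servo is rate-limited and reaches close targets exactly", {
  g <- gimbal_model(max_slew_deg_per_s = 300)
  st <- servo_state(gimbal_pose(0, 10))
  # target equals pose: unchanged
  out <- servo_step(g, st, gimbal_pose(0, 10), 0.05)
  expect_equal(c(out$pose$pan_deg, out$pose$tilt_deg), c(0, 10))
  # 10 degree error within the 15 degree bound: reached exactly
  out <- servo_step(g, st, gimbal_pose(10, 10), 0.05)
  expect_equal(out$pose$pan_deg, 10)
  # 40 degree error: moves exactly 15 degrees
  out <- servo_step(g, st, gimbal_pose(40, 10), 0.05)
  expect_equal(out$pose$pan_deg, 15)
  expect_error(servo_step(g, st, gimbal_pose(0, 0), 0), "dt")
})

test_that("the servo takes the short way around the pan circle", {
  g <- gimbal_model(max_slew_deg_per_s = 300)
  st <- servo_state(gimbal_pose(170, 10))
  out <- servo_step(g, st, gimbal_pose(-170, 10), 0.05)  # 20 deg via +/-180
  expect_equal(out$pose$pan_deg, -175)
})

test_that("a fixed target is reached in the predicted number of steps", {
  g <- gimbal_model(max_slew_deg_per_s = 100)
  target <- gimbal_pose(90, 40)
  st <- servo_state(gimbal_pose(-30, 0))
  dt <- 0.05
  n_pred <- ceiling(max(abs(90 - (-30)), abs(40 - 0)) /
                    (g$max_slew_deg_per_s * dt))
  for (i in seq_len(n_pred)) st <- servo_step(g, st, target, dt)
  expect_equal(c(st$pose$pan_deg, st$pose$tilt_deg), c(90, 40))
})

test_that("a stationary marker is hit to within a pixel footprint", {
  sc <- test_scene(n_frames = 12L)
  loop <- run_closed_loop(sc, motion_params(speed_scale_m_per_s = 0),
                          gimbal = gimbal_model(max_slew_deg_per_s = 1e6))
  px_m <- sc$arena_width_m / sc$image_width_px
  expect_true(all(loop$log$error_m[-1] <= px_m))
  expect_equal(loop$metrics$on_target_fraction, 1)
})

test_that("an OFF schedule keeps the laser dark with zero on-target fraction", {
  sc <- test_scene(n_frames = 8L)
  loop <- run_closed_loop(sc, schedule = light_schedule("OFF"))
  expect_equal(loop$metrics$frames_laser_on, 0)
  expect_equal(loop$metrics$on_target_fraction, 0)
  expect_true(all(is.na(loop$log$spot_x_m)))
})

test_that("laser gating never fires when scheduled off or target absent", {
  # compress 5 simulated days into 100 frames and occlude past the hold
  sc <- test_scene(n_frames = 100L, seed = 3L,
                   occlusion_intervals = list(c(20, 45)))
  loop <- run_closed_loop(sc, tparams = tracker_params(hold_frames = 5),
                          schedule = light_schedule("CYCLE"),
                          time_scale = 4320 * 20)
  log <- loop$log
  expect_gt(sum(log$laser_on), 0)
  expect_false(any(log$laser_on & !log$scheduled_on))
  expect_false(any(log$laser_on & is.na(log$smooth_u_px)))
  # target reported absent after the hold expires inside the occlusion
  expect_true(any(is.na(log$smooth_u_px[21:45])))
})

test_that("closed-loop runs are deterministic given the scene seed", {
  sc <- test_scene(n_frames = 10L, noise_sigma = 2, seed = 17L)
  a <- run_closed_loop(sc)
  b <- run_closed_loop(sc)
  expect_identical(a$log, b$log)
  expect_identical(a$metrics, b$metrics)
})

test_that("inconsistent camera and scene geometry is refused", {
  sc <- test_scene()
  # camera that maps the frame onto a 2 m arena
  bad <- camera_model(diag(c(2 / 320, 2 / 320, 1)))
  expect_error(run_closed_loop(sc, cam = bad), "inconsistent")
})

test_that("tidy/glance/autoplot expose the run results", {
  sc <- test_scene(n_frames = 6L)
  loop <- run_closed_loop(sc)
  expect_s3_class(tidy(loop), "tbl_df")
  expect_equal(nrow(tidy(loop)), 6)
  g <- glance(loop)
  expect_equal(g$n_frames, 6)
  expect_true(g$mean_pointing_error_m <= g$max_pointing_error_m)
  expect_s3_class(autoplot(loop), "ggplot")
})
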