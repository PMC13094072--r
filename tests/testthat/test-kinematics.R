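test_that("joint angles reproduce constructed geometries and the atan2 oracle", {
  # collinear: CT angle 180; right angle: CT 90
  pos <- rbind(c(-1, 1), c(0, 0), c(1, 0), c(2, 0), c(2, -1))
  tr <- constant_track(pos)
  ja <- joint_angles(tr)
  expect_equal(ja$ct_angle[1], 180)
  expect_equal(ja$ft_angle[1], 90)

  pos2 <- rbind(c(-1, 1), c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  ja2 <- joint_angles(constant_track(pos2))
  expect_equal(ja2$ct_angle[1], 90)

  set.seed(101)
  for (i in 1:200) {
    fr <- random_frame()
    ja <- joint_angles(constant_track(fr$pos, n = 3))
    expect_lt(abs(ja$ct_angle[1] - oracle_angle(fr$pos[2, ], fr$pos[3, ], fr$pos[4, ])), 1e-9)
    expect_lt(abs(ja$ft_angle[1] - oracle_angle(fr$pos[3, ], fr$pos[4, ], fr$pos[5, ])), 1e-9)
    expect_lt(abs(ja$ct_angle[1] - fr$ct), 1e-9)
    expect_lt(abs(ja$ft_angle[1] - fr$ft), 1e-9)
  }
})

test_that("angles are invariant under rigid transforms, scaling and y-flip", {
  tr <- generate_strike_track(strike_scenario(noise_sd = 0.8, seed = 3))
  ja <- joint_angles(tr)
  xy <- tr$xy

  rot <- matrix(c(cos(0.7), sin(0.7), -sin(0.7), cos(0.7)), 2, 2)
  xy_t <- xy
  for (lm in 1:5) {
    xy_t[, lm, ] <- sweep(xy[, lm, ] %*% t(rot) * 2.5, 2, c(123, -77), "+")
  }
  ja_t <- joint_angles(make_track(xy_t, fps = tr$fps, scale = tr$scale))
  expect_equal(ja_t$ct_angle, ja$ct_angle, tolerance = 1e-10)
  expect_equal(ja_t$ft_angle, ja$ft_angle, tolerance = 1e-10)

  xy_f <- xy
  xy_f[, , 2] <- -xy_f[, , 2] # y-down vs y-up
  ja_f <- joint_angles(make_track(xy_f, fps = tr$fps, scale = tr$scale))
  expect_equal(ja_f$ct_angle, ja$ct_angle, tolerance = 1e-10)
})

test_that("coincident landmarks abort with a frame-indexed error", {
  pos <- rbind(c(-1, 1), c(0, 0), c(0, 0), c(2, 0), c(2, -1))
  expect_error(joint_angles(constant_track(pos)),
               regexp = "CT joint, frame 0",
               class = "mantisstrike_degenerate_geometry_error")
})

test_that("standardization is zero-based, signed and idempotent", {
  tr <- generate_strike_track(strike_scenario(
    ct_program = angle_program(closed = 20, plateau_frames = 5,
                               opening_duration = 0.0025, peak_omega = 209.43951),
    n_frames = 40, noise_sd = 0
  ))
  ja <- joint_angles(tr)
  s <- standardize_angles(ja)
  expect_identical(s$ct_std[1], 0)
  # after a 30-degree opening the standardized angle is +30
  i30 <- which.min(abs(ja$ct_angle - 50))
  expect_equal(s$ct_std[i30], ja$ct_angle[i30] - 20, tolerance = 1e-9)
  expect_gt(s$ct_std[i30], 29)
  # literal convention mirrors the sign
  lit <- standardize_angles(ja, convention = "literal")
  expect_equal(lit$ct_std, -s$ct_std)
  # idempotent
  expect_identical(standardize_angles(s), s)
  # constant series standardizes to all zeros
  cst <- standardize_angles(joint_angles(constant_track(
    rbind(c(-1, 1), c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  )))
  expect_equal(cst$ct_std, rep(0, 5))
})

test_that("angular velocity is exact on ramps and zero on constants", {
  # 10 deg/frame at 10,000 fps = 100,000 deg/s = 1745.329 rad/s
  n <- 31
  xy <- array(0, dim = c(n, 5, 2))
  th <- (0:(n - 1)) * 10 + 30
  xy[, 1, ] <- matrix(c(-5, 5), n, 2, byrow = TRUE)
  xy[, 2, ] <- matrix(c(-1, 0), n, 2, byrow = TRUE)
  xy[, 3, ] <- 0
  xy[, 4, 1] <- -cos(th * pi / 180) # interior CT angle = th while th <= 180
  xy[, 4, 2] <- sin(th * pi / 180)
  xy[, 5, ] <- xy[, 4, ] + matrix(c(0.5, 0.5), n, 2, byrow = TRUE)
  th_int <- ifelse(th <= 180, th, 360 - th) # arccos folds past 180
  tr <- make_track(xy, fps = 10000)
  ja <- joint_angles(tr)
  expect_equal(ja$ct_angle, th_int, tolerance = 1e-9)

  interior <- 3:13 # strictly inside the rising ramp for both methods
  for (m in c("central_difference", "savitzky_golay")) {
    av <- angular_velocity(ja, method = m)
    expect_equal(av$omega_ct[interior], rep(100000 * pi / 180, length(interior)),
                 tolerance = 1e-9)
  }

  cst <- joint_angles(constant_track(rbind(c(-1, 1), c(0, 0), c(1, 0), c(1, 1), c(0, 1))))
  expect_equal(angular_velocity(cst)$omega_ct, rep(0, 5))
  expect_error(angular_velocity(ja, window = 4), class = "mantisstrike_validation_error")
})

test_that("Savitzky-Golay beats central differences on noisy ramps", {
  set.seed(7)
  fps <- 10000
  slope_deg <- 2 # deg per frame
  true_omega <- slope_deg * fps * pi / 180
  mse <- c(savitzky_golay = 0, central_difference = 0)
  for (r in 1:40) {
    n <- 60
    xy <- array(0, dim = c(n, 5, 2))
    th <- 30 + (0:(n - 1)) * slope_deg + rnorm(n, sd = 0.3)
    xy[, 1, ] <- matrix(c(-5, 5), n, 2, byrow = TRUE)
    xy[, 2, ] <- matrix(c(-1, 0), n, 2, byrow = TRUE)
    xy[, 4, 1] <- -cos(th * pi / 180)
    xy[, 4, 2] <- sin(th * pi / 180)
    xy[, 5, ] <- xy[, 4, ] + matrix(c(0.5, 0.5), n, 2, byrow = TRUE)
    ja <- joint_angles(make_track(xy, fps = fps))
    for (m in names(mse)) {
      om <- angular_velocity(ja, method = m)$omega_ct[5:(n - 5)]
      mse[m] <- mse[m] + mean((om - true_omega)^2)
    }
  }
  expect_lte(mse[["savitzky_golay"]], mse[["central_difference"]])
})

test_that("tip speed follows v = omega r, scales with mm/px, needs a scale", {
  # pure rotation about the CT joint: omega = 450 rad/s, r = 11 mm
  fps <- 12000
  n <- 40
  omega <- 450
  r_px <- 1100 # 11 mm at 0.01 mm/px
  th <- (0:(n - 1)) * omega / fps
  xy <- array(0, dim = c(n, 5, 2))
  xy[, 1, ] <- matrix(c(-5, 5), n, 2, byrow = TRUE)
  xy[, 2, ] <- matrix(c(-10, 0), n, 2, byrow = TRUE)
  xy[, 4, ] <- matrix(c(3, 4), n, 2, byrow = TRUE)
  xy[, 5, 1] <- r_px * cos(th)
  xy[, 5, 2] <- r_px * sin(th)
  tr <- make_track(xy, fps = fps, scale = 0.01)
  v <- tip_speed(tr)
  # central differences see the chord speed r sin(omega dt)/dt
  expect_equal(v[5], 4.95, tolerance = 1e-3)
  expect_equal(v[5], 11e-3 * sin(omega / fps) * fps, tolerance = 1e-9)

  tr2 <- make_track(xy, fps = fps, scale = 0.02)
  expect_equal(tip_speed(tr2), 2 * v, tolerance = 1e-12)

  tr3 <- make_track(xy, fps = fps, scale = NA_real_)
  expect_error(tip_speed(tr3), class = "mantisstrike_configuration_error")

  still <- constant_track(rbind(c(-1, 1), c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(tip_speed(still), rep(0, 5))
})

test_that("segmentation finds the constructed plateau and rejects ramps", {
  sc <- strike_scenario(
    ct_program = angle_program(closed = 15, plateau_frames = 20,
                               opening_duration = 0.002, peak_omega = 300),
    n_frames = 80, noise_sd = 0
  )
  tr <- generate_strike_track(sc)
  ja <- joint_angles(tr)
  tip <- tip_speed(tr)
  ph <- segment_strike(ja, tip)
  expect_identical(ph$start_frame, 20L)
  expect_identical(ph$end_frame, attr(tr, "truth")$end_frame)
  expect_lt(ph$plateau[2], ph$start_frame)

  # monotonically increasing series with no closed plateau
  n <- 30
  xy <- array(0, dim = c(n, 5, 2))
  th <- 20 + (0:(n - 1)) * 4
  xy[, 1, ] <- matrix(c(-5, 5), n, 2, byrow = TRUE)
  xy[, 2, ] <- matrix(c(-1, 0), n, 2, byrow = TRUE)
  xy[, 4, 1] <- -cos(th * pi / 180)
  xy[, 4, 2] <- sin(th * pi / 180)
  xy[, 5, ] <- xy[, 4, ] + matrix(c(0.5, 0.5), n, 2, byrow = TRUE)
  mono <- joint_angles(make_track(xy, fps = 10000))
  expect_error(segment_strike(mono, rep(1, n)),
               class = "mantisstrike_segmentation_error")
})

test_that("summaries recover generator truth and scale with fps", {
  sc <- strike_scenario(noise_sd = 0)
  kin <- strike_kinematics(generate_strike_track(sc))
  truth <- attr(generate_strike_track(sc), "truth")
  expect_equal(kin$summary$peak_omega_ct, truth$peak_omega_ct, tolerance = 1e-6)
  expect_equal(kin$summary$sweep_duration, truth$sweep_duration, tolerance = 1e-9)
  expect_equal(kin$summary$peak_tip_speed, truth$peak_tip_speed, tolerance = 1e-6)

  # doubling fps with the same per-frame program halves the sweep duration
  prog_frames <- function(fps) {
    strike_scenario(fps = fps, n_frames = 120,
                    ct_program = angle_program(closed = 15, plateau_frames = 30,
                                               opening_duration = 240 / fps / 10,
                                               peak_omega = 300),
                    noise_sd = 0)
  }
  k1 <- strike_kinematics(generate_strike_track(prog_frames(10000)))
  k2 <- strike_kinematics(generate_strike_track(prog_frames(20000)))
  expect_equal(k1$summary$sweep_duration / 2, k2$summary$sweep_duration,
               tolerance = 1e-9)

  # per-frame table is labeled consistently
  expect_setequal(unique(kin$frames$phase), c("plateau", "sweep", "post"))
  expect_equal(sum(kin$frames$phase == "sweep"),
               kin$phases$end_frame - kin$phases$start_frame + 1L)
})
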