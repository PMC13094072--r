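test_that("static scenario yields constant landmarks and determinism holds", {
  sc <- strike_scenario(
    ct_program = angle_program(closed = 30, plateau_frames = 1, peak_omega = 0),
    ft_program = angle_program(closed = 90, plateau_frames = 1, peak_omega = 0),
    n_frames = 10, noise_sd = 0
  )
  tr <- generate_strike_track(sc)
  for (lm in dimnames(tr$xy)[[2]]) {
    expect_equal(max(apply(tr$xy[, lm, ], 2, function(v) diff(range(v)))), 0)
  }

  sc2 <- strike_scenario(noise_sd = 1.5, seed = 42)
  t1 <- generate_strike_track(sc2)
  t2 <- generate_strike_track(sc2)
  expect_identical(t1$xy, t2$xy)
  t3 <- generate_strike_track(strike_scenario(noise_sd = 1.5, seed = 43))
  expect_false(identical(t1$xy, t3$xy))
})

test_that("noise-free tracks invert to the generating angle program", {
  sc <- strike_scenario(
    ct_program = angle_program(closed = 15, plateau_frames = 20,
                               opening_duration = 0.002, peak_omega = 300),
    noise_sd = 0, n_frames = 80
  )
  tr <- generate_strike_track(sc)
  truth <- attr(tr, "truth")
  ja <- joint_angles(tr)
  expect_lt(max(abs(ja$ct_angle - truth$ct_angle_deg)), 1e-9)
  expect_lt(max(abs(ja$ft_angle - truth$ft_angle_deg)), 1e-9)
  # plateau then strictly monotonic opening, as programmed
  expect_true(all(diff(ja$ct_angle[1:20]) == 0))
  expect_true(all(diff(ja$ct_angle[20:44]) > 0))
})

test_that("strike scenarios validate their fields", {
  expect_error(strike_scenario(fps = 0), class = "mantisstrike_validation_error")
  expect_error(strike_scenario(n_frames = 2), class = "mantisstrike_validation_error")
  expect_error(strike_scenario(segment_lengths = c(coxa = -1, trochanter_femur = 2, tibia = 2)),
               class = "mantisstrike_validation_error")
  expect_error(angle_program(peak_omega = -1), class = "mantisstrike_validation_error")
  # plateau + opening frames must fit into the recording
  sc <- strike_scenario(n_frames = 30,
                        ct_program = angle_program(plateau_frames = 25,
                                                   opening_duration = 0.001,
                                                   peak_omega = 200))
  expect_error(generate_strike_track(sc), class = "mantisstrike_validation_error")
})

test_that("force traces match their scenario analytically", {
  flat <- generate_force_trace(force_scenario(pulse_peak = 0, noise_sd = 0,
                                              drift_rate = 0, baseline = 2))
  expect_equal(range(flat$f), c(2, 2))

  # grid aligned with the pulse apex: fs = 1000, onset 0.08, rise 0.004
  sc <- force_scenario(fs = 1000, baseline = 0, drift_rate = 0,
                       pulse_peak = 17.62, pulse_onset = 0.08,
                       pulse_rise = 0.004, noise_sd = 0)
  tr <- generate_force_trace(sc)
  expect_lt(abs(max(tr$f) - 17.62), 1e-9)

  sc_n <- force_scenario(noise_sd = 0.2, seed = 11)
  expect_identical(generate_force_trace(sc_n)$f, generate_force_trace(sc_n)$f)

  expect_error(force_scenario(pulse_onset = 0.19, pulse_rise = 0.02, duration = 0.2),
               class = "mantisstrike_validation_error")
})

test_that("model trials honor release force, stationarity and saturation", {
  sc <- model_trial_scenario(true_release_force = 18.63,
                             post_release_peak_speed = 0.2,
                             spring_saturation_force = 0.5)
  trial <- mantisstrike:::simulate_model_trial(sc)
  expect_identical(trial_max_force(trial), 18.63)

  still <- mantisstrike:::simulate_model_trial(
    model_trial_scenario(post_release_peak_speed = 0)
  )
  expect_equal(diff(range(still$track$x)), 0)
  expect_equal(diff(range(still$track$y)), 0)

  # saturation: extra tensile force above the spring saturation force does
  # not raise the post-release peak speed
  speeds <- vapply(c(5, 10, 20, 40), function(f) {
    t <- mantisstrike:::simulate_model_trial(model_trial_scenario(
      true_release_force = f, spring_saturation_force = 5,
      post_release_peak_speed = 0.3
    ))
    trial_max_velocity(t)
  }, numeric(1))
  expect_equal(speeds, rep(0.3, 4), tolerance = 1e-9)
  # below saturation the speed scales with stored force
  low <- mantisstrike:::simulate_model_trial(model_trial_scenario(
    true_release_force = 2.5, spring_saturation_force = 5,
    post_release_peak_speed = 0.3
  ))
  expect_equal(trial_max_velocity(low), 0.15, tolerance = 1e-9)
})

test_that("model studies reject duplicate trial keys and keep truth metadata", {
  d <- model_study_design(n_samples = 2, n_repeats = 2, seed = 5)
  expect_error(generate_model_study(list()), class = "mantisstrike_validation_error")
  dup <- c(d, d[1])
  expect_error(generate_model_study(dup), class = "mantisstrike_validation_error")
  st <- generate_model_study(d)
  expect_length(st, 2 * 2 * 2 * 2)
  expect_named(attr(st, "truth"), c("force_means", "speed_means",
                                    "sample_sd_log_force", "sample_sd_speed",
                                    "trial_sd_log_force", "trial_sd_speed"))
})

test_that("trace-level extraction reproduces the design's generative table", {
  d <- model_study_design(n_samples = 2, n_repeats = 3, seed = 21)
  got <- trial_summaries(generate_model_study(d))
  want <- design_trial_table(d)
  expect_equal(got$max_force, want$max_force, tolerance = 1e-12)
  expect_equal(got$max_velocity, want$max_velocity, tolerance = 1e-12)
})
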