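test_that("trial maxima are extracted exactly from constructed traces", {
  ramp <- list(force = list(t = seq(0, 2.3, by = 0.01),
                            f = c(seq(0, 22.38, length.out = 220), rep(0.1, 11))))
  expect_equal(trial_max_force(ramp), 22.38)

  flat <- list(force = list(t = 0:10 / 10, f = rep(0, 11)))
  expect_warning(f0 <- trial_max_force(flat), regexp = "no release")
  expect_equal(f0, 0)

  expect_error(trial_max_force(list(force = list(t = numeric(), f = numeric()))),
               class = "mantisstrike_validation_error")

  # point moving 0.205 mm/frame at 1000 fps is 0.205 m/s
  trial <- list(force = list(t = c(0, 0.01, 0.02), f = c(1, 2, 0.1)),
                track = list(t = 0:100 / 1000,
                             x = c(rep(0, 21), cumsum(rep(0.205 / 0.2, 80))),
                             y = rep(0, 101)),
                fps = 1000, scale = 0.2)
  expect_equal(trial_max_velocity(trial), 0.205, tolerance = 1e-12)

  gap <- trial
  gap$track$x[50] <- NA
  expect_error(trial_max_velocity(gap), class = "mantisstrike_validation_error")

  # synthetic trial: noise-free recovery of both programmed maxima
  sc <- model_trial_scenario(true_release_force = 18.63,
                             spring_saturation_force = 1,
                             post_release_peak_speed = 0.205)
  tr <- mantisstrike:::simulate_model_trial(sc)
  expect_equal(trial_max_force(tr), 18.63, tolerance = 1e-9)
  expect_equal(trial_max_velocity(tr), 0.205, tolerance = 1e-9)
})

test_that("mixed models validate their design", {
  d <- design_trial_table(model_study_design(n_samples = 2, n_repeats = 2, seed = 1))
  expect_error(fit_trial_models(d[d$friction == "H", ]),
               class = "mantisstrike_validation_error")
  expect_error(fit_trial_models(d[!(d$type == "atrS" & d$friction == "L"), ]),
               regexp = "atrS", class = "mantisstrike_validation_error")
  one_sample <- d[d$sample %in% c("atrH1", "atrS1", "atrS2"), ]
  expect_error(fit_trial_models(one_sample), class = "mantisstrike_validation_error")
})

test_that("identical responses give null estimates and no significance", {
  d <- design_trial_table(model_study_design(n_samples = 2, n_repeats = 3, seed = 2))
  d$max_force <- 2
  d$max_velocity <- 0.1
  fit <- fit_trial_models(d)
  for (resp in c("force", "velocity")) {
    est <- fit[[resp]]$coefficients$estimate[-1] # beyond the intercept
    expect_equal(est, rep(0, 3), tolerance = 1e-8)
    expect_false(any(fit[[resp]]$contrasts$p.value < 0.05, na.rm = TRUE))
  }
  expect_equal(nrow(fit$force$emmeans), 4)
})

test_that("zero random-intercept variance reduces to the ordinary two-way fit", {
  d <- design_trial_table(model_study_design(
    n_samples = 3, n_repeats = 4, sample_sd_log_force = 0, sample_sd_speed = 0,
    seed = 8
  ))
  fit <- suppressWarnings(suppressMessages(fit_trial_models(d)))
  for (resp in c("force", "velocity")) {
    y <- if (resp == "force") log(d$max_force) else d$max_velocity
    dd <- data.frame(y = y, type = factor(d$type), friction = factor(d$friction))
    contrasts(dd$type) <- contr.sum(2)
    contrasts(dd$friction) <- contr.sum(2)
    ols <- lm(y ~ type * friction, data = dd)
    expect_equal(fit[[resp]]$coefficients$estimate, unname(coef(ols)),
                 tolerance = 1e-6)
  }
})

test_that("type III tests are invariant to factor-level ordering", {
  d <- design_trial_table(model_study_design(n_samples = 3, n_repeats = 4, seed = 12))
  f1 <- fit_trial_models(d)
  d2 <- d[rev(seq_len(nrow(d))), ]
  d2$type <- factor(d2$type, levels = c("atrS", "atrH"))
  d2$friction <- factor(d2$friction, levels = c("L", "H"))
  f2 <- fit_trial_models(d2)
  expect_equal(f1$force$anova$f_value, f2$force$anova$f_value, tolerance = 1e-8)
  expect_equal(f1$velocity$anova$p_value, f2$velocity$anova$p_value, tolerance = 1e-8)
})

test_that("adding a constant to velocities shifts only the intercept", {
  d <- design_trial_table(model_study_design(n_samples = 3, n_repeats = 4, seed = 13))
  f1 <- fit_trial_models(d)
  d$max_velocity <- d$max_velocity + 5
  f2 <- fit_trial_models(d)
  expect_equal(f2$velocity$coefficients$estimate[1],
               f1$velocity$coefficients$estimate[1] + 5, tolerance = 1e-6)
  expect_equal(f2$velocity$coefficients$estimate[-1],
               f1$velocity$coefficients$estimate[-1], tolerance = 1e-6)
  expect_equal(f2$velocity$contrasts$estimate, f1$velocity$contrasts$estimate,
               tolerance = 1e-6)
})

test_that("the fitted study mirrors the type-specific friction finding", {
  st <- generate_model_study(model_study_design(seed = 3))
  res <- run_model_experiment(st)
  fit <- res$models
  # force: strong friction main effect for both types
  an_f <- fit$force$anova
  expect_lt(an_f$p_value[an_f$term == "friction"], 0.001)
  # velocity: significant interaction; H vs L significant within atrS only
  an_v <- fit$velocity$anova
  expect_lt(an_v$p_value[an_v$term == "type:friction"], 0.001)
  ctr <- fit$velocity$contrasts
  expect_lt(ctr$p.value[ctr$type == "atrS"], 0.05)
  expect_gt(ctr$p.value[ctr$type == "atrH"], 0.05)
})

test_that("model reports render and round-trip through CSV", {
  d <- design_trial_table(model_study_design(n_samples = 2, n_repeats = 3, seed = 4))
  fit <- fit_trial_models(d)
  out <- withr::local_tempdir()
  tabs <- model_report(fit, out)
  expect_true(file.exists(file.path(out, "force_anova.csv")))
  expect_true(file.exists(file.path(out, "report.txt")))
  back <- read.csv(file.path(out, "velocity_contrasts.csv"))
  expect_equal(back$estimate, fit$velocity$contrasts$estimate, tolerance = 1e-12)
  # p-values in the text report use fixed decimal formatting
  rep_txt <- readLines(file.path(out, "report.txt"))
  expect_false(any(grepl("e-", grep("p = ", rep_txt, value = TRUE))))
  expect_error(model_report(list(), out), class = "mantisstrike_validation_error")
})
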