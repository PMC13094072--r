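## Synthetic-data generators: landmark tracks, force traces and
## physical-model trial studies with fully known ground truth. These define
## the study conditions used throughout the test suite; every generator is a
## pure function of its scenario (seeds are explicit fields, never global
## state).

#' Piecewise joint-angle program
#'
#' Describes the trajectory of one joint angle over a recording: a closed
#' plateau at a constant angle, followed by an opening ramp at constant
#' angular velocity, followed by a hold at the opened angle. The constant-rate
#' ramp makes the discrete ground truth exactly recoverable by finite
#' differences, which is what makes noise-free parameter-recovery tests sharp.
#'
#' @param closed plateau (closed-joint) angle in degrees.
#' @param plateau_frames number of frames spent at the closed angle before the
#'   joint starts to open.
#' @param opening_duration duration of the opening ramp in seconds.
#' @param peak_omega angular velocity of the ramp in rad/s (>= 0; 0 keeps the
#'   joint at the closed angle for the whole recording).
#' @return an object of class `angle_program`.
#' @export
angle_program <- function(closed = 15, plateau_frames = 40,
                          opening_duration = 0.0016, peak_omega = 450) {
  check_number(closed, "closed", lower = 0)
  if (closed >= 180) stop_validation("'closed' must be < 180 degrees")
  check_number(plateau_frames, "plateau_frames", lower = 1)
  check_number(opening_duration, "opening_duration", lower = 0, strict = TRUE)
  check_number(peak_omega, "peak_omega", lower = 0)
  structure(
    list(closed = closed, plateau_frames = as.integer(plateau_frames),
         opening_duration = opening_duration, peak_omega = peak_omega),
    class = "angle_program"
  )
}

# Evaluate an angle program on a frame grid. Frames 0..p-1 sit at the closed
# angle; frames p..p+m-1 ramp at peak_omega; later frames hold. Returns the
# series in degrees plus the ramp bookkeeping used as ground truth.
angle_program_series <- function(program, fps, n_frames) {
  p <- program$plateau_frames
  dt <- 1 / fps
  m <- if (program$peak_omega > 0) max(1L, as.integer(round(program$opening_duration * fps))) else 0L
  if (p + m > n_frames) {
    stop_validation(sprintf(
      "angle program needs %d plateau + %d opening frames but n_frames = %d",
      p, m, n_frames
    ))
  }
  step_deg <- rad2deg(program$peak_omega * dt)
  i <- seq_len(n_frames) - 1L # 0-based frame index
  ramp <- pmax(0, pmin(i - p + 1L, m))
  theta <- program$closed + step_deg * ramp
  if (max(theta) >= 180) {
    stop_validation(sprintf(
      "angle program opens past 180 degrees (reaches %.1f); shorten the ramp",
      max(theta)
    ))
  }
  list(theta_deg = theta, ramp_frames = m, step_deg = step_deg)
}

#' Synthetic strike scenario
#'
#' Ground-truth description of one impaling strike as seen by a high-speed
#' camera: planar forward kinematics of a three-segment foreleg (coxa,
#' trochanter-femur, tibia) driven by coxa-trochanter (CT) and femur-tibia
#' (FT) angle programs, observed as five tracked landmarks in image-style
#' (y-down) pixel coordinates with i.i.d. Gaussian landmark noise.
#'
#' Defaults emulate the recording conditions of the study system: 12,000 fps,
#' a closed CT plateau followed by a ~1.6 ms sweep at ~450 rad/s, and segment
#' lengths giving a joint-to-tip distance of ~11 mm (so a tip speed near
#' 5 m/s).
#'
#' @param fps frames per second of the emulated recording (> 0).
#' @param n_frames number of frames (>= 3).
#' @param scale mm per pixel (> 0).
#' @param segment_lengths named numeric: lengths in mm of `coxa`,
#'   `trochanter_femur` and `tibia` segments (> 0).
#' @param ct_program,ft_program [angle_program()] objects for the CT and FT
#'   joints.
#' @param noise_sd standard deviation of the Gaussian landmark noise, pixels.
#' @param seed integer seed; identical scenarios produce identical tracks.
#' @return an object of class `strike_scenario`.
#' @export
strike_scenario <- function(fps = 12000, n_frames = 120, scale = 0.01,
                            segment_lengths = c(coxa = 4, trochanter_femur = 8,
                                                tibia = 7.5),
                            ct_program = angle_program(),
                            ft_program = angle_program(closed = 90,
                                                       plateau_frames = 1,
                                                       peak_omega = 0),
                            noise_sd = 0, seed = 1L) {
  check_number(fps, "fps", lower = 0, strict = TRUE)
  check_number(n_frames, "n_frames", lower = 3)
  check_number(scale, "scale", lower = 0, strict = TRUE)
  need <- c("coxa", "trochanter_femur", "tibia")
  if (!is.numeric(segment_lengths) || !all(need %in% names(segment_lengths))) {
    stop_validation("'segment_lengths' must be named numeric with coxa, trochanter_femur, tibia")
  }
  check_number(unname(segment_lengths[need]), "segment_lengths", lower = 0,
               strict = TRUE, len = 3L)
  if (!inherits(ct_program, "angle_program") || !inherits(ft_program, "angle_program")) {
    stop_validation("'ct_program' and 'ft_program' must be angle_program objects")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(seed, "seed")
  structure(
    list(fps = fps, n_frames = as.integer(n_frames), scale = scale,
         segment_lengths = segment_lengths[need], ct_program = ct_program,
         ft_program = ft_program, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "strike_scenario"
  )
}

#' Generate a five-landmark strike track with known ground truth
#'
#' Places the five landmarks by planar forward kinematics: body and coxal
#' base are fixed; the CT joint sits at the end of the coxa segment; the FT
#' joint and tarsus base are placed so the interior angles at the CT and FT
#' joints follow the scenario's angle programs exactly. Coordinates are
#' converted to y-down pixel coordinates (tracker-export convention) and
#' Gaussian noise of sd `noise_sd` pixels is added to every coordinate.
#'
#' The returned track carries a `truth` attribute with the generating angle
#' series and the discrete-ground-truth strike summary: 0-based start and end
#' frames, sweep duration, peak CT angular velocity, and the peak tip speed
#' as observed by central differencing of the noiseless tip path (the chord
#' speed `R * sin(omega * dt) / dt`, with `R` the CT-joint-to-tarsus distance).
#'
#' @param scenario a [strike_scenario()].
#' @return a `landmark_track` (see [landmark_track()]) with attributes
#'   `truth` and `scenario`.
#' @export
generate_strike_track <- function(scenario) {
  if (!inherits(scenario, "strike_scenario")) {
    stop_validation("'scenario' must be a strike_scenario")
  }
  n <- scenario$n_frames
  fps <- scenario$fps
  dt <- 1 / fps
  L <- scenario$segment_lengths

  ct <- angle_program_series(scenario$ct_program, fps, n)
  ft <- angle_program_series(scenario$ft_program, fps, n)

  # Fixed points (mm, mathematical y-up frame).
  body <- c(-3, 2.5)
  coxal_base <- c(0, 0)
  coxa_dir <- deg2rad(-35) # arbitrary fixed coxa orientation
  ct_joint <- coxal_base + L[["coxa"]] * c(cos(coxa_dir), sin(coxa_dir))

  # Unit vector from ct_joint back to the coxal base; the trochanter-femur
  # segment makes the interior CT angle with it (opening rotates +).
  u_back <- (coxal_base - ct_joint) / L[["coxa"]]
  th_ct <- deg2rad(ct$theta_deg)
  ft_xy <- cbind(ct_joint[1] + L[["trochanter_femur"]] *
                   (u_back[1] * cos(th_ct) - u_back[2] * sin(th_ct)),
                 ct_joint[2] + L[["trochanter_femur"]] *
                   (u_back[1] * sin(th_ct) + u_back[2] * cos(th_ct)))
  # Tibia folds the other way: interior FT angle measured from the vector
  # ft_joint -> ct_joint, rotated by -theta_ft.
  v_back_x <- (ct_joint[1] - ft_xy[, 1]) / L[["trochanter_femur"]]
  v_back_y <- (ct_joint[2] - ft_xy[, 2]) / L[["trochanter_femur"]]
  th_ft <- deg2rad(ft$theta_deg)
  tarsus_xy <- cbind(ft_xy[, 1] + L[["tibia"]] *
                       (v_back_x * cos(th_ft) + v_back_y * sin(th_ft)),
                     ft_xy[, 2] + L[["tibia"]] *
                       (-v_back_x * sin(th_ft) + v_back_y * cos(th_ft)))

  xy <- array(NA_real_, dim = c(n, 5L, 2L),
              dimnames = list(NULL, LANDMARK_NAMES, c("x", "y")))
  xy[, "body", ] <- matrix(body, n, 2, byrow = TRUE)
  xy[, "coxal_base", ] <- matrix(coxal_base, n, 2, byrow = TRUE)
  xy[, "ct_joint", ] <- matrix(ct_joint, n, 2, byrow = TRUE)
  xy[, "ft_joint", ] <- ft_xy
  xy[, "tarsus_base", ] <- tarsus_xy

  # mm -> pixels, then flip to image-style y-down coordinates.
  xy <- xy / scenario$scale
  xy[, , 2] <- 2000 - xy[, , 2]

  if (scenario$noise_sd > 0) {
    noise <- withr::with_seed(
      scenario$seed,
      array(rnorm(length(xy), sd = scenario$noise_sd), dim = dim(xy))
    )
    xy <- xy + noise
  }

  track <- landmark_track(xy, fps = fps, scale = scenario$scale)

  p <- scenario$ct_program$plateau_frames
  m <- ct$ramp_frames
  omega <- scenario$ct_program$peak_omega
  ft_static <- scenario$ft_program$peak_omega == 0
  peak_tip <- if (ft_static && omega > 0) {
    phi <- deg2rad(scenario$ft_program$closed)
    r_mm <- sqrt(L[["trochanter_femur"]]^2 + L[["tibia"]]^2 -
                   2 * L[["trochanter_femur"]] * L[["tibia"]] * cos(phi))
    r_mm * sin(omega * dt) / dt / 1000
  } else if (omega == 0) 0 else NA_real_

  attr(track, "truth") <- list(
    ct_angle_deg = ct$theta_deg, ft_angle_deg = ft$theta_deg,
    start_frame = if (omega > 0) p else NA_integer_,
    end_frame = if (omega > 0) p + m else NA_integer_,
    sweep_duration = if (omega > 0) m / fps else NA_real_,
    peak_omega_ct = omega, peak_tip_speed = peak_tip
  )
  attr(track, "scenario") <- scenario
  track
}

#' Synthetic force-trace scenario
#'
#' One strike on a force transducer: baseline plus linear drift plus an
#' asymmetric pulse (linear rise to `pulse_peak`, then exponential decay)
#' plus Gaussian sampling noise. The analytic pulse maximum equals
#' `pulse_peak` and is hit exactly when `pulse_onset + pulse_rise` falls on
#' the sample grid.
#'
#' @param fs sampling rate, Hz (> 0).
#' @param duration trace duration, s.
#' @param baseline baseline force, mN.
#' @param drift_rate linear baseline drift, mN/s.
#' @param pulse_peak pulse amplitude above baseline+drift, mN (>= 0).
#' @param pulse_onset pulse start time, s.
#' @param pulse_rise rise time to the peak, s.
#' @param pulse_decay exponential decay time constant, s.
#' @param noise_sd Gaussian noise sd, mN.
#' @param seed integer seed.
#' @return an object of class `force_scenario`.
#' @export
force_scenario <- function(fs = 10000, duration = 0.2, baseline = 0,
                           drift_rate = 0, pulse_peak = 17.62,
                           pulse_onset = 0.08, pulse_rise = 0.004,
                           pulse_decay = 0.012, noise_sd = 0, seed = 1L) {
  check_number(fs, "fs", lower = 0, strict = TRUE)
  check_number(duration, "duration", lower = 0, strict = TRUE)
  check_number(baseline, "baseline")
  check_number(drift_rate, "drift_rate")
  check_number(pulse_peak, "pulse_peak", lower = 0)
  check_number(pulse_onset, "pulse_onset", lower = 0)
  check_number(pulse_rise, "pulse_rise", lower = 0, strict = TRUE)
  check_number(pulse_decay, "pulse_decay", lower = 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(seed, "seed")
  if (pulse_onset + pulse_rise >= duration) {
    stop_validation("'pulse_onset' + 'pulse_rise' must be < 'duration'")
  }
  structure(
    list(fs = fs, duration = duration, baseline = baseline,
         drift_rate = drift_rate, pulse_peak = pulse_peak,
         pulse_onset = pulse_onset, pulse_rise = pulse_rise,
         pulse_decay = pulse_decay, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "force_scenario"
  )
}

#' Generate a synthetic force trace
#'
#' @param scenario a [force_scenario()].
#' @return a `force_trace` (see [force_trace()]) with attribute `scenario`.
#' @export
generate_force_trace <- function(scenario) {
  if (!inherits(scenario, "force_scenario")) {
    stop_validation("'scenario' must be a force_scenario")
  }
  n <- as.integer(floor(scenario$duration * scenario$fs)) + 1L
  t <- (seq_len(n) - 1L) / scenario$fs
  t_peak <- scenario$pulse_onset + scenario$pulse_rise
  pulse <- numeric(n)
  rising <- t >= scenario$pulse_onset & t <= t_peak
  pulse[rising] <- scenario$pulse_peak *
    (t[rising] - scenario$pulse_onset) / scenario$pulse_rise
  decaying <- t > t_peak
  pulse[decaying] <- scenario$pulse_peak *
    exp(-(t[decaying] - t_peak) / scenario$pulse_decay)
  f <- scenario$baseline + scenario$drift_rate * t + pulse
  if (scenario$noise_sd > 0) {
    f <- f + withr::with_seed(scenario$seed, rnorm(n, sd = scenario$noise_sd))
  }
  trace <- force_trace(t, f, fs = scenario$fs)
  attr(trace, "scenario") <- scenario
  trace
}

#' Physical-model trial scenario
#'
#' Ground truth for one tensile test of an artificial trochanter: a tensile
#' ramp (nominal pull rate 10 mm/s) up to `true_release_force`, release, and
#' a post-release swing of the tracked point whose peak frame-to-frame speed
#' equals `post_release_peak_speed` scaled by the spring-saturation factor
#' `min(F, F_sat) / F_sat` — tensile force beyond the saturation force cannot
#' be stored in the spring and does not raise the speed.
#'
#' @param type artificial trochanter type: `"atrH"` (stiff) or `"atrS"`
#'   (flexible, double-spiral-bearing).
#' @param friction latch friction scenario, `"H"` (high) or `"L"` (low).
#' @param sample_id label of the physical sample.
#' @param rep_id repeat index within sample (integer).
#' @param true_release_force tensile force at release, N (>= 0).
#' @param spring_saturation_force force at which the spring saturates, N
#'   (> 0).
#' @param post_release_peak_speed programmed peak speed at/above saturation,
#'   m/s (>= 0).
#' @param fps video frame rate of the emulated trial recording (default 1000).
#' @param stiffness tensile stiffness of the loaded system, N/mm; with the
#'   10 mm/s pull rate this sets the ramp duration.
#' @param force_noise_sd Gaussian noise on the force samples, N.
#' @param track_noise_sd Gaussian noise on the tracked coordinates, pixels.
#' @param scale mm per pixel of the trial video.
#' @param seed integer seed.
#' @return an object of class `model_trial_scenario`.
#' @export
model_trial_scenario <- function(type = c("atrH", "atrS"),
                                 friction = c("H", "L"),
                                 sample_id = "s1", rep_id = 1L,
                                 true_release_force = 20,
                                 spring_saturation_force = 0.25,
                                 post_release_peak_speed = 0.1,
                                 fps = 1000, stiffness = 2,
                                 force_noise_sd = 0, track_noise_sd = 0,
                                 scale = 0.2, seed = 1L) {
  type <- match.arg(type)
  friction <- match.arg(friction)
  check_number(true_release_force, "true_release_force", lower = 0)
  check_number(spring_saturation_force, "spring_saturation_force", lower = 0,
               strict = TRUE)
  check_number(post_release_peak_speed, "post_release_peak_speed", lower = 0)
  check_number(fps, "fps", lower = 0, strict = TRUE)
  check_number(stiffness, "stiffness", lower = 0, strict = TRUE)
  check_number(force_noise_sd, "force_noise_sd", lower = 0)
  check_number(track_noise_sd, "track_noise_sd", lower = 0)
  check_number(scale, "scale", lower = 0, strict = TRUE)
  check_number(seed, "seed")
  structure(
    list(type = type, friction = friction, sample_id = as.character(sample_id),
         rep_id = as.integer(rep_id),
         true_release_force = true_release_force,
         spring_saturation_force = spring_saturation_force,
         post_release_peak_speed = post_release_peak_speed,
         fps = fps, stiffness = stiffness, force_noise_sd = force_noise_sd,
         track_noise_sd = track_noise_sd, scale = scale,
         seed = as.integer(seed)),
    class = "model_trial_scenario"
  )
}

# Realized post-release peak speed under spring saturation.
saturated_speed <- function(scenario) {
  scenario$post_release_peak_speed *
    min(scenario$true_release_force, scenario$spring_saturation_force) /
    scenario$spring_saturation_force
}

# Simulate a single physical-model trial from its scenario.
simulate_model_trial <- function(scenario) {
  fps <- scenario$fps
  dt <- 1 / fps
  pull_rate_mm_s <- 10 # constant crosshead rate of the tensile protocol

  # Tensile ramp: force = stiffness * displacement, displacement = rate * t.
  ramp_rate <- scenario$stiffness * pull_rate_mm_s # N/s
  t_release <- if (scenario$true_release_force > 0) {
    scenario$true_release_force / ramp_rate
  } else 0.2
  fs_force <- 200
  n_ramp <- as.integer(floor(t_release * fs_force)) + 1L
  t_ramp <- (seq_len(n_ramp) - 1L) / fs_force
  if (t_ramp[n_ramp] >= t_release) { # keep time strictly increasing
    t_ramp <- t_ramp[-n_ramp]
  }
  t_f <- c(t_ramp, t_release, t_release + (seq_len(20) / fs_force))
  f <- c(ramp_rate * t_ramp, scenario$true_release_force, rep(0, 20))
  if (scenario$force_noise_sd > 0) {
    f <- f + withr::with_seed(scenario$seed,
                              rnorm(length(f), sd = scenario$force_noise_sd))
  }

  # Tracked point: stationary until release, then a triangular speed profile
  # peaking exactly at the saturated speed (frame-to-frame displacement).
  n_pre <- as.integer(round(t_release * fps))
  speed <- saturated_speed(scenario) # m/s
  profile <- c(seq(0.25, 1, length.out = 4), seq(0.9, 0, length.out = 10))
  steps_m <- c(rep(0, n_pre), speed * profile * dt, rep(0, 10))
  x_px <- cumsum(c(0, steps_m)) * 1000 / scenario$scale # m -> mm -> px
  y_px <- rep(300, length(x_px))
  if (scenario$track_noise_sd > 0) {
    noise <- withr::with_seed(scenario$seed + 1L,
                              rnorm(2 * length(x_px),
                                    sd = scenario$track_noise_sd))
    x_px <- x_px + noise[seq_along(x_px)]
    y_px <- y_px + noise[-seq_along(x_px)]
  }

  structure(
    list(type = scenario$type, friction = scenario$friction,
         sample_id = scenario$sample_id, rep_id = scenario$rep_id,
         force = list(t = t_f, f = f),
         track = list(t = (seq_along(x_px) - 1L) / fps, x = x_px, y = y_px),
         fps = fps, scale = scenario$scale,
         truth = list(release_force = scenario$true_release_force,
                      peak_speed = speed, release_frame = n_pre)),
    class = "model_trial"
  )
}

#' Design a factorial physical-model study
#'
#' Builds the trial scenarios of a full type x friction study with
#' `n_samples` physical samples per trochanter type (each sample tested under
#' both friction scenarios) and `n_repeats` repeats per sample x friction
#' cell. Gaussian per-sample random intercepts are injected on log release
#' force (sd `sample_sd_log_force`) and on peak speed (sd `sample_sd_speed`),
#' matching the random-intercept structure of the mixed-effects analysis.
#'
#' Default cell means are at the magnitudes observed for the physical model:
#' high friction stores far more energy (release forces of tens of newtons
#' versus fractions of a newton at low friction), and only the flexible,
#' spring-bearing trochanter converts high-friction loading into a clearly
#' higher post-release speed.
#'
#' @param n_samples physical samples per type.
#' @param n_repeats repeats per sample and friction scenario.
#' @param force_means named numeric of cell mean release forces (N); names
#'   `atrH.H`, `atrS.H`, `atrH.L`, `atrS.L`.
#' @param speed_means named numeric of cell mean peak speeds (m/s), same
#'   names.
#' @param sample_sd_log_force sd of per-sample intercepts on log force.
#' @param sample_sd_speed sd of per-sample intercepts on speed, m/s.
#' @param trial_sd_log_force trial-to-trial sd on log force.
#' @param trial_sd_speed trial-to-trial sd on speed, m/s.
#' @param spring_saturation_force saturation force passed to each scenario, N.
#' @param seed integer seed.
#' @return list of [model_trial_scenario()] objects with attribute `truth`
#'   (the generative cell means and variance components).
#' @export
model_study_design <- function(n_samples = 4, n_repeats = 8,
                               force_means = c(atrH.H = 22.38, atrS.H = 18.63,
                                               atrH.L = 0.55, atrS.L = 0.39),
                               speed_means = c(atrH.H = 0.078, atrS.H = 0.205,
                                               atrH.L = 0.072, atrS.L = 0.056),
                               sample_sd_log_force = 0.15,
                               sample_sd_speed = 0.01,
                               trial_sd_log_force = 0.1,
                               trial_sd_speed = 0.02,
                               spring_saturation_force = 0.1,
                               seed = 1L) {
  check_number(n_samples, "n_samples", lower = 1)
  check_number(n_repeats, "n_repeats", lower = 1)
  cells <- c("atrH.H", "atrS.H", "atrH.L", "atrS.L")
  if (!all(cells %in% names(force_means)) || !all(cells %in% names(speed_means))) {
    stop_validation("'force_means' and 'speed_means' must name all four type.friction cells")
  }
  check_number(seed, "seed")

  samples <- data.frame(
    type = rep(c("atrH", "atrS"), each = n_samples),
    sample_id = c(paste0("atrH", seq_len(n_samples)),
                  paste0("atrS", seq_len(n_samples)))
  )
  withr::with_seed(seed, {
    b_force <- rnorm(nrow(samples), sd = sample_sd_log_force)
    b_speed <- rnorm(nrow(samples), sd = sample_sd_speed)
    design <- list()
    k <- 0L
    for (s in seq_len(nrow(samples))) {
      for (fr in c("H", "L")) {
        cell <- paste(samples$type[s], fr, sep = ".")
        for (r in seq_len(n_repeats)) {
          k <- k + 1L
          f_true <- exp(log(force_means[[cell]]) + b_force[s] +
                          rnorm(1, sd = trial_sd_log_force))
          v_true <- max(0, speed_means[[cell]] + b_speed[s] +
                          rnorm(1, sd = trial_sd_speed))
          design[[k]] <- model_trial_scenario(
            type = samples$type[s], friction = fr,
            sample_id = samples$sample_id[s], rep_id = r,
            true_release_force = f_true,
            # saturation far below the realized forces: the programmed speed
            # is realized exactly and speed differences come from v_true
            spring_saturation_force = spring_saturation_force,
            post_release_peak_speed = v_true,
            seed = seed + 13L * k
          )
        }
      }
    }
    design
  }) -> design
  attr(design, "truth") <- list(
    force_means = force_means, speed_means = speed_means,
    sample_sd_log_force = sample_sd_log_force,
    sample_sd_speed = sample_sd_speed,
    trial_sd_log_force = trial_sd_log_force,
    trial_sd_speed = trial_sd_speed
  )
  design
}

#' Simulate a physical-model study
#'
#' @param design non-empty list of [model_trial_scenario()] objects, e.g.
#'   from [model_study_design()]; duplicate (sample, repeat, friction) keys
#'   are an error.
#' @return list of `model_trial` objects (class `model_study`), carrying the
#'   design's `truth` attribute through.
#' @export
generate_model_study <- function(design) {
  if (!is.list(design) || length(design) == 0) {
    stop_validation("'design' must be a non-empty list of model_trial_scenario objects")
  }
  ok <- vapply(design, inherits, logical(1), "model_trial_scenario")
  if (!all(ok)) stop_validation("all design entries must be model_trial_scenario objects")
  keys <- vapply(design, function(s) {
    paste(s$sample_id, s$friction, s$rep_id, sep = "|")
  }, character(1))
  if (anyDuplicated(keys)) {
    stop_validation(sprintf("duplicate (sample, friction, repeat) keys: %s",
                            paste(unique(keys[duplicated(keys)]), collapse = ", ")))
  }
  trials <- lapply(design, simulate_model_trial)
  attr(trials, "truth") <- attr(design, "truth")
  class(trials) <- "model_study"
  trials
}
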