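## End-to-end orchestration: strike pipeline (tracks + force traces ->
## kinematics, force summaries, power estimates, study-level LaMSA verdict),
## synthetic-study simulation, spiral export and the model-experiment
## analysis. Every run can emit result CSVs plus a reproducibility manifest
## via write_results(); all stages are pure functions of (inputs, config,
## seed).

#' Simulate a matched strike study
#'
#' Generates `n_strikes` paired landmark tracks and force traces from
#' scenario templates, varying only the seed between strikes. Used both for
#' testing and for end-to-end demonstration runs.
#'
#' @param n_strikes number of strikes (>= 1).
#' @param strike a [strike_scenario()] template.
#' @param force a [force_scenario()] template.
#' @param seed integer base seed; strike `i` uses `seed + i`.
#' @return list with `tracks` (list of `landmark_track`) and `forces`
#'   (list of `force_trace`).
#' @export
simulate_strike_study <- function(n_strikes, strike = strike_scenario(),
                                  force = force_scenario(), seed = 1L) {
  check_number(n_strikes, "n_strikes", lower = 1)
  if (!inherits(strike, "strike_scenario")) stop_validation("'strike' must be a strike_scenario")
  if (!inherits(force, "force_scenario")) stop_validation("'force' must be a force_scenario")
  tracks <- vector("list", n_strikes)
  forces <- vector("list", n_strikes)
  for (i in seq_len(n_strikes)) {
    s <- strike
    s$seed <- as.integer(seed + i)
    f <- force
    f$seed <- as.integer(seed + 1000L + i)
    tracks[[i]] <- generate_strike_track(s)
    forces[[i]] <- generate_force_trace(f)
  }
  list(tracks = tracks, forces = forces)
}

#' Run the full strike analysis pipeline
#'
#' For each strike: kinematic analysis (joint angles, standardization,
#' angular velocity, tip speed, segmentation, summary), force processing
#' (baseline correction, peak/median extraction, body-mass-specific
#' normalization) and the two-approach power estimate with LaMSA verdict.
#' The lever arm of the leg model is measured per strike as the
#' CT-joint-to-tarsus distance at the strike start frame, converted with
#' the study scale.
#'
#' @param tracks non-empty list of [landmark_track()] objects.
#' @param forces list of [force_trace()] objects, one per track (mN).
#' @param config a [study_config()]; must resolve a muscle mass.
#' @param leg_mass_mg mass of the swinging leg for the inertia model, mg
#'   (point mass at the lever arm).
#' @param limits direct-muscle performance range, W/kg.
#' @param out_dir optional output directory for result CSVs + manifest.
#' @param seeds optional named seeds to record in the manifest.
#' @param ... passed to [strike_kinematics()].
#' @return an object of class `strike_study`: per-strike `kinematics`,
#'   `force`, and `power` tables, the study-level `verdict`, and the
#'   objects themselves in `details`.
#' @export
run_strike_pipeline <- function(tracks, forces, config, leg_mass_mg = 1,
                                limits = c(100, 500), out_dir = NULL,
                                seeds = NULL, ...) {
  if (!is.list(tracks) || length(tracks) == 0) {
    stop_validation("'tracks' must be a non-empty list of landmark_track objects")
  }
  if (!is.list(forces) || length(forces) != length(tracks)) {
    stop_validation("'forces' must be a list matching 'tracks' in length")
  }
  if (!inherits(config, "study_config")) stop_validation("'config' must be a study_config")
  muscle_mass_mg <- config_muscle_mass_mg(config)

  kin_rows <- list()
  force_rows <- list()
  power_rows <- list()
  details <- list()
  for (i in seq_along(tracks)) {
    kin <- tryCatch(
      strike_kinematics(tracks[[i]], ...),
      error = function(e) {
        ms_stop(sprintf("strike %d, kinematics stage: %s", i, conditionMessage(e)),
                class(e)[1])
      }
    )
    fsum <- tryCatch({
      corrected <- baseline_correct(forces[[i]])
      summarize_strike_force(corrected)
    }, error = function(e) {
      ms_stop(sprintf("strike %d, force stage: %s", i, conditionMessage(e)),
              class(e)[1])
    })

    start1 <- kin$phases$start_frame + 1L
    lever_px <- sqrt(sum((tracks[[i]]$xy[start1, "tarsus_base", ] -
                            tracks[[i]]$xy[start1, "ct_joint", ])^2))
    lever_mm <- lever_px * tracks[[i]]$scale
    muscle <- muscle_model(muscle_mass_mg, lever_mm,
                           segments = data.frame(kind = "point",
                                                 mass_mg = leg_mass_mg,
                                                 length_mm = lever_mm))
    pw <- power_estimate(fsum$f_peak / 1000, kin$summary, muscle, limits)

    s <- kin$summary
    kin_rows[[i]] <- data.frame(
      strike = i, sweep_duration = s$sweep_duration,
      peak_omega_ct = s$peak_omega_ct, peak_tip_speed = s$peak_tip_speed,
      mean_tip_speed = s$mean_tip_speed, start_frame = s$start_frame,
      end_frame = s$end_frame
    )
    force_rows[[i]] <- data.frame(
      strike = i, f_peak = fsum$f_peak, f_median = fsum$f_median,
      f_peak_specific = mass_specific_force(fsum, config)
    )
    power_rows[[i]] <- data.frame(
      strike = i, f_peak_N = pw$f_peak, v_tip_peak = pw$v_tip_peak,
      omega_peak = pw$omega_peak, sweep_duration = pw$sweep_duration,
      lever_arm_mm = lever_mm, mpo_inst = pw$mpo_inst,
      mpo_energetic = pw$mpo_energetic, verdict = pw$verdict,
      amplification_ratio = pw$amplification_ratio
    )
    details[[i]] <- list(kinematics = kin, force = fsum, power = pw)
  }
  kin_tab <- do.call(rbind, kin_rows)
  force_tab <- do.call(rbind, force_rows)
  power_tab <- do.call(rbind, power_rows)

  verdicts <- power_tab$verdict
  study_verdict <- if (all(verdicts == "amplified")) "amplified" else
    if (all(verdicts == "within_muscle_limits")) "within_muscle_limits" else "indeterminate"
  verdict_tab <- data.frame(
    n_strikes = length(tracks),
    mean_mpo_inst = mean(power_tab$mpo_inst),
    mean_mpo_energetic = mean(power_tab$mpo_energetic),
    limit_lower = limits[1], limit_upper = limits[2],
    verdict = study_verdict
  )

  manifest <- NULL
  if (!is.null(out_dir)) {
    manifest <- write_results(
      list(strike_kinematics = kin_tab, strike_forces = force_tab,
           strike_power = power_tab, study_verdict = verdict_tab),
      out_dir, config = config, seeds = seeds
    )
  }
  structure(list(kinematics = kin_tab, force = force_tab, power = power_tab,
                 verdict = verdict_tab, details = details,
                 manifest = manifest),
            class = "strike_study")
}

#' @export
print.strike_study <- function(x, ...) {
  cat(sprintf("<strike_study> %d strikes\n", nrow(x$kinematics)))
  cat(sprintf("  mean sweep %.4g ms, mean peak tip %.4g m/s, mean peak force %.4g mN\n",
              mean(x$kinematics$sweep_duration) * 1000,
              mean(x$kinematics$peak_tip_speed), mean(x$force$f_peak)))
  cat(sprintf("  mean mpo: %.1f W/kg (approach 1), %.1f W/kg (approach 2)\n",
              x$verdict$mean_mpo_inst, x$verdict$mean_mpo_energetic))
  cat(sprintf("  study verdict: %s\n", x$verdict$verdict))
  invisible(x)
}

#' Run the model-experiment analysis end to end
#'
#' Extracts per-trial maxima from a model study and fits the mixed-effects
#' models, optionally writing report tables.
#'
#' @param trials a `model_study` from [generate_model_study()] (or any list
#'   of `model_trial`s).
#' @param out_dir optional output directory for [model_report()].
#' @param alpha significance level.
#' @return list with `summaries` (trial table) and `models`
#'   ([fit_trial_models()] result).
#' @export
run_model_experiment <- function(trials, out_dir = NULL, alpha = 0.05) {
  summaries <- trial_summaries(trials)
  models <- fit_trial_models(summaries, alpha = alpha)
  if (!is.null(out_dir)) model_report(models, out_dir)
  list(summaries = summaries, models = models)
}

#' Export the double-spiral spring design
#'
#' Convenience wrapper: build the double spiral from two parameter sets and
#' export CSV and/or SVG files.
#'
#' @param spec1,spec2 [spiral_spec()] objects.
#' @param csv,svg optional output paths.
#' @param n_points points per polyline.
#' @return the [double_spiral()] geometry, invisibly.
#' @export
run_spiral_export <- function(spec1 = spiral_spec(r0 = 11),
                              spec2 = spiral_spec(r0 = 14.5),
                              csv = NULL, svg = NULL, n_points = 500L) {
  geom <- double_spiral(spec1, spec2, n_points)
  if (!is.null(csv)) export_geometry(geom, csv, "csv")
  if (!is.null(svg)) export_geometry(geom, svg, "svg")
  invisible(geom)
}
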