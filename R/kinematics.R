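## Strike kinematics from landmark tracks: joint angles by the
## dot-product/arc-cosine construction, standardized angles, angular
## velocities (Savitzky-Golay or central differences), tip speed, strike
## segmentation (closed-CT plateau -> rapid opening -> impalement) and peak
## summaries. All angle operations are invariant under rigid transforms and
## uniform scaling of the coordinates, and under the y-down/y-up flip of
## tracker exports.

# Interior angle (deg) at vertex b between rays b->a and b->c, per frame.
interior_angle <- function(a, b, c, joint, frames0) {
  v1 <- a - b
  v2 <- c - b
  n1 <- sqrt(rowSums(v1^2))
  n2 <- sqrt(rowSums(v2^2))
  bad <- which(n1 == 0 | n2 == 0)
  if (length(bad)) {
    stop_degenerate(sprintf(
      "coincident landmarks at %s joint, frame %s: zero-length vector",
      joint, paste(frames0[bad], collapse = ", ")
    ))
  }
  cosang <- pmin(1, pmax(-1, rowSums(v1 * v2) / (n1 * n2)))
  rad2deg(acos(cosang))
}

#' Joint-angle series from a landmark track
#'
#' Computes the per-frame interior coxa-trochanter (CT) angle (at the CT
#' joint, between the vectors to the coxal base and to the femur-tibia
#' joint) and femur-tibia (FT) angle (at the FT joint, between the vectors
#' to the CT joint and to the tarsus base), via the dot-product/arc-cosine
#' construction. Angles lie in [0, 180] degrees and are invariant under
#' global translation, rotation, reflection and uniform scaling of the
#' coordinates.
#'
#' @param track a [landmark_track()].
#' @return an object of class `joint_angle_series` with elements `t`, `fps`,
#'   `ct_angle`, `ft_angle` (degrees) and placeholders for standardized
#'   angles and angular velocities.
#' @export
joint_angles <- function(track) {
  if (!inherits(track, "landmark_track")) stop_validation("'track' must be a landmark_track")
  frames0 <- seq_len(n_frames(track)) - 1L
  ct <- interior_angle(track$xy[, "coxal_base", ], track$xy[, "ct_joint", ],
                       track$xy[, "ft_joint", ], "CT", frames0)
  ft <- interior_angle(track$xy[, "ct_joint", ], track$xy[, "ft_joint", ],
                       track$xy[, "tarsus_base", ], "FT", frames0)
  structure(list(t = track$t, fps = track$fps, ct_angle = ct, ft_angle = ft,
                 ct_std = NULL, ft_std = NULL, omega_ct = NULL,
                 omega_ft = NULL, convention = NULL),
            class = "joint_angle_series")
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("<joint_angle_series> %d frames @ %g fps; CT %.1f..%.1f deg, FT %.1f..%.1f deg\n",
              length(x$t), x$fps, min(x$ct_angle), max(x$ct_angle),
              min(x$ft_angle), max(x$ft_angle)))
  if (!is.null(x$convention)) cat(sprintf("  standardized (%s)\n", x$convention))
  invisible(x)
}

#' Standardize joint angles against the initial frame
#'
#' Standardized angles reference each joint to its value at frame 0. The
#' default `"opening_positive"` convention stores `angle - angle[0]`, so
#' joint opening is positive — the sign convention every downstream velocity
#' and power computation relies on. The `"literal"` convention stores the
#' mirrored difference `angle[0] - angle` (initial minus raw) and is kept as
#' a documented alternative. Frame 0 maps to exactly 0 under both. The
#' operation is idempotent: standardizing an already standardized series
#' returns it unchanged.
#'
#' @param series a [joint_angles()] result.
#' @param convention `"opening_positive"` (default) or `"literal"`.
#' @return the series with `ct_std`/`ft_std` filled in and the convention
#'   recorded.
#' @export
standardize_angles <- function(series,
                               convention = c("opening_positive", "literal")) {
  if (!inherits(series, "joint_angle_series")) {
    stop_validation("'series' must be a joint_angle_series")
  }
  convention <- match.arg(convention)
  if (!is.null(series$convention)) return(series) # already standardized
  sgn <- if (convention == "opening_positive") 1 else -1
  series$ct_std <- sgn * (series$ct_angle - series$ct_angle[1])
  series$ft_std <- sgn * (series$ft_angle - series$ft_angle[1])
  series$convention <- convention
  series
}

# One-sided/central finite differences: interior frames use the central
# difference, endpoints the one-sided difference.
finite_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}

#' Angular velocity of the joint-angle series
#'
#' Differentiates the raw joint angles to rad/s. `"savitzky_golay"`
#' (default) fits a local quadratic in a moving window (endpoint frames use
#' the one-sided filter rows); `"central_difference"` uses plain central
#' differences with one-sided endpoints. Both reproduce the slope of a
#' strictly linear ramp exactly and never flip its sign.
#'
#' @param series a [joint_angles()] result.
#' @param method `"savitzky_golay"` or `"central_difference"`.
#' @param window odd window length in frames (>= 3, <= n) for the smoothing
#'   method.
#' @return the series with `omega_ct`/`omega_ft` (rad/s) filled in.
#' @export
angular_velocity <- function(series,
                             method = c("savitzky_golay", "central_difference"),
                             window = 5L) {
  if (!inherits(series, "joint_angle_series")) {
    stop_validation("'series' must be a joint_angle_series")
  }
  method <- match.arg(method)
  n <- length(series$ct_angle)
  dt <- 1 / series$fps
  if (method == "savitzky_golay") {
    if (window %% 2 == 0 || window < 3 || window > n) {
      stop_validation("'window' must be odd, >= 3 and <= the number of frames")
    }
    p <- min(2L, window - 1L)
    d_ct <- signal::sgolayfilt(series$ct_angle, p = p, n = window, m = 1, ts = dt)
    d_ft <- signal::sgolayfilt(series$ft_angle, p = p, n = window, m = 1, ts = dt)
  } else {
    d_ct <- finite_diff(series$ct_angle, dt)
    d_ft <- finite_diff(series$ft_angle, dt)
  }
  series$omega_ct <- deg2rad(d_ct)
  series$omega_ft <- deg2rad(d_ft)
  series$omega_method <- method
  series
}

#' Linear tip speed of the tarsus-base landmark
#'
#' Per-frame speed of the distal (tarsus-base) landmark in m/s, from central
#' differences of its pixel coordinates (one-sided at the endpoints), with
#' the pixel-to-mm-to-m conversion applied exactly once.
#'
#' @param track a [landmark_track()] with a known mm/pixel scale.
#' @return numeric vector of speeds, m/s, one per frame.
#' @export
tip_speed <- function(track) {
  if (!inherits(track, "landmark_track")) stop_validation("'track' must be a landmark_track")
  if (is.na(track$scale)) stop_config("track has no mm/pixel scale; set it in the study config")
  dt <- 1 / track$fps
  vx <- finite_diff(track$xy[, "tarsus_base", "x"], dt)
  vy <- finite_diff(track$xy[, "tarsus_base", "y"], dt)
  sqrt(vx^2 + vy^2) * track$scale / 1000
}

#' Segment a strike into plateau, sweep and impalement
#'
#' Operationalizes the verbal strike definition: the strike starts the
#' moment the CT joint begins to open after having been completely closed,
#' and ends when the apical tibial spur stops penetrating the prey.
#' Concretely:
#'
#' * The closed plateau is the longest run of at least `min_plateau` frames
#'   whose CT angle stays within `closed_tolerance` degrees of the running
#'   CT minimum.
#' * The start frame is the first frame in that run whose rise over the
#'   previous frame exceeds an adaptive threshold (`rise_sigma_mult` times a
#'   robust MAD estimate of the frame-to-frame noise inside the plateau,
#'   floored at a tiny epsilon so noise-free ramps are caught on their first
#'   rising frame) for `confirm_frames` consecutive frames. The reported
#'   plateau is trimmed to end just before the start frame.
#' * The end frame is the first frame after the peak tip speed at which the
#'   tip speed falls below `end_speed_frac` of that peak (penetration depth
#'   is not tracked, so "stops penetrating" is operationalized as the tip
#'   essentially stopping).
#'
#' All frame indices are 0-based, matching the tracker-file frame column.
#'
#' @param series a [joint_angles()] result.
#' @param tip tip-speed series from [tip_speed()], aligned with `series`.
#' @param closed_tolerance plateau tolerance, degrees.
#' @param min_plateau minimum plateau length, frames.
#' @param end_speed_frac end-of-strike threshold as a fraction of the peak
#'   tip speed.
#' @param rise_sigma_mult multiplier on the robust frame-to-frame noise
#'   estimate for the start-detection threshold.
#' @param confirm_frames consecutive rising frames required to confirm the
#'   start.
#' @return an object of class `strike_phases`: 0-based `start_frame`,
#'   `end_frame` and `plateau` range.
#' @export
segment_strike <- function(series, tip, closed_tolerance = 1,
                           min_plateau = 5L, end_speed_frac = 0.05,
                           rise_sigma_mult = 3, confirm_frames = 2L) {
  if (!inherits(series, "joint_angle_series")) {
    stop_validation("'series' must be a joint_angle_series")
  }
  theta <- series$ct_angle
  n <- length(theta)
  if (length(tip) != n) stop_validation("'tip' must be aligned with 'series' (same length)")
  check_number(closed_tolerance, "closed_tolerance", lower = 0, strict = TRUE)
  check_number(min_plateau, "min_plateau", lower = 1)
  check_number(end_speed_frac, "end_speed_frac", lower = 0)

  run_min <- cummin(theta)
  mask <- theta <= run_min + closed_tolerance
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= min_plateau)
  if (length(ok) == 0L) {
    stop_segmentation(sprintf(
      paste0("no closed-CT plateau found (no run of >= %d frames within ",
             "%.3g deg of the running minimum); longest candidate run: %d frames"),
      min_plateau, closed_tolerance,
      if (any(r$values)) max(r$lengths[r$values]) else 0L
    ))
  }
  best <- ok[which.max(r$lengths[ok])]
  a <- starts[best] # 1-based plateau run start
  b <- ends[best]   # 1-based plateau run end (may overshoot into the ramp)

  d <- diff(theta) # d[i] = theta[i+1] - theta[i]
  # Robust frame-to-frame noise estimate over everything up to the end of
  # the plateau run; MAD keeps a few contaminating ramp frames harmless.
  plateau_d <- d[seq_len(max(a, b - 1L))]
  sigma <- mad(plateau_d, center = 0)
  thr <- max(rise_sigma_mult * sigma, 1e-9)
  start1 <- NA_integer_ # 1-based start frame
  for (i in (a + 1L):(n - 1L)) {
    upto <- min(i + confirm_frames - 1L, n) - 1L
    if (all(d[(i - 1L):upto] > thr)) {
      start1 <- i
      break
    }
  }
  if (is.na(start1)) {
    stop_segmentation(sprintf(
      "CT joint never starts to open: no %d consecutive rises above %.3g deg after the plateau",
      confirm_frames, thr
    ))
  }

  seg <- start1:n
  pk <- seg[which.max(tip[seg])]
  end1 <- n
  if (pk < n) {
    below <- which(tip[(pk + 1L):n] < end_speed_frac * tip[pk])
    if (length(below)) end1 <- pk + below[1]
  }

  structure(list(start_frame = start1 - 1L, end_frame = end1 - 1L,
                 plateau = c(a, min(b, start1 - 1L)) - 1L,
                 params = list(closed_tolerance = closed_tolerance,
                               min_plateau = as.integer(min_plateau),
                               end_speed_frac = end_speed_frac,
                               rise_sigma_mult = rise_sigma_mult,
                               confirm_frames = as.integer(confirm_frames))),
            class = "strike_phases")
}

#' @export
print.strike_phases <- function(x, ...) {
  cat(sprintf("<strike_phases> plateau frames %d..%d, sweep %d..%d (0-based)\n",
              x$plateau[1], x$plateau[2], x$start_frame, x$end_frame))
  invisible(x)
}

#' Summarize peak strike kinematics
#'
#' Sweep duration `(end - start) / fps`, peak CT angular velocity, and peak
#' and mean tip speed, all evaluated within the segmented sweep window.
#'
#' @param series a series with angular velocities (see [angular_velocity()]).
#' @param phases a [segment_strike()] result.
#' @param tip tip-speed series from [tip_speed()].
#' @return an object of class `strike_summary`.
#' @export
summarize_strike <- function(series, phases, tip) {
  if (!inherits(phases, "strike_phases")) stop_validation("'phases' must be strike_phases")
  if (is.null(series$omega_ct)) {
    stop_validation("series has no angular velocities; call angular_velocity() first")
  }
  idx <- (phases$start_frame:phases$end_frame) + 1L
  structure(list(
    sweep_duration = (phases$end_frame - phases$start_frame) / series$fps,
    peak_omega_ct = max(series$omega_ct[idx]),
    peak_tip_speed = max(tip[idx]),
    mean_tip_speed = mean(tip[idx]),
    start_frame = phases$start_frame, end_frame = phases$end_frame,
    fps = series$fps
  ), class = "strike_summary")
}

#' @export
print.strike_summary <- function(x, ...) {
  cat(sprintf(paste0("<strike_summary> sweep %.4g ms (frames %d..%d), ",
                     "peak omega_CT %.4g rad/s, peak tip %.4g m/s, mean tip %.4g m/s\n"),
              x$sweep_duration * 1000, x$start_frame, x$end_frame,
              x$peak_omega_ct, x$peak_tip_speed, x$mean_tip_speed))
  invisible(x)
}

#' Full kinematic analysis of one strike
#'
#' Convenience chain: joint angles, standardization, angular velocity, tip
#' speed, segmentation and summary, plus a per-frame table with phase
#' labels (`plateau`, `sweep`, `post` or `pre`).
#'
#' @param track a [landmark_track()].
#' @param method,window passed to [angular_velocity()].
#' @param convention passed to [standardize_angles()].
#' @param ... passed to [segment_strike()].
#' @return an object of class `strike_kinematics` with elements `series`,
#'   `tip`, `phases`, `summary` and the per-frame data frame `frames`.
#' @export
strike_kinematics <- function(track, method = "savitzky_golay", window = 5L,
                              convention = "opening_positive", ...) {
  series <- joint_angles(track)
  series <- standardize_angles(series, convention = convention)
  series <- angular_velocity(series, method = method, window = window)
  tip <- tip_speed(track)
  phases <- segment_strike(series, tip, ...)
  summ <- summarize_strike(series, phases, tip)
  frame0 <- seq_along(series$t) - 1L
  phase <- rep("pre", length(frame0))
  phase[frame0 >= phases$plateau[1] & frame0 <= phases$plateau[2]] <- "plateau"
  phase[frame0 >= phases$start_frame & frame0 <= phases$end_frame] <- "sweep"
  phase[frame0 > phases$end_frame] <- "post"
  frames <- data.frame(
    frame = frame0, t = series$t, ct_angle = series$ct_angle,
    ft_angle = series$ft_angle, ct_std = series$ct_std,
    ft_std = series$ft_std, omega_ct = series$omega_ct,
    omega_ft = series$omega_ft, tip_speed = tip, phase = phase
  )
  structure(list(series = series, tip = tip, phases = phases,
                 summary = summ, frames = frames),
            class = "strike_kinematics")
}

#' @export
print.strike_kinematics <- function(x, ...) {
  print(x$phases)
  print(x$summary)
  invisible(x)
}
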