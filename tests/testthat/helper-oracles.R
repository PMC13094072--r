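# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately use a different construction than the
# package (atan2 + wrapped difference vs dot product + arccos).

# Interior angle in degrees at vertex b, via atan2 of each ray and the
# absolute wrapped difference.
oracle_angle <- function(a, b, c) {
  a1 <- atan2(a[2] - b[2], a[1] - b[1])
  a2 <- atan2(c[2] - b[2], c[1] - b[1])
  d <- abs(a1 - a2) %% (2 * pi)
  if (d > pi) d <- 2 * pi - d
  d * 180 / pi
}

# Build a landmark_track from an n x 5 x 2 array of raw coordinates.
make_track <- function(xy, fps = 1000, scale = 0.01) {
  dimnames(xy) <- list(NULL, mantisstrike:::LANDMARK_NAMES, c("x", "y"))
  landmark_track(xy, fps = fps, scale = scale)
}

# Track with every landmark constant at the given 5 x 2 position matrix.
constant_track <- function(pos, n = 5, fps = 1000, scale = 0.01) {
  xy <- array(NA_real_, dim = c(n, 5, 2))
  for (i in 1:5) xy[, i, ] <- matrix(pos[i, ], n, 2, byrow = TRUE)
  make_track(xy, fps, scale)
}

# Random non-degenerate frame: five points whose CT and FT interior angles
# are drawn uniformly away from 0/180 degrees. Returns the 5 x 2 matrix and
# the true angles.
random_frame <- function() {
  ct_true <- runif(1, 5, 175)
  ft_true <- runif(1, 5, 175)
  base <- runif(2, -200, 200)
  dir0 <- runif(1, 0, 2 * pi)
  l1 <- runif(1, 50, 300)
  l2 <- runif(1, 50, 300)
  l3 <- runif(1, 50, 300)
  coxal_base <- base
  ct <- base + l1 * c(cos(dir0), sin(dir0))
  dir1 <- dir0 + pi - ct_true * pi / 180 # ray ct -> ft
  ft <- ct + l2 * c(cos(dir1), sin(dir1))
  dir2 <- dir1 + pi + ft_true * pi / 180 # ray ft -> tarsus
  tars <- ft + l3 * c(cos(dir2), sin(dir2))
  body <- base + runif(2, -50, 50)
  list(pos = rbind(body, coxal_base, ct, ft, tars),
       ct = ct_true, ft = ft_true)
}

# Direct trial table from a design's generative truth (no trace
# simulation); equals trial_summaries(generate_model_study(design)) because
# the noise-free extraction is exact.
design_trial_table <- function(design) {
  do.call(rbind, lapply(design, function(s) {
    data.frame(
      type = s$type, friction = s$friction, sample = s$sample_id,
      rep = s$rep_id, max_force = s$true_release_force,
      max_velocity = s$post_release_peak_speed *
        min(s$true_release_force, s$spring_saturation_force) /
        s$spring_saturation_force
    )
  }))
}

# Generative parameters for the two mixed-model recovery simulations: (a) a
# pure friction main effect on log force with all velocity effects null;
# (b) a type-specific friction effect on velocity (flexible gains under
# high friction, stiff exactly does not).
sim_design_a <- function(seed) {
  model_study_design(
    n_samples = 4, n_repeats = 8,
    force_means = c(atrH.H = 20, atrS.H = 20,
                    atrH.L = 20 * exp(-1), atrS.L = 20 * exp(-1)),
    speed_means = c(atrH.H = 0.1, atrS.H = 0.1, atrH.L = 0.1, atrS.L = 0.1),
    seed = seed
  )
}

sim_design_b <- function(seed) {
  model_study_design(
    n_samples = 4, n_repeats = 8,
    force_means = c(atrH.H = 22.38, atrS.H = 18.63,
                    atrH.L = 0.55, atrS.L = 0.39),
    speed_means = c(atrH.H = 0.07, atrS.H = 0.205,
                    atrH.L = 0.07, atrS.L = 0.056),
    seed = seed
  )
}
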