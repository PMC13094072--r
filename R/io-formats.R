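## File formats and core containers. One documented tracker dialect is used
## on disk (wide layout, one file per strike): columns
## `frame, <landmark>_x, <landmark>_y` for the five landmarks, tab- or
## comma-separated. Units on disk are pixels (coordinates), mN (force) and
## s (time); conversion to SI happens exactly once, inside the kinematics
## and force modules.

#' Five-landmark strike track
#'
#' Container for per-frame 2-D positions of the five tracked strike
#' landmarks (body, coxal base, coxa-trochanter joint, femur-tibia joint,
#' tarsus base) in image-style pixel coordinates, plus timing and scale
#' metadata.
#'
#' @param xy numeric array `n_frames x 5 x 2` (frames, landmarks, x/y), in
#'   pixels; landmark dimnames must match the canonical order.
#' @param fps frames per second (> 0).
#' @param scale mm per pixel (> 0), or `NA` if unknown.
#' @return an object of class `landmark_track`.
#' @export
landmark_track <- function(xy, fps, scale = NA_real_) {
  if (!is.array(xy) || length(dim(xy)) != 3L || dim(xy)[2] != 5L ||
      dim(xy)[3] != 2L) {
    stop_validation("'xy' must be an n_frames x 5 x 2 array")
  }
  if (dim(xy)[1] < 3L) stop_validation("a landmark track needs >= 3 frames")
  if (anyNA(xy) || any(!is.finite(xy))) {
    stop_validation("landmark coordinates contain NA/NaN/Inf values")
  }
  check_number(fps, "fps", lower = 0, strict = TRUE)
  if (!is.na(scale)) check_number(scale, "scale", lower = 0, strict = TRUE)
  if (is.null(dimnames(xy)[[2]])) {
    dimnames(xy) <- list(NULL, LANDMARK_NAMES, c("x", "y"))
  } else if (!identical(dimnames(xy)[[2]], LANDMARK_NAMES)) {
    stop_validation(sprintf("landmarks must be, in order: %s",
                            paste(LANDMARK_NAMES, collapse = ", ")))
  }
  structure(list(xy = xy, fps = fps, scale = scale,
                 t = (seq_len(dim(xy)[1]) - 1L) / fps),
            class = "landmark_track")
}

n_frames <- function(track) dim(track$xy)[1]

#' @export
print.landmark_track <- function(x, ...) {
  cat(sprintf("<landmark_track> %d frames @ %g fps, scale %s mm/px\n",
              n_frames(x), x$fps,
              if (is.na(x$scale)) "?" else format(x$scale)))
  invisible(x)
}

#' Force-time trace
#'
#' @param t sample times, s (strictly increasing).
#' @param f force samples, mN.
#' @param fs sampling rate, Hz; inferred from the median time step when
#'   omitted.
#' @param animal_id,day,prey_size_class optional grouping labels.
#' @return an object of class `force_trace`.
#' @export
force_trace <- function(t, f, fs = NULL, animal_id = NA_character_,
                        day = NA_character_, prey_size_class = NA_character_) {
  if (length(t) != length(f) || length(t) < 2L) {
    stop_validation("'t' and 'f' must have equal length >= 2")
  }
  if (anyNA(t) || anyNA(f) || any(!is.finite(t)) || any(!is.finite(f))) {
    stop_validation("force trace contains NA/NaN/Inf values")
  }
  if (any(diff(t) <= 0)) {
    stop_validation("force trace time must be strictly increasing")
  }
  if (is.null(fs)) fs <- 1 / median(diff(t))
  structure(list(t = t, f = f, fs = fs, animal_id = animal_id, day = day,
                 prey_size_class = prey_size_class),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> %d samples @ %.6g Hz, %.3g s, peak %.4g mN\n",
              length(x$t), x$fs, max(x$t) - min(x$t), max(x$f)))
  invisible(x)
}

#' Per-animal study configuration
#'
#' Metadata required to convert tracker pixels and transducer output into
#' physical quantities: frame rate, spatial scale, body mass and (for power
#' computation) either a measured muscle mass or a muscle-mass fraction of
#' body mass. No silent muscle-mass default exists: power functions error if
#' neither is given.
#'
#' @param fps frames per second of the video (> 0).
#' @param scale mm per pixel (> 0).
#' @param body_mass body mass, g (> 0).
#' @param muscle_mass extensor muscle mass, mg (optional).
#' @param muscle_mass_fraction muscle mass as a fraction of body mass
#'   (optional fallback).
#' @param animal_id,trial_id labels.
#' @param landmark_names ordered landmark labels (fixed five-name vocabulary).
#' @return an object of class `study_config`.
#' @export
study_config <- function(fps, scale, body_mass, muscle_mass = NULL,
                         muscle_mass_fraction = NULL, animal_id = "animal1",
                         trial_id = "trial1",
                         landmark_names = LANDMARK_NAMES) {
  check_number(fps, "fps", lower = 0, strict = TRUE)
  check_number(scale, "scale", lower = 0, strict = TRUE)
  check_number(body_mass, "body_mass", lower = 0, strict = TRUE)
  if (!is.null(muscle_mass)) check_number(muscle_mass, "muscle_mass", lower = 0, strict = TRUE)
  if (!is.null(muscle_mass_fraction)) {
    check_number(muscle_mass_fraction, "muscle_mass_fraction", lower = 0, strict = TRUE)
  }
  if (length(landmark_names) != 5L || !identical(as.character(landmark_names), LANDMARK_NAMES)) {
    stop_validation(sprintf("'landmark_names' must be exactly: %s",
                            paste(LANDMARK_NAMES, collapse = ", ")))
  }
  structure(list(fps = fps, scale = scale, body_mass = body_mass,
                 muscle_mass = muscle_mass,
                 muscle_mass_fraction = muscle_mass_fraction,
                 animal_id = as.character(animal_id),
                 trial_id = as.character(trial_id),
                 landmark_names = LANDMARK_NAMES),
            class = "study_config")
}

# Resolve muscle mass in mg from a study_config; errors when neither field
# is present (power computation must never guess).
config_muscle_mass_mg <- function(config) {
  if (!is.null(config$muscle_mass)) return(config$muscle_mass)
  if (!is.null(config$muscle_mass_fraction)) {
    return(config$muscle_mass_fraction * config$body_mass * 1000)
  }
  stop_config("neither 'muscle_mass' nor 'muscle_mass_fraction' is set in the study config")
}

#' Read / write a study configuration (flat YAML)
#'
#' @param path file path.
#' @return [read_study_config()] returns a `study_config`;
#'   [write_study_config()] returns the path, invisibly.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  do.call(study_config, y)
}

#' @param config a [study_config()].
#' @rdname read_study_config
#' @export
write_study_config <- function(config, path) {
  if (!inherits(config, "study_config")) stop_validation("'config' must be a study_config")
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

track_columns <- function() {
  c("frame", as.vector(t(outer(LANDMARK_NAMES, c("x", "y"), paste, sep = "_"))))
}

detect_sep <- function(header_line) {
  if (grepl("\t", header_line, fixed = TRUE)) "\t" else ","
}

#' Read a tracker landmark export
#'
#' Reads the package's tracker dialect: one file per strike, tab- or
#' comma-separated, wide layout `frame, <name>_x, <name>_y` for the five
#' landmarks in canonical order, frames indexed from 0 with no gaps or
#' duplicates. Missing frames are an error, never silently filled.
#'
#' @param path file path.
#' @param config a [study_config()] supplying fps and scale.
#' @return a [landmark_track()].
#' @export
read_landmark_track <- function(path, config) {
  if (!inherits(config, "study_config")) stop_validation("'config' must be a study_config")
  if (!file.exists(path)) stop_format(sprintf("track file not found: %s", path))
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop_format(sprintf("empty track file: %s", path))
  sep <- detect_sep(header)
  d <- read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  want <- track_columns()
  if (!identical(names(d), want)) {
    stop_format(sprintf(
      "unexpected tracker columns in %s; expected the wide dialect: %s",
      path, paste(want, collapse = ", ")
    ))
  }
  if (nrow(d) < 3L) stop_format(sprintf("track file %s has < 3 frames", path))
  if (!is.numeric(as.matrix(d)) || anyNA(d)) {
    stop_format(sprintf("non-numeric or NA values in track file %s", path))
  }
  fr <- d$frame
  if (anyDuplicated(fr)) stop_format(sprintf("duplicate frame indices in %s", path))
  if (any(diff(fr) <= 0)) stop_format(sprintf("non-monotonic frame index in %s", path))
  if (!identical(as.integer(fr), seq_len(nrow(d)) - 1L)) {
    stop_format(sprintf("missing frames in %s: frame index must run 0..n-1 without gaps", path))
  }
  xy <- array(NA_real_, dim = c(nrow(d), 5L, 2L),
              dimnames = list(NULL, LANDMARK_NAMES, c("x", "y")))
  for (lm in LANDMARK_NAMES) {
    xy[, lm, "x"] <- d[[paste0(lm, "_x")]]
    xy[, lm, "y"] <- d[[paste0(lm, "_y")]]
  }
  landmark_track(xy, fps = config$fps, scale = config$scale)
}

#' Write a landmark track in the tracker dialect
#'
#' Values are written with 17 significant digits, so a write/read round trip
#' reproduces the doubles bit exactly.
#'
#' @param track a [landmark_track()].
#' @param path output path.
#' @param sep field separator, `"\t"` (default) or `","`.
#' @return the path, invisibly.
#' @export
write_landmark_track <- function(track, path, sep = "\t") {
  if (!inherits(track, "landmark_track")) stop_validation("'track' must be a landmark_track")
  n <- n_frames(track)
  cols <- list(frame = seq_len(n) - 1L)
  for (lm in LANDMARK_NAMES) {
    cols[[paste0(lm, "_x")]] <- fmt_full(track$xy[, lm, "x"])
    cols[[paste0(lm, "_y")]] <- fmt_full(track$xy[, lm, "y"])
  }
  lines <- c(paste(names(cols), collapse = sep),
             do.call(paste, c(cols, sep = sep)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a force trace (two-column time/force CSV)
#'
#' Expects a header plus two numeric columns: time in s (strictly
#' increasing) and force in mN. The sampling rate is inferred from the
#' median time step.
#'
#' @param path file path.
#' @return a [force_trace()].
#' @export
read_force_trace <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("force file not found: %s", path))
  if (file.size(path) == 0L) stop_format(sprintf("empty force file: %s", path))
  d <- read.table(path, header = TRUE, sep = ",")
  if (ncol(d) != 2L) {
    stop_format(sprintf("force file %s must have exactly 2 columns (time s, force mN), found %d",
                        path, ncol(d)))
  }
  if (nrow(d) < 2L) stop_format(sprintf("force file %s has < 2 samples", path))
  if (!is.numeric(d[[1]]) || !is.numeric(d[[2]]) || anyNA(d)) {
    stop_format(sprintf("non-numeric or NA values in force file %s", path))
  }
  if (any(diff(d[[1]]) <= 0)) {
    stop_format(sprintf("time column in %s must be strictly increasing", path))
  }
  force_trace(d[[1]], d[[2]])
}

#' Write a force trace as time/force CSV
#'
#' @param trace a [force_trace()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_force_trace <- function(trace, path) {
  if (!inherits(trace, "force_trace")) stop_validation("'trace' must be a force_trace")
  writeLines(c("time_s,force_mN",
               paste(fmt_full(trace$t), fmt_full(trace$f), sep = ",")),
             path)
  invisible(path)
}

#' Write result tables and a run manifest
#'
#' Writes each table in `tables` as `<name>.csv` (deterministic column and
#' row order as given) plus `manifest.json` recording the package version,
#' the configuration snapshot, seeds, consumed input files (with MD5
#' hashes), and an index of the written outputs. Two runs on identical
#' inputs produce byte-identical files.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if needed).
#' @param config optional [study_config()] (or any list) snapshot.
#' @param seeds optional named list/vector of seeds used.
#' @param inputs character vector of input file paths consumed.
#' @return invisibly, the manifest as a list.
#' @export
write_results <- function(tables, out_dir, config = NULL, seeds = NULL,
                          inputs = character()) {
  if (!is.list(tables) || (length(tables) > 0 && is.null(names(tables)))) {
    stop_validation("'tables' must be a named list of data frames")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_validation(sprintf("cannot create output directory %s", out_dir))
  files <- character()
  for (nm in names(tables)) {
    stopifnot(is.data.frame(tables[[nm]]))
    fp <- file.path(out_dir, paste0(nm, ".csv"))
    tab <- tables[[nm]]
    # full-precision doubles so the CSV round-trips values bit exactly
    for (cl in names(tab)) {
      if (is.double(tab[[cl]])) tab[[cl]] <- fmt_full(tab[[cl]])
    }
    write.csv(tab, fp, row.names = FALSE)
    files <- c(files, fp)
  }
  manifest <- list(
    package = "mantisstrike",
    version = as.character(packageVersion("mantisstrike")),
    config = if (is.null(config)) NULL else unclass(config),
    seeds = seeds,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    outputs = lapply(files, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
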