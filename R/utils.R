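#' @keywords internal
"_PACKAGE"

#' @importFrom stats median mad rnorm coef lm anova predict var sd setNames
#'   kruskal.test integrate as.formula contr.sum contrasts contrasts<- vcov
#' @importFrom utils read.table write.csv packageVersion capture.output
NULL

# Canonical ordered landmark names for a five-point strike track:
# the body at the forewing base, the coxal base, the coxa-trochanter joint,
# the femur-tibia joint, and the base of the tarsus.
LANDMARK_NAMES <- c("body", "coxal_base", "ct_joint", "ft_joint", "tarsus_base")

# Classed condition helpers. Every user-facing validation failure carries a
# class so callers (and tests) can distinguish bad parameters from bad files
# from degenerate geometry.
ms_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mantisstrike_error")))
}

stop_validation <- function(msg) ms_stop(msg, "mantisstrike_validation_error")
stop_format <- function(msg) ms_stop(msg, "mantisstrike_format_error")
stop_config <- function(msg) ms_stop(msg, "mantisstrike_configuration_error")
stop_segmentation <- function(msg) ms_stop(msg, "mantisstrike_segmentation_error")
stop_degenerate <- function(msg) ms_stop(msg, "mantisstrike_degenerate_geometry_error")

check_number <- function(x, name, lower = -Inf, strict = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(!is.finite(x))) {
    stop_validation(sprintf("'%s' must be a finite numeric of length %d", name, len))
  }
  bad <- if (strict) any(x <= lower) else any(x < lower)
  if (bad) {
    stop_validation(sprintf(
      "'%s' must be %s %g (got %s)", name, if (strict) ">" else ">=",
      lower, paste(signif(x, 6), collapse = ", ")
    ))
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_validation(sprintf("'%s' must be TRUE or FALSE", name))
  }
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# 2-D rotation of the rows of an n x 2 matrix by `angle_rad`.
rotate_xy <- function(xy, angle_rad) {
  R <- matrix(c(cos(angle_rad), sin(angle_rad),
                -sin(angle_rad), cos(angle_rad)), 2, 2)
  xy %*% t(R)
}

# Full-precision number formatting: survives a write/read round trip bit
# exactly for doubles.
fmt_full <- function(x) sprintf("%.17g", x)
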