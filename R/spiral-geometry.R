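## Archimedean double-spiral spring geometry for the physical
## proof-of-concept model. The spring element is built from two Archimedean
## spirals r(theta) = r0 + k*theta; the second arm (spirals 3 and 4) is
## derived by point reflection through the origin (rotation by pi), a
## declared, pluggable rule. Model units are dimensionless design units;
## exports carry a unit tag.

#' Archimedean spiral specification
#'
#' `r(theta) = r0 + k * theta` on `theta in [theta0, theta_max]`.
#'
#' @param theta0,theta_max angular range, rad (`theta_max > theta0`).
#' @param k radial growth rate, length/rad (>= 0; 0 gives a circular arc).
#' @param r0 starting radius (> 0).
#' @param units unit tag carried into exports.
#' @return an object of class `spiral_spec`.
#' @export
spiral_spec <- function(theta0 = 0, theta_max = 2 * pi, k = 2, r0 = 11,
                        units = "model") {
  check_number(theta0, "theta0")
  check_number(theta_max, "theta_max")
  if (theta_max <= theta0) stop_validation("'theta_max' must be > 'theta0'")
  check_number(k, "k", lower = 0)
  check_number(r0, "r0", lower = 0, strict = TRUE)
  structure(list(theta0 = theta0, theta_max = theta_max, k = k, r0 = r0,
                 units = units),
            class = "spiral_spec")
}

#' Sample an Archimedean spiral as a polyline
#'
#' Points `(r cos(theta), r sin(theta))` with `theta` sampled uniformly on
#' `[theta0, theta_max]`. For `k > 0` the radius is strictly increasing
#' along the polyline.
#'
#' @param spec a [spiral_spec()].
#' @param n_points number of points (>= 2).
#' @return an `n_points x 2` matrix with columns `x`, `y`.
#' @export
archimedean_spiral <- function(spec, n_points = 500L) {
  if (!inherits(spec, "spiral_spec")) stop_validation("'spec' must be a spiral_spec")
  check_number(n_points, "n_points", lower = 2)
  theta <- seq(spec$theta0, spec$theta_max, length.out = n_points)
  r <- spec$r0 + spec$k * theta
  cbind(x = r * cos(theta), y = r * sin(theta))
}

#' Closed-form arc length of an Archimedean spiral
#'
#' `L = integral sqrt(r(theta)^2 + k^2) dtheta` evaluated with the
#' closed-form antiderivative
#' `(1/k) * [a/2 sqrt(a^2 + k^2) + (k^2/2) asinh(a/k)]` at `a = r(theta)`;
#' for `k = 0` this degenerates exactly to `r0 * (theta_max - theta0)`.
#'
#' @param spec a [spiral_spec()].
#' @return the arc length in model units.
#' @export
arc_length <- function(spec) {
  if (!inherits(spec, "spiral_spec")) stop_validation("'spec' must be a spiral_spec")
  k <- spec$k
  if (k == 0) return(spec$r0 * (spec$theta_max - spec$theta0))
  F <- function(a) a / 2 * sqrt(a^2 + k^2) + k^2 / 2 * asinh(a / k)
  (F(spec$r0 + k * spec$theta_max) - F(spec$r0 + k * spec$theta0)) / k
}

# Total length of a polyline (n x 2 matrix).
polyline_length <- function(xy) {
  sum(sqrt(rowSums(diff(xy)^2)))
}

#' Double-spiral spring geometry
#'
#' Builds the four polylines of the double-spiral spring element: spirals 1
#' and 2 directly from their specifications, spirals 3 and 4 as the point
#' reflections (rotation by pi about the origin) of spirals 1 and 2 — the
#' declared derivation rule, recorded in the metadata. If the two arms'
#' radial ranges touch or cross at any common angle, a warning (not an
#' error) is issued.
#'
#' @param spec1,spec2 [spiral_spec()] objects for the inner and outer spiral
#'   of one arm.
#' @param n_points points per polyline.
#' @return an object of class `double_spiral`: `spirals` (list of four
#'   `n x 2` matrices), `specs`, `derivation`, `units`.
#' @export
double_spiral <- function(spec1, spec2, n_points = 500L) {
  if (!inherits(spec1, "spiral_spec") || !inherits(spec2, "spiral_spec")) {
    stop_validation("'spec1' and 'spec2' must be spiral_spec objects")
  }
  s1 <- archimedean_spiral(spec1, n_points)
  s2 <- archimedean_spiral(spec2, n_points)
  lo <- max(spec1$theta0, spec2$theta0)
  hi <- min(spec1$theta_max, spec2$theta_max)
  if (lo < hi) {
    gap <- function(th) (spec2$r0 + spec2$k * th) - (spec1$r0 + spec1$k * th)
    if (min(gap(lo), gap(hi)) <= 0) {
      warning("spiral 1 touches or crosses spiral 2 within the shared angular range",
              call. = FALSE)
    }
  }
  structure(list(spirals = list(spiral1 = s1, spiral2 = s2,
                                spiral3 = -s1, spiral4 = -s2),
                 specs = list(spec1 = spec1, spec2 = spec2),
                 derivation = "point_reflection_pi",
                 units = spec1$units),
            class = "double_spiral")
}

#' @export
print.double_spiral <- function(x, ...) {
  cat(sprintf("<double_spiral> 4 polylines of %d points (%s units); arms 3-4 by %s\n",
              nrow(x$spirals[[1]]), x$units, x$derivation))
  for (i in 1:2) {
    sp <- x$specs[[i]]
    cat(sprintf("  spiral %d: theta [%.4g, %.4g] rad, k = %g, r0 = %g, arc length %.4f\n",
                i, sp$theta0, sp$theta_max, sp$k, sp$r0, arc_length(sp)))
  }
  invisible(x)
}

#' Export double-spiral geometry as CSV or SVG
#'
#' CSV: columns `spiral, x, y` at full precision (a CSV re-import
#' reproduces the coordinates exactly). SVG: one `<path>` element per
#' spiral (four in total), y-axis flipped into the SVG convention.
#'
#' @param geom a [double_spiral()].
#' @param path output file path.
#' @param format `"csv"` or `"svg"`.
#' @return the path, invisibly.
#' @export
export_geometry <- function(geom, path, format = c("csv", "svg")) {
  if (!inherits(geom, "double_spiral")) stop_validation("'geom' must be a double_spiral")
  if (length(geom$spirals) == 0 || any(vapply(geom$spirals, nrow, integer(1)) < 2)) {
    stop_validation("geometry is empty")
  }
  format <- match.arg(format)
  if (format == "csv") {
    lines <- c(sprintf("# units: %s", geom$units), "spiral,x,y")
    for (i in seq_along(geom$spirals)) {
      xy <- geom$spirals[[i]]
      lines <- c(lines, paste(i, fmt_full(xy[, 1]), fmt_full(xy[, 2]), sep = ","))
    }
    writeLines(lines, path)
  } else {
    all_xy <- do.call(rbind, geom$spirals)
    pad <- 0.05 * max(diff(range(all_xy[, 1])), diff(range(all_xy[, 2])))
    x0 <- min(all_xy[, 1]) - pad
    y0 <- min(-all_xy[, 2]) - pad
    w <- diff(range(all_xy[, 1])) + 2 * pad
    h <- diff(range(all_xy[, 2])) + 2 * pad
    paths <- vapply(geom$spirals, function(xy) {
      pts <- paste(sprintf("%.6f", xy[, 1]), sprintf("%.6f", -xy[, 2]),
                   sep = ",", collapse = " L ")
      sprintf('  <path d="M %s" fill="none" stroke="black" stroke-width="%.4f"/>',
              pts, w / 400)
    }, character(1))
    writeLines(c(
      sprintf('<svg xmlns="http://www.w3.org/2000/svg" viewBox="%.6f %.6f %.6f %.6f">',
              x0, y0, w, h),
      sprintf('  <!-- double-spiral spring, units: %s -->', geom$units),
      paths,
      "</svg>"
    ), path)
  }
  invisible(path)
}

#' Re-import a double-spiral CSV export
#'
#' @param path a CSV file written by [export_geometry()].
#' @return list of polyline matrices, one per spiral.
#' @export
read_spiral_csv <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("spiral file not found: %s", path))
  d <- read.table(path, header = TRUE, sep = ",", comment.char = "#")
  if (!identical(names(d), c("spiral", "x", "y"))) {
    stop_format("expected spiral CSV columns: spiral, x, y")
  }
  lapply(split(d[c("x", "y")], d$spiral), function(p) {
    cbind(x = p$x, y = p$y)
  })
}
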