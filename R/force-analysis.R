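## Force-trace processing: baseline correction, per-strike peak/median
## extraction, body-mass-specific normalization, and grouped summaries with
## a rank-based group test.

#' Baseline-correct a force trace
#'
#' Subtracts the median force over the pre-strike window `[0, pre_window)`
#' seconds (measured from the first sample). Idempotent: the corrected
#' trace's pre-window median is 0, so correcting again changes nothing.
#'
#' @param trace a [force_trace()].
#' @param pre_window length of the pre-strike window, s; must be shorter
#'   than the trace.
#' @return the corrected `force_trace` (attribute `baseline` records the
#'   subtracted value).
#' @export
baseline_correct <- function(trace, pre_window = 0.05) {
  if (!inherits(trace, "force_trace")) stop_validation("'trace' must be a force_trace")
  check_number(pre_window, "pre_window", lower = 0, strict = TRUE)
  rel_t <- trace$t - trace$t[1]
  if (pre_window >= max(rel_t)) {
    stop_validation("'pre_window' must be shorter than the trace")
  }
  base <- median(trace$f[rel_t < pre_window])
  trace$f <- trace$f - base
  attr(trace, "baseline") <- base
  trace
}

#' Extract peak and median force of a strike
#'
#' On a baseline-corrected trace, the strike window is the contiguous run of
#' samples around the peak where the force stays at or above
#' `threshold_frac` of the peak. The peak is the maximum force (first
#' occurrence on ties, which is messaged); the median is taken within the
#' strike window.
#'
#' @param trace a baseline-corrected [force_trace()].
#' @param threshold_frac window threshold as a fraction of the peak force.
#' @return an object of class `force_summary` with `f_peak` and `f_median`
#'   (mN), the 0-based strike `window`, and the trace labels.
#' @export
summarize_strike_force <- function(trace, threshold_frac = 0.05) {
  if (!inherits(trace, "force_trace")) stop_validation("'trace' must be a force_trace")
  check_number(threshold_frac, "threshold_frac", lower = 0)
  f <- trace$f
  peak <- max(f)
  if (peak <= 0) {
    ms_stop("no strike found: trace maximum is not positive after baseline correction",
            "mantisstrike_no_strike_error")
  }
  ipk <- which(f == peak)
  if (length(ipk) > 1L) {
    message(sprintf("tie: %d equal force maxima; reporting the first (t = %.6g s)",
                    length(ipk), trace$t[ipk[1]]))
  }
  ipk <- ipk[1]
  above <- f >= threshold_frac * peak
  lo <- ipk
  while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- ipk
  while (hi < length(f) && above[hi + 1L]) hi <- hi + 1L
  structure(list(f_peak = peak, f_median = median(f[lo:hi]),
                 window = c(lo, hi) - 1L, peak_index = ipk - 1L,
                 animal_id = trace$animal_id, day = trace$day,
                 prey_size_class = trace$prey_size_class),
            class = "force_summary")
}

#' @export
print.force_summary <- function(x, ...) {
  cat(sprintf("<force_summary> peak %.4g mN, median %.4g mN, window samples %d..%d\n",
              x$f_peak, x$f_median, x$window[1], x$window[2]))
  invisible(x)
}

#' Body-mass-specific peak force
#'
#' @param summary a [summarize_strike_force()] result.
#' @param config a [study_config()] carrying the body mass (g), or a single
#'   body mass in g.
#' @return peak force per body mass, mN/g.
#' @export
mass_specific_force <- function(summary, config) {
  if (!inherits(summary, "force_summary")) stop_validation("'summary' must be a force_summary")
  body_mass <- if (inherits(config, "study_config")) config$body_mass else config
  if (is.null(body_mass) || !is.numeric(body_mass) || length(body_mass) != 1 ||
      is.na(body_mass) || body_mass <= 0) {
    stop_config("body mass (g) is missing or not positive")
  }
  summary$f_peak / body_mass
}

#' Grouped force summaries with a rank-based test
#'
#' For each requested grouping factor, reports group means, standard
#' deviations and sizes, plus a Kruskal-Wallis rank test of the peak force
#' across groups (descriptive plumbing; the rank test is used because no
#' parametric test is assumed for these small samples). Significance is
#' flagged at `alpha`. A factor with a single observed level gets its test
#' skipped with a notice; all-tied data are reported as p = 1 (no effect).
#'
#' @param summaries non-empty list of [summarize_strike_force()] results (or
#'   a data frame with columns `f_peak`, `animal`, `day`, `prey_size`).
#' @param grouping character vector of grouping factors to test, from
#'   `"animal"`, `"day"`, `"prey_size"`.
#' @param alpha significance level.
#' @return an object of class `force_aggregate`: per-factor group tables and
#'   test results.
#' @export
aggregate_forces <- function(summaries, grouping = c("animal", "day", "prey_size"),
                             alpha = 0.05) {
  grouping <- match.arg(grouping, several.ok = TRUE)
  if (is.data.frame(summaries)) {
    d <- summaries
    if (!"f_peak" %in% names(d)) stop_validation("data frame needs an 'f_peak' column")
  } else {
    if (!is.list(summaries) || length(summaries) == 0) {
      stop_validation("'summaries' must be a non-empty list of force_summary objects")
    }
    ok <- vapply(summaries, inherits, logical(1), "force_summary")
    if (!all(ok)) stop_validation("all entries must be force_summary objects")
    d <- data.frame(
      f_peak = vapply(summaries, `[[`, numeric(1), "f_peak"),
      animal = vapply(summaries, function(s) as.character(s$animal_id), character(1)),
      day = vapply(summaries, function(s) as.character(s$day), character(1)),
      prey_size = vapply(summaries, function(s) as.character(s$prey_size_class), character(1))
    )
  }
  out <- list()
  for (g in grouping) {
    if (!g %in% names(d)) stop_validation(sprintf("grouping column '%s' not found", g))
    fac <- factor(d[[g]])
    tab <- data.frame(
      group = levels(fac),
      n = as.vector(table(fac)),
      mean = as.vector(tapply(d$f_peak, fac, mean)),
      sd = as.vector(tapply(d$f_peak, fac, sd))
    )
    if (nlevels(fac) < 2L) {
      out[[g]] <- list(table = tab, p_value = NA_real_, significant = NA,
                       note = "single group: test skipped")
      message(sprintf("aggregate_forces: single '%s' group, test skipped", g))
    } else if (length(unique(d$f_peak)) == 1L) {
      # all observations tied: no evidence of any group effect
      out[[g]] <- list(table = tab, p_value = 1, significant = FALSE,
                       note = "all values tied; p set to 1")
    } else {
      kt <- kruskal.test(d$f_peak, fac)
      out[[g]] <- list(table = tab, p_value = kt$p.value,
                       significant = kt$p.value < alpha, note = NULL)
    }
  }
  structure(list(groups = out, alpha = alpha), class = "force_aggregate")
}

#' @export
print.force_aggregate <- function(x, ...) {
  for (g in names(x$groups)) {
    r <- x$groups[[g]]
    cat(sprintf("== %s (Kruskal-Wallis p = %s%s) ==\n", g,
                if (is.na(r$p_value)) "skipped" else format.pval(r$p_value, digits = 4),
                if (isTRUE(r$significant)) sprintf(", significant at %.2g", x$alpha) else ""))
    print(r$table, row.names = FALSE)
  }
  invisible(x)
}
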