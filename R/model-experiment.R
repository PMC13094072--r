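## Physical-model trial analysis: per-trial maximum tensile force and
## post-release tracked-point speed, then the study's mixed-effects models
##
##   log(force) ~ type * friction + (1 | sample)
##   velocity   ~ type * friction + (1 | sample)
##
## with sum-to-zero factor coding, type III tests (Satterthwaite df),
## estimated marginal means per type x friction cell, and unadjusted
## pairwise high-vs-low-friction contrasts within each type.

#' Maximum tensile force of a model trial
#'
#' The release is detected as the first sample whose force has dropped by
#' more than 50% from the running maximum; the trial maximum is the largest
#' force before that sample (first occurrence on ties). A trace that never
#' drops triggers a no-release warning.
#'
#' @param trial a `model_trial` (see [generate_model_study()]) or any list
#'   with `force = list(t, f)`.
#' @return maximum tensile force, N.
#' @export
trial_max_force <- function(trial) {
  f <- trial$force$f
  if (is.null(f) || length(f) == 0) stop_validation("trial has an empty force trace")
  runmax <- cummax(f)
  drop_at <- which(f < 0.5 * runmax & runmax > 0)
  if (length(drop_at) == 0L) {
    warning("no release detected in force trace (force never drops > 50% from its running maximum)",
            call. = FALSE)
    return(max(f))
  }
  max(f[seq_len(drop_at[1] - 1L)])
}

# Index (into trial$force$t) of the last sample before the release drop, or
# NA when no release is present.
release_index <- function(trial) {
  f <- trial$force$f
  runmax <- cummax(f)
  drop_at <- which(f < 0.5 * runmax & runmax > 0)
  if (length(drop_at) == 0L) return(NA_integer_)
  drop_at[1] - 1L
}

#' Maximum post-release speed of the tracked point
#'
#' Maps the force-trace release instant onto the video time base (shared
#' wall-clock start, plus an optional offset), then reports the maximum
#' frame-to-frame linear speed of the tracked point from the release frame
#' onwards, converted with the trial's mm/pixel scale.
#'
#' @param trial a `model_trial`.
#' @param time_offset seconds added to the force-trace release time when
#'   mapping it to video frames.
#' @return maximum post-release speed, m/s.
#' @export
trial_max_velocity <- function(trial, time_offset = 0) {
  tr <- trial$track
  if (is.null(tr) || length(tr$x) < 3L) stop_validation("trial needs >= 3 tracked frames")
  if (is.null(trial$scale) || is.na(trial$scale)) stop_config("trial has no mm/pixel scale")
  if (anyNA(tr$x) || anyNA(tr$y)) {
    stop_validation("tracking gap (NA coordinates) in trial track")
  }
  ri <- release_index(trial)
  t_release <- if (is.na(ri)) 0 else trial$force$t[ri] + time_offset
  release_frame <- max(0L, as.integer(round(t_release * trial$fps))) # 0-based
  steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) # px per frame; steps[j]: frame j-1 -> j
  speeds <- steps * trial$fps * trial$scale / 1000 # m/s
  from <- min(release_frame + 1L, length(speeds))
  max(speeds[from:length(speeds)])
}

#' Summarize a model study into a trial table
#'
#' @param trials a `model_study` (list of `model_trial`s).
#' @return data frame with one row per trial: `type`, `friction`, `sample`,
#'   `rep`, `max_force` (N), `max_velocity` (m/s).
#' @export
trial_summaries <- function(trials) {
  if (!is.list(trials) || length(trials) == 0) stop_validation("'trials' must be a non-empty list")
  rows <- lapply(trials, function(tr) {
    data.frame(type = tr$type, friction = tr$friction, sample = tr$sample_id,
               rep = tr$rep_id, max_force = trial_max_force(tr),
               max_velocity = trial_max_velocity(tr))
  })
  do.call(rbind, rows)
}

# Fit one response with lmerTest, type III ANOVA, EMMs and within-type
# friction contrasts. `log_response` flags the log transform (force).
fit_one_lme <- function(d, response, log_response, alpha) {
  d$.y <- if (log_response) log(d[[response]]) else d[[response]]
  if (log_response && any(d[[response]] <= 0)) {
    stop_validation(sprintf("'%s' must be strictly positive for the log transform", response))
  }
  # Sum-to-zero coding makes the type III tests invariant to level order.
  d$type <- factor(d$type)
  d$friction <- factor(d$friction)
  contrasts(d$type) <- contr.sum(nlevels(d$type))
  contrasts(d$friction) <- contr.sum(nlevels(d$friction))
  fit_expr <- quote(lmerTest::lmer(.y ~ type * friction + (1 | sample), data = d))
  degenerate <- var(d$.y) < 1e-12
  m <- if (degenerate) suppressWarnings(suppressMessages(eval(fit_expr))) else eval(fit_expr)
  an <- as.data.frame(anova(m, type = "III"))
  an <- cbind(term = rownames(an), an)
  rownames(an) <- NULL
  names(an) <- c("term", "sum_sq", "mean_sq", "num_df", "den_df", "f_value", "p_value")
  emm <- emmeans::emmeans(m, ~ friction | type, lmer.df = "satterthwaite")
  emm_df <- as.data.frame(emm)
  ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "none"))
  vc <- as.data.frame(lme4::VarCorr(m))
  list(model = m, response = response, log_response = log_response,
       coefficients = data.frame(term = names(lme4::fixef(m)),
                                 estimate = unname(lme4::fixef(m)),
                                 se = unname(sqrt(diag(as.matrix(stats::vcov(m)))))),
       anova = an, emmeans = emm_df, contrasts = ctr,
       random_intercept_var = vc$vcov[vc$grp == "sample"][1],
       alpha = alpha)
}

#' Fit the type x friction mixed-effects models
#'
#' Fits `log(max_force) ~ type * friction + (1 | sample)` and
#' `max_velocity ~ type * friction + (1 | sample)` to a trial table,
#' evaluating the fixed effects with type III analysis of variance
#' (Satterthwaite degrees of freedom), and quantifying friction effects
#' within each trochanter type via estimated marginal means and unadjusted
#' pairwise contrasts. Significance is judged at `alpha`.
#'
#' @param summaries data frame from [trial_summaries()] (columns `type`,
#'   `friction`, `sample`, `max_force`, `max_velocity`).
#' @param alpha significance level (default 0.05).
#' @return an object of class `trial_models` with components `force` and
#'   `velocity`, each holding the fitted model, type III ANOVA, EMMs,
#'   contrasts and the sample random-intercept variance.
#' @export
fit_trial_models <- function(summaries, alpha = 0.05) {
  need <- c("type", "friction", "sample", "max_force", "max_velocity")
  if (!is.data.frame(summaries) || !all(need %in% names(summaries))) {
    stop_validation(sprintf("'summaries' needs columns: %s", paste(need, collapse = ", ")))
  }
  if (length(unique(summaries$type)) < 2L || length(unique(summaries$friction)) < 2L) {
    stop_validation("both trochanter types and both friction scenarios must be present")
  }
  cells <- table(summaries$type, summaries$friction)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop_validation(sprintf("rank-deficient design: empty cell %s x %s",
                            rownames(cells)[empty[1, 1]], colnames(cells)[empty[1, 2]]))
  }
  for (tp in unique(summaries$type)) {
    if (length(unique(summaries$sample[summaries$type == tp])) < 2L) {
      stop_validation(sprintf("need >= 2 samples for type %s", tp))
    }
  }
  structure(list(
    force = fit_one_lme(summaries, "max_force", log_response = TRUE, alpha = alpha),
    velocity = fit_one_lme(summaries, "max_velocity", log_response = FALSE, alpha = alpha),
    n_trials = nrow(summaries), alpha = alpha
  ), class = "trial_models")
}

fmt_p <- function(p) {
  # fixed decimal formatting; never locale/scientific dependent
  ifelse(is.na(p), "NA", ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p)))
}

#' @export
print.trial_models <- function(x, ...) {
  for (nm in c("force", "velocity")) {
    r <- x[[nm]]
    cat(sprintf("== %s%s ~ type * friction + (1|sample), n = %d ==\n",
                if (r$log_response) "log " else "", r$response, x$n_trials))
    an <- r$anova
    for (i in seq_len(nrow(an))) {
      cat(sprintf("  %-14s F(%g, %.1f) = %8.3f, p = %s\n", an$term[i],
                  an$num_df[i], an$den_df[i], an$f_value[i], fmt_p(an$p_value[i])))
    }
    cat(sprintf("  sample random-intercept variance: %.4g\n", r$random_intercept_var))
    ctr <- r$contrasts
    for (i in seq_len(nrow(ctr))) {
      cat(sprintf("  %s [%s]: estimate %.4g, p = %s\n", ctr$contrast[i],
                  ctr$type[i], ctr$estimate[i], fmt_p(ctr$p.value[i])))
    }
  }
  invisible(x)
}

#' Render mixed-model results as tables
#'
#' Writes coefficient, type III ANOVA, EMM and contrast tables for both
#' responses as CSVs plus a human-readable `report.txt` (p-values in fixed
#' decimal formatting).
#'
#' @param results a [fit_trial_models()] result.
#' @param out_dir output directory.
#' @return invisibly, the named list of tables written.
#' @export
model_report <- function(results, out_dir) {
  if (!inherits(results, "trial_models")) stop_validation("'results' must be a trial_models object")
  tables <- list()
  for (nm in c("force", "velocity")) {
    r <- results[[nm]]
    tables[[paste0(nm, "_coefficients")]] <- r$coefficients
    tables[[paste0(nm, "_anova")]] <- r$anova
    tables[[paste0(nm, "_emmeans")]] <- r$emmeans
    tables[[paste0(nm, "_contrasts")]] <- r$contrasts
  }
  write_results(tables, out_dir)
  txt <- utils::capture.output(print(results))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(tables)
}
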