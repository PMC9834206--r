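.outcome_map <- list(
  steps = list(y = "mean_daily_steps", trt = "trt_step",
               prev = "prev_week_steps"),
  sleep = list(y = "mean_daily_sleep_min", trt = "trt_sleep",
               prev = "prev_week_sleep"),
  mood = list(y = "mean_mood", trt = "trt_any", prev = "prev_week_mood"),
  participation_steps = list(y = "participation_rate_steps", trt = "trt_any",
                             prev = NULL),
  participation_sleep = list(y = "participation_rate_sleep", trt = "trt_any",
                             prev = NULL)
)

build_wcls_formula <- function(outcome) {
  m <- .outcome_map[[outcome]]
  rhs <- c("week", "pct_female", "baseline_mean_steps", "baseline_mean_sleep",
           "baseline_mean_phq9", m$prev)
  stats::as.formula(paste(m$y, "~", paste(rhs, collapse = " + ")),
                    env = globalenv())
}

#' Standard causal-effect models on the team-week table
#'
#' Convenience wrappers around [wcls()] using the trial's standard control
#' set (week-in-study, percent female, team baseline means of steps, sleep
#' and PHQ-9, and the previous week's outcome).  The treatment indicator is
#' the matching competition type for the step and sleep outcomes
#' (`trt_step`, `trt_sleep`) and any competition for mood and the
#' participation rates (`trt_any`).
#'
#' * `wcls_marginal()` — marginal (week-averaged) effect, no moderators.
#' * `wcls_week_moderation()` — adds the centered-treatment-by-week
#'   interaction; the treatment main term is then the week-0 effect and the
#'   interaction is the per-week change.
#' * `wcls_pairing_moderation()` — adds centered-treatment interactions
#'   with the intra-institution and intra-specialty pairing flags.
#' * `wcls_participation()` — linear probability model for the weekly
#'   participation rate (fit on non-imputed data: participation *is* the
#'   missingness process); coefficients are risk differences.
#'
#' @param data team-week table from [aggregate_team_week()].
#' @param outcome one of `"steps"`, `"sleep"`, `"mood"` (or for
#'   `wcls_participation()`, `"steps"`/`"sleep"` meaning that outcome's
#'   participation rate).
#' @param ... further arguments passed to [wcls()] (e.g. `weights`,
#'   `prob`, `prob_tilde`).
#' @return A `"wcls"` fit.
#' @export
wcls_marginal <- function(data, outcome = c("steps", "sleep", "mood"), ...) {
  outcome <- match.arg(outcome)
  fit <- wcls(build_wcls_formula(outcome), data,
              treatment = .outcome_map[[outcome]]$trt, cluster = "team_id",
              ...)
  fit$call <- match.call()
  fit
}

#' @rdname wcls_marginal
#' @export
wcls_week_moderation <- function(data, outcome = c("steps", "sleep", "mood"),
                                 ...) {
  outcome <- match.arg(outcome)
  fit <- wcls(build_wcls_formula(outcome), data,
              treatment = .outcome_map[[outcome]]$trt, cluster = "team_id",
              moderator = ~ week, ...)
  fit$call <- match.call()
  fit
}

#' @rdname wcls_marginal
#' @export
wcls_pairing_moderation <- function(data,
                                    outcome = c("steps", "sleep", "mood"),
                                    ...) {
  outcome <- match.arg(outcome)
  fit <- wcls(build_wcls_formula(outcome), data,
              treatment = .outcome_map[[outcome]]$trt, cluster = "team_id",
              moderator = ~ intra_institution + intra_specialty,
              drop_aliased = TRUE, ...)
  fit$call <- match.call()
  fit
}

#' @rdname wcls_marginal
#' @export
wcls_participation <- function(data, outcome = c("steps", "sleep"), ...) {
  outcome <- match.arg(outcome)
  key <- paste0("participation_", outcome)
  fit <- wcls(build_wcls_formula(key), data,
              treatment = .outcome_map[[key]]$trt, cluster = "team_id", ...)
  fit$call <- match.call()
  fit
}

#' Moderated causal effect at a given study week
#'
#' Evaluates a linear time-varying causal effect at a 1-indexed study week:
#' with the week-in-study coded from 0 (first week) to 11 (final week), the
#' effect during week number `w` is `beta0 + beta_week * (w - 1)`.  For
#' example, a week-0 step effect of 185.3 decaying by 14.5 steps per week
#' gives 112.8 additional steps/day during the sixth week and 25.8 during
#' the twelfth.
#'
#' @param beta0 effect at week 0 (the treatment main term of a
#'   week-moderated fit).
#' @param beta_week per-week change (the treatment-by-week interaction).
#' @param week_number 1-indexed week of the study (>= 1).
#' @param vcov optional 2x2 covariance of `(beta0, beta_week)`; when given,
#'   a delta-method `"se"` attribute is attached.
#' @return The moderated effect (numeric), optionally with an `"se"`
#'   attribute.
#' @examples
#' effect_at_week(185.3, -14.5, 6)   # 112.8
#' effect_at_week(185.3, -14.5, 12)  # 25.8
#' @export
effect_at_week <- function(beta0, beta_week, week_number, vcov = NULL) {
  if (any(week_number < 1) || any(week_number != round(week_number)))
    stop("week_number must be an integer >= 1", call. = FALSE)
  est <- beta0 + beta_week * (week_number - 1)
  if (!is.null(vcov)) {
    g <- cbind(1, week_number - 1)
    attr(est, "se") <- sqrt(rowSums((g %*% vcov) * g))
  }
  est
}

#' Person-days of additional data from a participation-rate effect
#'
#' Converts a causal effect on the daily participation rate into the number
#' of additional person-day records a full competition week would yield:
#' `round(n_participants * rate_effect * days)`.  A 0.3% step-participation
#' effect over 1779 interns is 37 additional person-days of step count in a
#' week; a 0.9% sleep effect is 112.
#'
#' @param n_participants number of participants.
#' @param rate_effect participation-rate difference (proportion, in
#'   `[-1, 1]`).
#' @param days days per episode (default 7).
#' @return Integer count of person-days.
#' @examples
#' person_days_gain(1779, 0.003)  # 37
#' person_days_gain(1779, 0.009)  # 112
#' @export
person_days_gain <- function(n_participants, rate_effect, days = 7) {
  stopifnot(rate_effect >= -1, rate_effect <= 1)
  as.integer(round(n_participants * rate_effect * days))
}

#' Stage percentages along a study-flow exclusion chain
#'
#' Given ordered, nonincreasing stage counts (invited, enrolled, grouped,
#' analyzed, ...), returns each stage's percentage of the preceding stage,
#' rounded to one decimal — the numbers printed in a recruitment flow
#' diagram.
#'
#' @param counts nonincreasing integer vector of stage counts.
#' @return Numeric vector, same length, `NA` for the first stage.
#' @examples
#' study_flow(c(4791, 2286, 1936, 1779))  # NA 47.7 84.7 91.9
#' @export
study_flow <- function(counts) {
  if (length(counts) < 1) stop("empty counts", call. = FALSE)
  if (any(diff(counts) > 0))
    stop("stage counts must be nonincreasing", call. = FALSE)
  c(NA_real_, round(100 * counts[-1] / counts[-length(counts)], 1))
}

#' Pool estimates across multiply imputed datasets by Rubin's rules
#'
#' Combines per-imputation estimates and standard errors: the pooled
#' estimate is the mean of the `M` estimates; the total variance is the
#' within-imputation variance `W` plus `(1 + 1/M)` times the
#' between-imputation variance `B`; degrees of freedom use Rubin's
#' small-sample formula `(M - 1)(1 + W / ((1 + 1/M) B))^2`, and two-sided
#' p-values come from the t distribution on those df (normal when `B = 0`).
#'
#' @param fits either a list of `"wcls"` fits (pooled coefficient-wise), or
#'   a numeric vector/matrix of estimates (imputations in rows).
#' @param ses standard errors matching `fits` when `fits` is numeric.
#' @param level confidence level for the reported interval.
#' @return A data frame of class `"mi_pooled"` with one row per term:
#'   `estimate`, `within_var`, `between_var`, `total_var`, `se`, `df`,
#'   `statistic`, `p`, `lower`, `upper`, plus attribute `M`.
#' @examples
#' pool_rubin(c(1, 3), c(1, 1))  # estimate 2, se 2
#' @export
pool_rubin <- function(fits, ses = NULL, level = 0.95) {
  if (is.list(fits) && length(fits) && inherits(fits[[1]], "wcls")) {
    est <- do.call(rbind, lapply(fits, coef))
    ses <- do.call(rbind, lapply(fits, function(f) sqrt(diag(vcov(f)))))
  } else if (is.null(dim(fits))) {
    est <- cbind(estimate = as.numeric(fits))
    ses <- cbind(as.numeric(ses))
  } else {
    est <- as.matrix(fits)
    ses <- as.matrix(ses)
  }
  if (is.null(ses) || any(dim(est) != dim(ses)))
    stop("estimates and standard errors must have matching shape",
         call. = FALSE)
  M <- nrow(est)
  if (M < 1) stop("need at least one imputation", call. = FALSE)
  if (!all(is.finite(est)) || !all(is.finite(ses)))
    stop("non-finite estimates or standard errors", call. = FALSE)

  qbar <- colMeans(est)
  Wv <- colMeans(ses^2)
  Bv <- if (M > 1) apply(est, 2, stats::var) else rep(0, ncol(est))
  Tv <- Wv + (1 + 1 / M) * Bv
  se <- sqrt(Tv)
  df <- ifelse(Bv > 0 & M > 1,
               (M - 1) * (1 + Wv / ((1 + 1 / M) * Bv))^2, Inf)
  stat <- ifelse(se > 0, qbar / se, 0)
  pval <- 2 * stats::pt(-abs(stat), df)
  q <- stats::qt(1 - (1 - level) / 2, df)
  out <- data.frame(
    term = if (!is.null(colnames(est))) colnames(est)
           else paste0("par", seq_along(qbar)),
    estimate = qbar, within_var = Wv, between_var = Bv, total_var = Tv,
    se = se, df = df, statistic = stat, p = pval,
    lower = qbar - q * se, upper = qbar + q * se,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "M") <- M
  class(out) <- c("mi_pooled", "data.frame")
  out
}

#' @export
print.mi_pooled <- function(x, digits = 4, ...) {
  cat("Rubin-pooled estimates over", attr(x, "M"), "imputations\n")
  print.data.frame(
    cbind(x["term"],
          round(x[c("estimate", "se", "df", "statistic", "p",
                    "lower", "upper")], digits)),
    row.names = FALSE)
  invisible(x)
}
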