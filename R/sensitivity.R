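#' Nonlinear (spline) time-varying moderation of the causal effect
#'
#' Relaxes the linearity-in-week assumption of the moderated model by
#' letting the causal effect of competition vary with week-in-study through
#' a flexible function `f`: the treatment part of the model becomes
#' \eqn{(A - \tilde p) f(week)}.  Two bases are available:
#' \describe{
#'   \item{`"tp"`}{penalized thin-plate regression spline, smoothing
#'     selected by REML (via [mgcv::gam()] with a varying-coefficient
#'     `by =` smooth); pointwise intervals use the smooth's Bayesian
#'     covariance.}
#'   \item{`"ns"`}{unpenalized natural cubic basis of dimension `df`
#'     (an intercept plus `df - 1` natural-spline columns) inside the
#'     WCLS fit, with cluster-robust pointwise intervals.  `df = 2`
#'     reproduces the linear moderated fit exactly, since a natural cubic
#'     spline with no interior knots is a straight line.}
#' }
#'
#' @param data team-week table from [aggregate_team_week()].
#' @param outcome `"steps"` or `"sleep"`.
#' @param basis `"tp"` (default) or `"ns"`.
#' @param df basis dimension of `f` including its intercept (default 6;
#'   must be >= 2 and at most the number of distinct weeks).
#' @param prob,prob_tilde randomization and centering probabilities.
#' @param weeks grid on which to evaluate the effect curve.
#' @return An `"effect_curve"` data frame (`week`, `estimate`, `se`,
#'   `lower`, `upper`), with the underlying fit in attribute `"fit"`.
#' @export
fit_spline_moderation <- function(data, outcome = c("steps", "sleep"),
                                  basis = c("tp", "ns"), df = 6,
                                  prob = 0.5, prob_tilde = 0.5,
                                  weeks = NULL) {
  outcome <- match.arg(outcome)
  basis <- match.arg(basis)
  nweeks <- length(unique(data$week))
  if (df < 2) stop("df must be >= 2", call. = FALSE)
  if (df > nweeks)
    stop("df (", df, ") exceeds the number of distinct weeks (", nweeks, ")",
         call. = FALSE)
  if (is.null(weeks)) weeks <- sort(unique(data$week))
  m <- .outcome_map[[outcome]]

  if (basis == "ns") {
    # the control model must span the effect basis: when the centering
    # probability differs from the realized randomization probability, any
    # moderator term missing from the controls leaks a spurious week shape
    # into the effect curve
    mod <- if (df == 2) ~ week else
      stats::as.formula(sprintf("~ splines::ns(week, df = %d)", df - 1),
                        env = globalenv())
    ctrl <- build_wcls_formula(outcome)
    if (df > 2)   # ns basis spans the linear trend; swap it in for `week`
      ctrl <- stats::update(ctrl, stats::as.formula(
        sprintf(". ~ . - week + splines::ns(week, df = %d)", df - 1)))
    fit <- wcls(ctrl, data, treatment = m$trt,
                cluster = "team_id", moderator = mod,
                prob = prob, prob_tilde = prob_tilde)
    out <- effect_curve(fit, weeks)
  } else {
    d <- data
    d$.y <- d[[m$y]]
    d$.Ac <- d[[m$trt]] - rep_len(prob_tilde, nrow(d))
    keep <- stats::complete.cases(
      d[, c(".y", "week", "pct_female", "baseline_mean_steps",
            "baseline_mean_sleep", "baseline_mean_phq9", m$prev)])
    d <- d[keep, ]
    d$.prev <- d[[m$prev]]
    A <- d[[m$trt]]
    p <- rep_len(prob, nrow(d)); pt <- rep_len(prob_tilde, nrow(d))
    d$.w <- ifelse(A == 1, pt / p, (1 - pt) / (1 - p))
    d$.team <- factor(d$team_id)
    # team random intercept accounts for within-team correlation; intervals
    # use the smoothing-uncertainty-corrected covariance when available
    fit <- mgcv::gam(
      .y ~ s(week, k = df, bs = "tp") + pct_female + baseline_mean_steps +
        baseline_mean_sleep + baseline_mean_phq9 + .prev +
        s(.team, bs = "re") + s(week, by = .Ac, k = df, bs = "tp"),
      data = d, weights = .w, method = "REML")
    nd <- data.frame(week = weeks, pct_female = 0, baseline_mean_steps = 0,
                     baseline_mean_sleep = 0, baseline_mean_phq9 = 0,
                     .prev = 0, .Ac = 1, .team = d$.team[1])
    Xp <- stats::predict(fit, nd, type = "lpmatrix")
    sm <- grep("^s\\(week\\):", colnames(Xp))
    est <- drop(Xp[, sm, drop = FALSE] %*% stats::coef(fit)[sm])
    Vfull <- if (!is.null(fit$Vc)) fit$Vc else fit$Vp
    Vp <- Vfull[sm, sm, drop = FALSE]
    se <- sqrt(rowSums((Xp[, sm, drop = FALSE] %*% Vp) *
                         Xp[, sm, drop = FALSE]))
    out <- data.frame(week = weeks, estimate = est, se = se,
                      lower = est - 1.96 * se, upper = est + 1.96 * se)
    class(out) <- c("effect_curve", "data.frame")
  }
  attr(out, "fit") <- fit
  attr(out, "basis") <- basis
  out
}

#' Complete-case filtering of imputed data for interns who dropped out
#'
#' For the dropout sensitivity analysis: removes (re-masks as `NA`) every
#' imputed value after an intern's last observed data point, so interns who
#' left the study early contribute no imputed tail.
#'
#' @param imputed a completed record data frame (one imputation) or a list
#'   of them.
#' @param observed the pre-imputation records with `NA`s, defining each
#'   intern's last observed day (any outcome).
#' @return Filtered dataset(s) of the same shape; idempotent.
#' @export
complete_case_dropout <- function(imputed, observed) {
  if (is.list(imputed) && !is.data.frame(imputed))
    return(lapply(imputed, complete_case_dropout, observed = observed))
  any_obs <- !is.na(observed$steps) | !is.na(observed$sleep_min) |
    !is.na(observed$mood)
  obs_days <- observed$day_index[any_obs]
  obs_ids <- observed$intern_id[any_obs]
  last_day <- tapply(obs_days, obs_ids, max)
  ld <- last_day[imputed$intern_id]
  ld[is.na(ld)] <- -1                      # no data at all: mask everything
  mask <- imputed$day_index > ld
  imputed$steps[mask] <- NA_real_
  imputed$sleep_min[mask] <- NA_real_
  imputed$mood[mask] <- NA_real_
  imputed
}

#' Drop team-weeks with heavy weekly missingness
#'
#' For the weekly-missingness complete-case analysis: removes team-week
#' rows where more than `max_missing` person-days of the outcome were
#' unobserved.
#'
#' @param team_week team-week table from [aggregate_team_week()] computed
#'   on the *observed* (non-imputed) records, so its participation rates
#'   reflect true missingness.
#' @param outcome `"steps"` or `"sleep"`.
#' @param max_missing maximum tolerated missing person-days per team-week
#'   (default 5); use `Inf` to keep everything.
#' @return The filtered team-week table; idempotent.
#' @export
complete_case_weekly <- function(team_week, outcome = c("steps", "sleep"),
                                 max_missing = 5) {
  outcome <- match.arg(outcome)
  pr <- team_week[[paste0("participation_rate_", outcome)]]
  missing_days <- (1 - pr) * 7 * team_week$n_members
  team_week[missing_days <= max_missing + 1e-9, , drop = FALSE]
}

#' Compare multiple-imputation and complete-case causal estimates
#'
#' Runs the same causal model through both missing-data treatments on one
#' simulated (or supplied) trial: the multiple-imputation pipeline (impute
#' daily records, aggregate each completed dataset, fit, pool by Rubin's
#' rules) and the complete-case pipeline (aggregate the observed records,
#' fit once).  Reports the paired estimates, standard errors and the
#' standardized difference for each causal term.
#'
#' @param trial a trial list as returned by [simulate_trial()] (components
#'   `records`, `interns`, `assignments`).
#' @param outcome `"steps"` or `"sleep"`.
#' @param moderator moderator formula passed to [wcls()].
#' @param M,n_sweeps,k_donors imputation settings (see [impute_pmm()]).
#' @return Data frame: `term`, `est_mi`, `se_mi`, `est_cc`, `se_cc`,
#'   `std_diff` (`(est_mi - est_cc) / sqrt(se_mi^2 + se_cc^2)`).
#' @export
compare_mi_vs_cc <- function(trial, outcome = c("steps", "sleep"),
                             moderator = ~ 1, M = 5, n_sweeps = 5,
                             k_donors = 5) {
  outcome <- match.arg(outcome)
  m <- .outcome_map[[outcome]]
  fit1 <- function(tw) wcls(build_wcls_formula(outcome), tw,
                            treatment = m$trt, cluster = "team_id",
                            moderator = moderator)
  tw_cc <- aggregate_team_week(trial$records, trial$interns,
                               trial$assignments)
  cc <- fit1(tw_cc)
  imps <- impute_pmm(trial$records, trial$interns, M = M,
                     n_sweeps = n_sweeps, k_donors = k_donors)
  fits <- lapply(imps, function(r)
    fit1(aggregate_team_week(r, trial$interns, trial$assignments)))
  pooled <- pool_rubin(fits)
  bt <- cc$beta_terms
  i <- match(bt, pooled$term)
  data.frame(
    term = bt,
    est_mi = pooled$estimate[i], se_mi = pooled$se[i],
    est_cc = coef(cc)[bt], se_cc = sqrt(diag(vcov(cc)))[bt],
    std_diff = (pooled$estimate[i] - coef(cc)[bt]) /
      sqrt(pooled$se[i]^2 + diag(vcov(cc))[bt]),
    row.names = NULL, stringsAsFactors = FALSE)
}
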