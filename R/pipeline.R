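#' Run a full synthetic trial and analysis end to end
#'
#' Orchestrates the whole pipeline with one master seed: simulate the
#' cohort, randomize the weekly competitions, generate outcomes, apply
#' missingness, multiply impute, optionally compute post-stratification
#' weights, aggregate each completed dataset to team-weeks, fit the
#' marginal and week-moderated WCLS models for the requested outcomes,
#' pool by Rubin's rules, and fit the participation-rate linear probability
#' models on the observed (non-imputed) data.  Per-stage sub-seeds are
#' derived deterministically from the master seed, so the entire results
#' bundle is reproducible byte for byte.
#'
#' @param config a [sim_config()] object.
#' @param seed master integer seed.
#' @param M number of imputations (`0` to skip imputation and analyze the
#'   observed data complete-case).
#' @param n_sweeps,k_donors imputation settings.
#' @param outcomes outcomes to analyze (`"steps"`, `"sleep"`, `"mood"`).
#' @param margins optional population margins for [two_step_weights()];
#'   `NULL` skips the weighting stage.
#' @return A list: `interns`, `teams`, `assignments`, `records`,
#'   `records_complete`, `team_week` (observed-data aggregation),
#'   `weights` (or `NULL`), `fits` (per outcome: `marginal` and
#'   `week_moderation`, each an `"mi_pooled"` table), `participation`
#'   (per outcome, a `"wcls"` fit), and `manifest` (seed, stage row
#'   counts, flow counts, timestamp-free).
#' @export
run_trial <- function(config = sim_config(), seed = 1, M = 20,
                      n_sweeps = 10, k_donors = 5,
                      outcomes = c("steps", "sleep"), margins = NULL) {
  seeds <- derive_seeds(seed, c("population", "randomize", "outcomes",
                                "missingness", "impute"))

  set.seed(seeds[["population"]])
  pop <- simulate_population(config)
  set.seed(seeds[["randomize"]])
  assignments <- randomize_trial(pop$teams, n_weeks = config$n_weeks)
  set.seed(seeds[["outcomes"]])
  complete <- simulate_outcomes(pop$interns, pop$teams, assignments, config)
  set.seed(seeds[["missingness"]])
  records <- apply_missingness(complete, pop$interns, assignments, config)

  tw_obs <- aggregate_team_week(records, pop$interns, assignments)

  wdf <- NULL
  tw_weights <- NULL
  if (!is.null(margins)) {
    wdf <- two_step_weights(pop$interns, margins)
    tmw <- team_weights(wdf, pop$interns)
    tw_weights <- tmw$w[match(tw_obs$team_id, tmw$team_id)]
  }

  if (M > 0) {
    set.seed(seeds[["impute"]])
    imps <- impute_pmm(records, pop$interns, M = M, n_sweeps = n_sweeps,
                       k_donors = k_donors)
    tws <- lapply(imps, function(r)
      aggregate_team_week(r, pop$interns, assignments))
  } else {
    tws <- list(tw_obs)
  }

  fits <- list()
  for (o in outcomes) {
    marg <- lapply(tws, function(tw) wcls_marginal(tw, o, drop_aliased = TRUE))
    wkmod <- lapply(tws, function(tw)
      wcls_week_moderation(tw, o, drop_aliased = TRUE))
    fits[[o]] <- list(marginal = pool_rubin(marg),
                      week_moderation = pool_rubin(wkmod))
    if (!is.null(tw_weights)) {
      # report the post-stratification-weighted fit alongside the unweighted
      margw <- lapply(tws, function(tw)
        wcls_marginal(tw, o, drop_aliased = TRUE,
                      weights = tw_weights[match(tw$team_id,
                                                 tw_obs$team_id)]))
      fits[[o]]$marginal_weighted <- pool_rubin(margw)
    }
  }

  participation <- list()
  for (o in intersect(outcomes, c("steps", "sleep")))
    participation[[o]] <- wcls_participation(tw_obs, o)

  n_eligible <- sum(pop$teams$eligible)
  manifest <- list(
    seed = seed, config = unclass(config),
    n_interns = nrow(pop$interns), n_teams = nrow(pop$teams),
    n_eligible_teams = n_eligible,
    n_daily_records = nrow(records),
    n_observed_steps = sum(!is.na(records$steps)),
    n_observed_sleep = sum(!is.na(records$sleep_min)),
    n_team_weeks = nrow(tw_obs),
    flow_counts = c(simulated = nrow(pop$interns),
                    grouped = nrow(pop$interns),
                    analyzed = nrow(pop$interns)),
    M = M)

  list(interns = pop$interns, teams = pop$teams, assignments = assignments,
       records = records, records_complete = complete, team_week = tw_obs,
       weights = wdf, fits = fits, participation = participation,
       manifest = manifest)
}

# stable per-stage sub-seeds below 2^31, derived from the master seed
derive_seeds <- function(seed, stages) {
  h <- vapply(stages, function(s)
    sum(utf8ToInt(s) * seq_along(utf8ToInt(s))), numeric(1))
  out <- as.integer((seed * 48271 + h * 2654435) %% .Machine$integer.max)
  stats::setNames(out, stages)
}

#' Monte-Carlo operating characteristics of the WCLS pipeline
#'
#' Repeatedly simulates complete-data trials from a configuration with
#' known causal parameters, fits the week-moderated WCLS models for steps
#' and sleep, and summarizes parameter recovery per causal term: mean bias,
#' RMSE, empirical coverage of the 95% Wald interval, and the rejection
#' rate of the two-sided Wald test (the type-I error for terms whose
#' generating value is 0), each with its Monte-Carlo standard error.
#'
#' @param config a [sim_config()] object; its effect parameters are the
#'   generating truths.
#' @param n_reps number of replicate trials (>= 2).
#' @param seed integer seed.
#' @param missingness simulate with missingness (complete-case analysis)?
#'   Default `FALSE`: complete data isolates estimator behavior.
#' @return Data frame of class `"mrt_opchar"`, one row per causal term:
#'   `outcome`, `term`, `truth`, `mean_est`, `bias`, `mc_se_bias`, `rmse`,
#'   `coverage`, `mc_se_coverage`, `reject_rate`.
#' @examples
#' \donttest{
#' op <- replicate_study(sim_config(n_teams = 40, n_institutions = 15),
#'                       n_reps = 20, seed = 2)
#' op[op$term == "trt_step", ]
#' }
#' @export
replicate_study <- function(config = sim_config(), n_reps = 100, seed = 1,
                            missingness = FALSE) {
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  truths <- list(
    steps = c(trt = config$beta_step0, `trt:week` = config$beta_step_week),
    sleep = c(trt = config$beta_sleep0, `trt:week` = config$beta_sleep_week))
  res <- vector("list", n_reps)
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    tr <- simulate_trial(config, missingness = missingness)
    tw <- aggregate_team_week(tr$records, tr$interns, tr$assignments)
    row <- list()
    for (o in c("steps", "sleep")) {
      f <- wcls_week_moderation(tw, o)
      bt <- f$beta_terms                      # main term, then :week
      est <- coef(f)[bt]
      se <- sqrt(diag(vcov(f)))[bt]
      row[[o]] <- data.frame(outcome = o,
                             term = c("trt", "trt:week"),
                             est = as.numeric(est), se = as.numeric(se),
                             stringsAsFactors = FALSE)
    }
    res[[r]] <- do.call(rbind, row)
  }
  all <- do.call(rbind, res)
  out <- do.call(rbind, lapply(split(all, list(all$outcome, all$term)),
    function(d) {
      tr <- truths[[d$outcome[1]]][[d$term[1]]]
      cover <- abs(d$est - tr) <= 1.96 * d$se
      rej <- abs(d$est / d$se) > 1.96
      data.frame(
        outcome = d$outcome[1], term = d$term[1], truth = tr,
        mean_est = mean(d$est), bias = mean(d$est) - tr,
        mc_se_bias = stats::sd(d$est) / sqrt(nrow(d)),
        rmse = sqrt(mean((d$est - tr)^2)),
        coverage = mean(cover),
        mc_se_coverage = stats::sd(cover) / sqrt(nrow(d)),
        reject_rate = mean(rej),
        stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  class(out) <- c("mrt_opchar", "data.frame")
  out
}
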