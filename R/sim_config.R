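#' Simulation configuration for a synthetic team-competition trial
#'
#' Builds and validates the full set of generative parameters for a synthetic
#' cluster micro-randomized trial: cohort structure (teams, institutions,
#' specialties), baseline covariate distributions, the causal excursion
#' effects of weekly competition on daily step count and sleep minutes
#' (a week-0 effect plus a linear per-week change, and pairing-rule
#' moderation offsets), secular time trends, a three-level Gaussian noise
#' hierarchy (team, intern, day) with AR(1) day-to-day dependence, and the
#' missingness process (daily missing-at-random probabilities, dependence on
#' the previous day's outcome, a participation uplift under competition, and
#' a weekly dropout hazard that grows over the study).
#'
#' Defaults reproduce the conditions of a 12-week trial of roughly 1779
#' interns in 191 teams across 90 institutions and 12 specialties: baseline
#' steps ~ N(8121, 3229), baseline sleep ~ N(420.6, 107.5), a step effect of
#' 185.3 steps/day at week 0 decaying by 14.5 steps per week, a sleep effect
#' of 9.8 min/day decaying by 1.9 min per week, and daily missingness above
#' 30\% for steps and 50\% for sleep once dropout is included.
#'
#' @param n_teams number of program-based teams to generate.
#' @param n_institutions number of residency institutions.
#' @param n_weeks number of weekly competition episodes (7 days each).
#' @param team_size_min,team_size_mean team sizes are drawn as
#'   `team_size_min + Poisson(team_size_mean - team_size_min)`.
#' @param specialty_probs named marginal distribution over specialties.
#' @param p_female probability an intern is female.
#' @param race_probs named marginal distribution over race categories.
#' @param age_mean,age_sd age distribution (years).
#' @param p_fitbit probability of a Fitbit (vs Apple Watch) device.
#' @param baseline_steps_mean,baseline_steps_sd pre-internship daily steps.
#' @param baseline_sleep_mean,baseline_sleep_sd pre-internship daily sleep
#'   minutes (clipped to `[0, 1440]`).
#' @param phq9_mean,phq9_sd PHQ-9 depressive-symptom score (rounded,
#'   clipped to `[0, 27]`).
#' @param beta_step0,beta_step_week causal effect of a step competition on
#'   daily steps at week 0 and its linear change per week-in-study.
#' @param beta_sleep0,beta_sleep_week same for a sleep competition on daily
#'   sleep minutes.
#' @param mod_intra_institution_step,mod_intra_specialty_step additive
#'   offsets to the step effect when the opponent shares the institution or
#'   the specialty.
#' @param mod_intra_institution_sleep,mod_intra_specialty_sleep same for the
#'   sleep effect.
#' @param mood_effect effect of being in any competition on the daily mood
#'   score (1-10 scale).
#' @param trend_step,trend_sleep secular change per week-in-study in steps
#'   and sleep minutes, applied to everyone.
#' @param step_shift,sleep_shift internship-onset shift from the
#'   pre-internship baseline level.
#' @param team_sd_step,team_sd_sleep,team_sd_mood SD of team-level random
#'   intercepts.
#' @param intern_sd_step,intern_sd_sleep,intern_sd_mood SD of intern-level
#'   random intercepts (on top of the intern's own baseline).
#' @param day_sd_step,day_sd_sleep,day_sd_mood SD of day-level noise.
#' @param ar1_rho AR(1) correlation of day-level noise within intern.
#' @param mood_mean latent mean of the daily mood score before clipping.
#' @param p_miss_step,p_miss_sleep,p_miss_mood marginal daily probability
#'   that the outcome is unrecorded (before dropout).
#' @param mar_coef_step,mar_coef_sleep,mar_coef_mood logit-scale shift in
#'   the missingness probability per SD of the previous day's outcome
#'   (negative: low values yesterday make today more likely missing).
#' @param uplift_step,uplift_sleep reduction (probability points) in daily
#'   missingness while the team is in any competition week — the
#'   participation-rate effect of competition.
#' @param dropout_hazard0,dropout_hazard_growth weekly dropout hazard
#'   `dropout_hazard0 * (1 + dropout_hazard_growth)^week`; after dropout all
#'   outcomes are missing for the rest of the study.
#' @param clip_outcomes clip daily steps at 0 and sleep to `[0, 1440]`
#'   (default `TRUE`).  Boundary censoring makes the generating coefficient
#'   differ slightly from the causal estimand (a few percent attenuation in
#'   low-count interns), so estimator-validation scenarios may switch it
#'   off to keep the generative model exactly linear; mood is always
#'   clipped to its 1-10 scale.
#'
#' @return An object of class `"sim_config"` (a named list).
#' @seealso [simulate_population()], [simulate_trial()]
#' @examples
#' cfg <- sim_config(n_teams = 10, n_institutions = 4)
#' cfg$n_teams
#' @export
sim_config <- function(n_teams = 191,
                       n_institutions = 90,
                       n_weeks = 12,
                       team_size_min = 5,
                       team_size_mean = 1779 / 191,
                       specialty_probs = c(
                         internal_medicine = 0.277, surgery = 0.135,
                         pediatrics = 0.121, emergency_medicine = 0.082,
                         psychiatry = 0.071, obgyn = 0.058,
                         anesthesiology = 0.053, family_medicine = 0.044,
                         neurology = 0.028, med_peds = 0.021,
                         transitional = 0.012, other = 0.099),
                       p_female = 0.545,
                       race_probs = c(
                         white = 0.538, asian = 0.236,
                         black = 0.060, hispanic = 0.054,
                         arab_middle_eastern = 0.017,
                         other_multiracial = 0.095),
                       age_mean = 27.6, age_sd = 2.6,
                       p_fitbit = 0.7,
                       baseline_steps_mean = 8121, baseline_steps_sd = 3228.9,
                       baseline_sleep_mean = 420.6, baseline_sleep_sd = 107.5,
                       phq9_mean = 3, phq9_sd = 3,
                       beta_step0 = 185.3, beta_step_week = -14.5,
                       beta_sleep0 = 9.8, beta_sleep_week = -1.9,
                       mod_intra_institution_step = -90.3,
                       mod_intra_specialty_step = 26.4,
                       mod_intra_institution_sleep = 0.1,
                       mod_intra_specialty_sleep = -1.5,
                       mood_effect = 0.02,
                       trend_step = -11.0, trend_sleep = 0.6,
                       step_shift = -450, sleep_shift = -5,
                       team_sd_step = 300, team_sd_sleep = 10,
                       team_sd_mood = 0.3,
                       intern_sd_step = 800, intern_sd_sleep = 25,
                       intern_sd_mood = 1.0,
                       day_sd_step = 2500, day_sd_sleep = 60,
                       day_sd_mood = 1.5,
                       ar1_rho = 0.3,
                       mood_mean = 7,
                       p_miss_step = 0.31, p_miss_sleep = 0.52,
                       p_miss_mood = 0.55,
                       mar_coef_step = -0.4, mar_coef_sleep = -0.4,
                       mar_coef_mood = -0.3,
                       uplift_step = 0.003, uplift_sleep = 0.009,
                       dropout_hazard0 = 0.004,
                       dropout_hazard_growth = 0.2,
                       clip_outcomes = TRUE) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  pos_int <- c("n_teams", "n_institutions", "n_weeks", "team_size_min")
  for (f in pos_int) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop("invalid config: '", f, "' must be a positive integer", call. = FALSE)
  }
  if (cfg$team_size_mean < cfg$team_size_min)
    stop("invalid config: 'team_size_mean' must be >= 'team_size_min'",
         call. = FALSE)
  sds <- grep("_sd$|^team_sd_|^intern_sd_|^day_sd_", names(cfg), value = TRUE)
  for (f in c(sds, "dropout_hazard_growth")) {
    if (cfg[[f]] < 0)
      stop("invalid config: '", f, "' must be >= 0", call. = FALSE)
  }
  probs <- c("p_female", "p_fitbit", "p_miss_step", "p_miss_sleep",
             "p_miss_mood", "uplift_step", "uplift_sleep", "dropout_hazard0")
  for (f in probs) {
    v <- cfg[[f]]
    if (v < 0 || v > 1)
      stop("invalid config: '", f, "' must be a probability in [0, 1]",
           call. = FALSE)
  }
  if (abs(cfg$ar1_rho) >= 1)
    stop("invalid config: 'ar1_rho' must be in (-1, 1)", call. = FALSE)
  for (f in c("specialty_probs", "race_probs")) {
    v <- cfg[[f]]
    if (is.null(names(v)) || any(v < 0) || abs(sum(v) - 1) > 0.02)
      stop("invalid config: '", f,
           "' must be a named nonnegative vector summing to 1", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cluster-MRT configuration\n")
  cat(sprintf("  %d teams (size >= %d, mean %.2f), %d institutions, %d specialties, %d weeks\n",
              x$n_teams, x$team_size_min, x$team_size_mean,
              x$n_institutions, length(x$specialty_probs), x$n_weeks))
  cat(sprintf("  step effect %.1f %+.1f/week; sleep effect %.1f %+.1f/week\n",
              x$beta_step0, x$beta_step_week, x$beta_sleep0, x$beta_sleep_week))
  cat(sprintf("  daily missingness: steps %.2f, sleep %.2f, mood %.2f (+ dropout)\n",
              x$p_miss_step, x$p_miss_sleep, x$p_miss_mood))
  invisible(x)
}
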