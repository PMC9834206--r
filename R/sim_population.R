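#' Generate a synthetic intern cohort grouped into teams
#'
#' Draws a population of interns organised into program-based teams
#' (program = institution x specialty), with baseline covariates matching
#' the configured marginal distributions.  Team sizes follow a shifted
#' Poisson with the configured minimum, institutions are assigned uniformly
#' and specialties by their marginal frequencies, so the expected cohort
#' under the default configuration is about 1779 interns in 191 teams.
#' Each intern also receives a latent dropout week drawn from the weekly
#' dropout hazard (`n_weeks + 1` codes "never drops out").
#'
#' Randomness comes from the session RNG; call [set.seed()] first for a
#' reproducible cohort.
#'
#' @param config a [sim_config()] object.
#' @return A list with two data frames:
#'   \describe{
#'     \item{interns}{one row per intern: `intern_id`, `team_id`,
#'       `program_id`, `institution_id`, `specialty`, `sex`, `race`,
#'       `age_years`, `device_type`, `phq9`, `neuroticism`,
#'       `early_family_env`, `baseline_steps`, `baseline_sleep`,
#'       `baseline_mood`, `dropout_week`.}
#'     \item{teams}{one row per team: `team_id`, `institution_id`,
#'       `specialty`, `team_type`, `n_members`, `eligible`.}
#'   }
#' @examples
#' set.seed(1)
#' pop <- simulate_population(sim_config(n_teams = 8, n_institutions = 3))
#' nrow(pop$teams)
#' @export
simulate_population <- function(config = sim_config()) {
  validate_sim_config(config)
  nt <- config$n_teams

  sizes <- config$team_size_min +
    stats::rpois(nt, config$team_size_mean - config$team_size_min)
  institution <- sprintf("H%02d", sample.int(config$n_institutions, nt,
                                             replace = TRUE))
  specialty <- sample(names(config$specialty_probs), nt, replace = TRUE,
                      prob = config$specialty_probs)
  team_id <- sprintf("T%03d", seq_len(nt))
  teams <- data.frame(
    team_id = team_id,
    institution_id = institution,
    specialty = specialty,
    team_type = "program",
    n_members = sizes,
    eligible = sizes >= config$team_size_min,
    stringsAsFactors = FALSE
  )

  n <- sum(sizes)
  idx <- rep(seq_len(nt), sizes)
  interns <- data.frame(
    intern_id = sprintf("I%05d", seq_len(n)),
    team_id = team_id[idx],
    program_id = paste(institution, specialty, sep = ":")[idx],
    institution_id = institution[idx],
    specialty = specialty[idx],
    sex = ifelse(stats::runif(n) < config$p_female, "female", "male"),
    race = sample(names(config$race_probs), n, replace = TRUE,
                  prob = config$race_probs),
    age_years = stats::rnorm(n, config$age_mean, config$age_sd),
    device_type = ifelse(stats::runif(n) < config$p_fitbit,
                         "fitbit", "apple_watch"),
    phq9 = pmin(27, pmax(0, round(stats::rnorm(n, config$phq9_mean,
                                               config$phq9_sd)))),
    neuroticism = stats::rnorm(n),
    early_family_env = stats::rnorm(n),
    baseline_steps = pmax(0, stats::rnorm(n, config$baseline_steps_mean,
                                          config$baseline_steps_sd)),
    baseline_sleep = pmin(1440, pmax(0, stats::rnorm(n,
                                                     config$baseline_sleep_mean,
                                                     config$baseline_sleep_sd))),
    stringsAsFactors = FALSE
  )
  # pre-internship mood survey value, used as the week-0 lag anchor
  interns$baseline_mood <- pmin(10, pmax(1, stats::rnorm(
    n, config$mood_mean, config$intern_sd_mood)))
  interns$dropout_week <- draw_dropout_week(n, config)

  list(interns = interns, teams = teams)
}

# dropout_week = w means all outcomes missing from 0-based week w - 1 onward;
# n_weeks + 1 means the intern never drops out.
draw_dropout_week <- function(n, config) {
  W <- config$n_weeks
  haz <- config$dropout_hazard0 * (1 + config$dropout_hazard_growth)^(0:(W - 1))
  haz <- pmin(haz, 1)
  u <- matrix(stats::runif(n * W), n, W) <
    matrix(haz, n, W, byrow = TRUE)
  first <- apply(u, 1L, function(z) {
    k <- which(z)
    if (length(k)) k[1L] else W + 1L
  })
  as.integer(first)
}
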