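#' Simulate daily step, sleep and mood streams for a randomized cohort
#'
#' Generates complete (pre-missingness) daily outcomes for every intern over
#' `7 * n_weeks` days under a linear causal excursion model.  On day `d` of
#' 0-based week `w`, an intern's outcome is
#' \deqn{y = baseline + shift + trend \cdot w + b_{team} + b_{intern} +
#'       A_w (\beta_0 + \beta_{week} w + moderation) + \epsilon_d,}
#' where `A_w` is 1 when the intern's team is competing on the matching
#' competition type that week (a step competition moves steps, a sleep
#' competition moves sleep), the moderation offsets apply when the pairing
#' shares the institution or the specialty, and the day-level noise
#' \eqn{\epsilon_d} is a stationary AR(1) process within intern.  Mood is
#' generated on a latent Gaussian scale, shifted by `mood_effect` under any
#' competition, then clipped to `[1, 10]`; steps are clipped at 0 and sleep
#' to `[0, 1440]`.
#'
#' @param interns,teams data frames from [simulate_population()].
#' @param assignments weekly assignments from [randomize_trial()]; must
#'   cover every team for weeks `0 .. n_weeks - 1`.
#' @param config a [sim_config()] object.
#' @return Data frame of daily records, one row per intern-day:
#'   `intern_id`, `team_id`, `day_index` (0-based), `week_index`, `steps`,
#'   `sleep_min`, `mood`.
#' @export
simulate_outcomes <- function(interns, teams, assignments, config) {
  validate_sim_config(config)
  W <- config$n_weeks
  D <- 7L * W
  n <- nrow(interns)
  nt <- nrow(teams)

  key <- paste(assignments$team_id, assignments$week_index)
  need <- paste(rep(teams$team_id, each = W), rep(0:(W - 1L), nt))
  if (!all(need %in% key))
    stop("assignments do not cover all teams x weeks", call. = FALSE)
  if (!all(interns$team_id %in% teams$team_id))
    stop("interns reference unknown teams", call. = FALSE)

  row_of <- match(need, key)                       # nt x W, team-major
  A_any <- matrix(assignments$in_competition[row_of], nt, W, byrow = TRUE)
  type <- matrix(assignments$competition_type[row_of], nt, W, byrow = TRUE)
  rule <- matrix(assignments$pairing_rule[row_of], nt, W, byrow = TRUE)
  A_step <- A_any & !is.na(type) & type == "step"
  A_sleep <- A_any & !is.na(type) & type == "sleep"
  ii <- A_any & !is.na(rule) & rule == "intra_institution"
  is_ <- A_any & !is.na(rule) & rule == "intra_specialty"

  wk <- matrix(0:(W - 1L), nt, W, byrow = TRUE)
  eff_step <- A_step * (config$beta_step0 + config$beta_step_week * wk +
                        config$mod_intra_institution_step * ii +
                        config$mod_intra_specialty_step * is_)
  eff_sleep <- A_sleep * (config$beta_sleep0 + config$beta_sleep_week * wk +
                          config$mod_intra_institution_sleep * ii +
                          config$mod_intra_specialty_sleep * is_)
  eff_mood <- A_any * config$mood_effect

  b_team <- cbind(step = stats::rnorm(nt, 0, config$team_sd_step),
                  sleep = stats::rnorm(nt, 0, config$team_sd_sleep),
                  mood = stats::rnorm(nt, 0, config$team_sd_mood))
  ti <- match(interns$team_id, teams$team_id)

  week_of_day <- rep(0:(W - 1L), each = 7L)
  day_cols <- week_of_day + 1L                      # week index per day column

  level_step <- interns$baseline_steps + config$step_shift +
    stats::rnorm(n, 0, config$intern_sd_step) + b_team[ti, "step"]
  level_sleep <- interns$baseline_sleep + config$sleep_shift +
    stats::rnorm(n, 0, config$intern_sd_sleep) + b_team[ti, "sleep"]
  level_mood <- interns$baseline_mood + b_team[ti, "mood"]

  mk <- function(level, trend, eff, sd) {
    m <- matrix(level, n, D) +
      matrix(trend * week_of_day, n, D, byrow = TRUE) +
      eff[ti, day_cols, drop = FALSE] +
      ar1_noise(n, D, sd, config$ar1_rho)
    m
  }
  steps <- mk(level_step, config$trend_step, eff_step, config$day_sd_step)
  sleep <- mk(level_sleep, config$trend_sleep, eff_sleep, config$day_sd_sleep)
  clip <- is.null(config$clip_outcomes) || isTRUE(config$clip_outcomes)
  if (clip) {
    steps <- pmax(steps, 0)
    sleep <- pmin(pmax(sleep, 0), 1440)
  }
  mood <- pmin(pmax(mk(level_mood, 0, eff_mood, config$day_sd_mood), 1), 10)

  data.frame(
    intern_id = rep(interns$intern_id, each = D),
    team_id = rep(interns$team_id, each = D),
    day_index = rep(0:(D - 1L), n),
    week_index = rep(week_of_day, n),
    steps = as.vector(t(steps)),
    sleep_min = as.vector(t(sleep)),
    mood = as.vector(t(mood)),
    stringsAsFactors = FALSE
  )
}

# stationary AR(1) noise, n x D, marginal SD sd
ar1_noise <- function(n, D, sd, rho) {
  if (sd == 0) return(matrix(0, n, D))
  if (rho == 0) return(matrix(stats::rnorm(n * D, 0, sd), n, D))
  innov <- matrix(stats::rnorm(n * D), D, n)
  x <- stats::filter(innov * sqrt(1 - rho^2), rho, method = "recursive",
                     init = matrix(stats::rnorm(n), 1L, n))
  t(matrix(x, D, n)) * sd
}

#' Apply missing-at-random missingness and dropout to complete records
#'
#' Masks daily outcomes with `NA` by two mechanisms.  (1) MAR daily
#' missingness: each outcome is missing with baseline probability
#' `p_miss_*`, reduced by the participation uplift while the team is in any
#' competition week, and shifted on the logit scale by `mar_coef_*` times
#' the standardized most recent observed value of that outcome (the
#' previous observed day, or the intern's pre-internship baseline before
#' any observation) — so missingness depends only on observed quantities.
#' (2) Dropout: an intern with `dropout_week = w` has every outcome missing
#' from 0-based week `w - 1` onward (`n_weeks + 1` = never).
#'
#' The input (complete) records are not modified; keep them to measure
#' imputation error.
#'
#' @param records complete daily records from [simulate_outcomes()].
#' @param interns intern table with `dropout_week` and baseline columns.
#' @param assignments weekly assignments (for the participation uplift).
#' @param config a [sim_config()] object.
#' @return The records data frame with `NA` in masked cells.
#' @export
apply_missingness <- function(records, interns, assignments, config) {
  validate_sim_config(config)
  W <- config$n_weeks
  D <- 7L * W
  n <- nrow(interns)
  ord <- order(match(records$intern_id, interns$intern_id), records$day_index)
  if (any(ord != seq_along(ord))) records <- records[ord, ]
  stopifnot(nrow(records) == n * D)

  key <- paste(assignments$team_id, assignments$week_index)
  nt_w <- match(paste(rep(unique(interns$team_id), each = W),
                      rep(0:(W - 1L), length(unique(interns$team_id)))), key)
  A_tw <- matrix(assignments$in_competition[nt_w],
                 nrow = length(unique(interns$team_id)), ncol = W,
                 byrow = TRUE,
                 dimnames = list(unique(interns$team_id), NULL))
  team_row <- match(interns$team_id, rownames(A_tw))

  outs <- c(steps = "steps", sleep = "sleep_min", mood = "mood")
  p0 <- c(steps = config$p_miss_step, sleep = config$p_miss_sleep,
          mood = config$p_miss_mood)
  mar <- c(steps = config$mar_coef_step, sleep = config$mar_coef_sleep,
           mood = config$mar_coef_mood)
  uplift <- c(steps = config$uplift_step, sleep = config$uplift_sleep,
              mood = 0)
  base_col <- c(steps = "baseline_steps", sleep = "baseline_sleep",
                mood = "baseline_mood")

  drop_from <- interns$dropout_week - 1L            # 0-based week of dropout
  week_of_day <- rep(0:(W - 1L), each = 7L)

  for (o in names(outs)) {
    col <- outs[[o]]
    Y <- matrix(records[[col]], D, n)               # day x intern
    mu <- mean(Y); sg <- stats::sd(Y); if (!is.finite(sg) || sg == 0) sg <- 1
    last_obs <- interns[[base_col[[o]]]]
    if (is.null(last_obs)) last_obs <- rep(mu, n)
    for (d in seq_len(D)) {
      w <- week_of_day[d]
      A <- as.numeric(A_tw[cbind(team_row, w + 1L)])
      p_eff <- pmin(pmax(p0[[o]] - uplift[[o]] * A, 0), 1)
      z <- (last_obs - mu) / sg
      pm <- ifelse(p_eff <= 0, 0,
                   ifelse(p_eff >= 1, 1,
                          stats::plogis(stats::qlogis(p_eff) + mar[[o]] * z)))
      miss <- stats::runif(n) < pm
      miss <- miss | (w >= drop_from)
      last_obs <- ifelse(miss, last_obs, Y[d, ])
      Y[d, miss] <- NA_real_
    }
    records[[col]] <- as.vector(Y)
  }
  records
}

#' Simulate a complete synthetic trial
#'
#' Convenience wrapper running cohort generation, weekly randomization,
#' outcome generation and (optionally) missingness with one call, drawing
#' from the session RNG.
#'
#' @param config a [sim_config()] object.
#' @param missingness apply the missingness model (default `TRUE`).
#' @return A list: `interns`, `teams`, `assignments`, `records` (observed,
#'   with `NA`s if `missingness`), `records_complete`, `config`.
#' @examples
#' set.seed(11)
#' tr <- simulate_trial(sim_config(n_teams = 6, n_institutions = 3,
#'                                 n_weeks = 3))
#' head(tr$records)
#' @export
simulate_trial <- function(config = sim_config(), missingness = TRUE) {
  pop <- simulate_population(config)
  assignments <- randomize_trial(pop$teams, n_weeks = config$n_weeks)
  complete <- simulate_outcomes(pop$interns, pop$teams, assignments, config)
  observed <- if (missingness)
    apply_missingness(complete, pop$interns, assignments, config)
  else complete
  list(interns = pop$interns, teams = pop$teams, assignments = assignments,
       records = observed, records_complete = complete, config = config)
}
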