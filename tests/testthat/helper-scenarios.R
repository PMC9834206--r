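# Shared simulation scenarios for the test suite.
#
# `small_config()` is a fast, down-scaled cohort for unit tests.
# `recovery_config()` is the estimator-validation scenario: the generating
# model matches the fitted model exactly (no pairing moderation, no
# boundary censoring), so the generating coefficients are the estimands.

small_config <- function(n_teams = 12, n_institutions = 5, ...) {
  sim_config(n_teams = n_teams, n_institutions = n_institutions, ...)
}

recovery_config <- function(n_teams = 150, ...) {
  sim_config(n_teams = n_teams, n_institutions = round(0.4 * n_teams),
             mod_intra_institution_step = 0, mod_intra_specialty_step = 0,
             mod_intra_institution_sleep = 0, mod_intra_specialty_sleep = 0,
             clip_outcomes = FALSE, ...)
}

# tiny deterministic roster for randomizer tests
toy_teams <- function(n, institutions = NULL, specialties = NULL) {
  data.frame(
    team_id = sprintf("T%02d", seq_len(n)),
    institution_id = if (is.null(institutions)) rep("H1", n) else institutions,
    specialty = if (is.null(specialties)) rep("s", n) else specialties,
    stringsAsFactors = FALSE)
}

# hand-checkable 2-team, 2-week fixture with constant outcomes
make_tiny_trial <- function() {
  interns <- data.frame(
    intern_id = sprintf("I%02d", 1:10),
    team_id = rep(c("T1", "T2"), each = 5),
    program_id = rep(c("A:x", "B:y"), each = 5),
    institution_id = rep(c("A", "B"), each = 5),
    specialty = rep(c("x", "y"), each = 5),
    sex = rep(c("female", "male"), 5),
    phq9 = 2, baseline_steps = 8000, baseline_sleep = 420,
    baseline_mood = 7, dropout_week = 13L,
    stringsAsFactors = FALSE)
  D <- 14L
  records <- data.frame(
    intern_id = rep(interns$intern_id, each = D),
    team_id = rep(interns$team_id, each = D),
    day_index = rep(0:(D - 1L), 10),
    week_index = rep(rep(0:1, each = 7), 10),
    steps = 8000, sleep_min = 400, mood = 7,
    stringsAsFactors = FALSE)
  assignments <- data.frame(
    team_id = rep(c("T1", "T2"), each = 2),
    week_index = rep(0:1, 2),
    in_competition = c(TRUE, FALSE, TRUE, FALSE),
    pairing_rule = c("total", NA, "total", NA),
    opponent_team_id = c("T2", NA, "T1", NA),
    competition_type = c("step", NA, "step", NA),
    leftover = FALSE, stringsAsFactors = FALSE)
  list(interns = interns, records = records, assignments = assignments)
}

# simulate one small complete-data trial and aggregate it
small_team_week <- function(seed = 1, config = small_config(),
                            missingness = FALSE) {
  set.seed(seed)
  tr <- simulate_trial(config, missingness = missingness)
  list(trial = tr,
       tw = aggregate_team_week(tr$records, tr$interns, tr$assignments))
}
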