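test_that("config validation names the offending field", {
  expect_error(sim_config(team_sd_step = -1), "team_sd_step")
  expect_error(sim_config(p_miss_step = 1.2), "p_miss_step")
  expect_error(sim_config(ar1_rho = 1), "ar1_rho")
  expect_error(sim_config(n_teams = 0), "n_teams")
})

test_that("degenerate population: one institution, one specialty", {
  set.seed(1)
  pop <- simulate_population(sim_config(
    n_teams = 1, n_institutions = 1, team_size_min = 10, team_size_mean = 10,
    specialty_probs = c(psychiatry = 1)))
  expect_equal(nrow(pop$interns), 10)
  expect_equal(length(unique(pop$interns$program_id)), 1)
  expect_true(all(pop$interns$specialty == "psychiatry"))
})

test_that("default cohort is about 1779 interns in 191 teams", {
  set.seed(42)
  pop <- simulate_population(sim_config())
  expect_equal(nrow(pop$teams), 191)
  expect_gt(nrow(pop$interns), 1779 * 0.93)
  expect_lt(nrow(pop$interns), 1779 * 1.07)
  expect_true(all(pop$teams$n_members >= 5))
  expect_true(all(pop$interns$baseline_steps >= 0))
  expect_true(all(pop$interns$baseline_sleep >= 0 &
                  pop$interns$baseline_sleep <= 1440))
})

test_that("specialty margins are close to the configured targets", {
  set.seed(7)
  pop <- simulate_population(sim_config())
  p <- table(pop$teams$specialty) / nrow(pop$teams)
  tgt <- sim_config()$specialty_probs
  expect_lt(max(abs(p[names(tgt)] - tgt), na.rm = TRUE), 0.08)
})

test_that("simulation is deterministic given the seed", {
  set.seed(99); a <- simulate_trial(small_config(n_weeks = 3))
  set.seed(99); b <- simulate_trial(small_config(n_weeks = 3))
  expect_identical(a$interns, b$interns)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$records, b$records)
})

test_that("noiseless generation reproduces the causal contrast exactly", {
  cfg <- small_config(
    n_weeks = 2,
    beta_step0 = 100, beta_step_week = 0,
    beta_sleep0 = 0, beta_sleep_week = 0,
    mod_intra_institution_step = 0, mod_intra_specialty_step = 0,
    mod_intra_institution_sleep = 0, mod_intra_specialty_sleep = 0,
    trend_step = 0, trend_sleep = 0, step_shift = 0, sleep_shift = 0,
    team_sd_step = 0, team_sd_sleep = 0, team_sd_mood = 0,
    intern_sd_step = 0, intern_sd_sleep = 0, intern_sd_mood = 0,
    day_sd_step = 0, day_sd_sleep = 0, day_sd_mood = 0,
    baseline_steps_sd = 0, baseline_sleep_sd = 0, mood_effect = 0)
  set.seed(3)
  pop <- simulate_population(cfg)
  asg <- randomize_trial(pop$teams, n_weeks = 2)
  rec <- simulate_outcomes(pop$interns, pop$teams, asg, cfg)
  key <- paste(asg$team_id, asg$week_index)
  a_step <- asg$in_competition & !is.na(asg$competition_type) &
    asg$competition_type == "step"
  trt <- a_step[match(paste(rec$team_id, rec$week_index), key)]
  expect_true(all(abs(rec$steps[trt] - (cfg$baseline_steps_mean + 100)) < 1e-9))
  expect_true(all(abs(rec$steps[!trt] - cfg$baseline_steps_mean) < 1e-9))
})

test_that("assignment/team mismatch is a structural error", {
  set.seed(5)
  pop <- simulate_population(small_config(n_weeks = 2))
  asg <- randomize_trial(pop$teams, n_weeks = 1)   # missing week 1
  expect_error(simulate_outcomes(pop$interns, pop$teams, asg,
                                 small_config(n_weeks = 2)),
               "cover all teams")
})

test_that("zero missingness parameters leave no missing cells", {
  cfg <- small_config(p_miss_step = 0, p_miss_sleep = 0, p_miss_mood = 0,
                      dropout_hazard0 = 0)
  set.seed(8)
  tr <- simulate_trial(cfg)
  expect_false(anyNA(tr$records$steps))
  expect_false(anyNA(tr$records$sleep_min))
  expect_false(anyNA(tr$records$mood))
})

test_that("certain dropout at a given week blanks all later records", {
  cfg <- small_config(p_miss_step = 0, p_miss_sleep = 0, p_miss_mood = 0,
                      dropout_hazard0 = 0, n_weeks = 8)
  set.seed(8)
  pop <- simulate_population(cfg)
  pop$interns$dropout_week <- 7L   # data through 0-based week 5 only
  asg <- randomize_trial(pop$teams, n_weeks = 8)
  rec <- simulate_outcomes(pop$interns, pop$teams, asg, cfg)
  obs <- apply_missingness(rec, pop$interns, asg, cfg)
  late <- obs$week_index >= 6
  expect_true(all(is.na(obs$steps[late])))
  expect_true(all(is.na(obs$sleep_min[late])))
  expect_false(anyNA(obs$steps[!late]))
})

test_that("empirical missing fractions track the configured rates", {
  cfg <- sim_config(n_teams = 120, n_institutions = 40,
                    p_miss_step = 0.3, p_miss_sleep = 0.5,
                    dropout_hazard0 = 0)
  set.seed(10)
  tr <- simulate_trial(cfg)
  expect_lt(abs(mean(is.na(tr$records$steps)) - 0.3), 0.02)
  expect_lt(abs(mean(is.na(tr$records$sleep_min)) - 0.5), 0.02)
  # and sleep missingness exceeds step missingness under defaults
  set.seed(11)
  tr2 <- simulate_trial(sim_config(n_teams = 60, n_institutions = 20))
  expect_gt(mean(is.na(tr2$records$sleep_min)),
            mean(is.na(tr2$records$steps)))
})

test_that("null effects give exchangeable competition/non-competition teams", {
  cfg <- sim_config(n_teams = 60, n_institutions = 20,
                    beta_step0 = 0, beta_step_week = 0,
                    beta_sleep0 = 0, beta_sleep_week = 0,
                    mod_intra_institution_step = 0, mod_intra_specialty_step = 0,
                    mod_intra_institution_sleep = 0, mod_intra_specialty_sleep = 0,
                    mood_effect = 0, uplift_step = 0, uplift_sleep = 0)
  set.seed(14)
  ps <- replicate(20, {
    tr <- simulate_trial(cfg, missingness = FALSE)
    tw <- aggregate_team_week(tr$records, tr$interns, tr$assignments)
    stats::t.test(mean_daily_steps ~ trt_step, data = tw)$p.value
  })
  # p-values should look uniform: no mass piling near 0
  expect_gt(min(ps), 1e-4)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
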