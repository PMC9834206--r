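test_that("WCLS with constant p = ptilde is centered OLS to 1e-10", {
  x <- small_team_week(seed = 21, config = small_config(n_teams = 15))
  tw <- x$tw
  f <- wcls_marginal(tw, "steps")
  tw$Ac <- tw$trt_step - 0.5
  ols <- stats::lm(mean_daily_steps ~ week + pct_female +
                     baseline_mean_steps + baseline_mean_sleep +
                     baseline_mean_phq9 + prev_week_steps + Ac, tw)
  expect_lt(abs(unname(coef(f)["trt_step"] - coef(ols)["Ac"])), 1e-10)
  expect_lt(max(abs(fitted(f) - fitted(ols))), 1e-8)
})

test_that("cluster sandwich matches the independent sandwich implementation", {
  x <- small_team_week(seed = 22, config = small_config(n_teams = 15))
  tw <- x$tw
  f <- wcls_week_moderation(tw, "steps")
  tw$Ac <- tw$trt_step - 0.5
  tw$Acw <- tw$Ac * tw$week
  ols <- stats::lm(mean_daily_steps ~ week + pct_female +
                     baseline_mean_steps + baseline_mean_sleep +
                     baseline_mean_phq9 + prev_week_steps + Ac + Acw, tw)
  V <- sandwich::vcovCL(ols, cluster = tw$team_id, type = "HC0",
                        cadjust = FALSE)
  expect_equal(unname(sqrt(diag(vcov(f)))[c("trt_step", "trt_step:week")]),
               unname(sqrt(diag(V))[c("Ac", "Acw")]), tolerance = 1e-8)
})

test_that("one row per cluster reduces the sandwich to HC0", {
  x <- small_team_week(seed = 23, config = small_config(n_teams = 30,
                                                        n_institutions = 10))
  wk <- which(tapply(x$tw$trt_step, x$tw$week, function(z)
    length(unique(z))) == 2)[1] - 1
  tw1 <- x$tw[x$tw$week == wk, ]
  f <- wcls(mean_daily_steps ~ pct_female + baseline_mean_steps, tw1,
            treatment = "trt_step", cluster = "team_id")
  tw1$Ac <- tw1$trt_step - 0.5
  o <- stats::lm(mean_daily_steps ~ pct_female + baseline_mean_steps + Ac,
                 tw1)
  expect_equal(unname(diag(vcov(f))),
               unname(diag(sandwich::vcovHC(o, type = "HC0"))),
               tolerance = 1e-8)
})

test_that("zero-variance outcome gives zero effects and zero SEs", {
  x <- small_team_week(seed = 24)
  tw <- x$tw
  tw$mean_daily_steps <- 5000
  f <- wcls(mean_daily_steps ~ week, tw, treatment = "trt_step",
            cluster = "team_id")
  expect_equal(unname(coef(f)["trt_step"]), 0, tolerance = 1e-9)
  expect_equal(unname(sqrt(vcov(f)["trt_step", "trt_step"])), 0,
               tolerance = 1e-9)
  s <- summary(f)
  expect_true(all(is.finite(s$coefficients[, "Pr(>|z|)"])))
})

test_that("non-binary treatment and bad probabilities are rejected", {
  x <- small_team_week(seed = 25)
  tw <- x$tw
  tw$bad <- tw$trt_step + 0.5
  expect_error(wcls(mean_daily_steps ~ week, tw, "bad", "team_id"),
               "binary")
  expect_error(wcls(mean_daily_steps ~ week, tw, "trt_step", "team_id",
                    prob = 1.5), "prob")
  expect_error(wcls(mean_daily_steps ~ week, tw, "nope", "team_id"),
               "not found")
})

test_that("singular designs name the collinear term or drop it on request", {
  x <- small_team_week(seed = 26)
  tw <- x$tw
  tw$dup <- tw$week
  expect_error(wcls(mean_daily_steps ~ week + dup, tw, "trt_step",
                    "team_id"), "dup")
  # degenerate moderation: all competitions intra-institution
  tw$intra_institution <- tw$trt_any
  tw$intra_specialty <- 0
  expect_message(
    f <- wcls(mean_daily_steps ~ week, tw, "trt_any", "team_id",
              moderator = ~ intra_institution + intra_specialty,
              drop_aliased = TRUE),
    "inestimable")
  expect_true("trt_any:intra_specialty" %in% f$dropped_terms)
})

test_that("week-moderated effect evaluation matches the direct formula", {
  x <- small_team_week(seed = 27, config = small_config(n_teams = 20))
  f <- wcls_week_moderation(x$tw, "steps")
  b <- coef(f)
  ec <- effect_curve(f, 0:11)
  expect_equal(ec$estimate,
               unname(b["trt_step"] + b["trt_step:week"] * (0:11)))
  # delta-method SE at week 0 equals the main term's SE
  expect_equal(ec$se[1], unname(sqrt(vcov(f)["trt_step", "trt_step"])))
  # effect_at_week agrees
  expect_equal(effect_at_week(b[["trt_step"]], b[["trt_step:week"]], 5),
               ec$estimate[5])
})

test_that("effect_at_week reproduces printed worked examples and guards", {
  expect_equal(effect_at_week(185.3, -14.5, 1), 185.3)
  expect_equal(effect_at_week(185.3, -14.5, 6), 112.8)
  expect_equal(effect_at_week(185.3, -14.5, 12), 25.8, tolerance = 1e-12)
  expect_equal(effect_at_week(9.8, -1.9, 1), 9.8)
  expect_error(effect_at_week(1, 1, 0), "week_number")
  v <- diag(c(4, 0.25))
  e <- effect_at_week(10, -1, 3, vcov = v)
  expect_equal(attr(e, "se"), sqrt(4 + 4 * 0.25))
})

test_that("person-day arithmetic and study-flow percentages", {
  expect_identical(person_days_gain(1779, 0.003), 37L)
  expect_identical(person_days_gain(1779, 0.009), 112L)
  expect_identical(person_days_gain(1000, 0), 0L)
  expect_equal(study_flow(c(4791, 2286)), c(NA, 47.7))
  expect_equal(study_flow(c(2286, 1936)), c(NA, 84.7))
  expect_equal(study_flow(c(1936, 1779)), c(NA, 91.9))
  expect_equal(study_flow(c(50, 50)), c(NA, 100.0))
  expect_error(study_flow(c(10, 20)), "nonincreasing")
})

test_that("analysis weights and Mancl-DeRouen correction behave sanely", {
  x <- small_team_week(seed = 28, config = small_config(n_teams = 15))
  tw <- x$tw
  f0 <- wcls_marginal(tw, "steps")
  # unit weights change nothing
  f1 <- wcls_marginal(tw, "steps", weights = rep(1, nrow(tw)))
  expect_equal(coef(f0), coef(f1))
  # Mancl-DeRouen inflates (or keeps) the robust SE
  fmd <- wcls_marginal(tw, "steps", vcov_type = "mancl-derouen")
  expect_equal(coef(f0), coef(fmd))
  expect_gte(vcov(fmd)["trt_step", "trt_step"],
             vcov(f0)["trt_step", "trt_step"])
  # non-unit weights move the fit
  f2 <- wcls_marginal(tw, "steps", weights = runif(nrow(tw), 0.5, 2))
  expect_false(isTRUE(all.equal(coef(f0)["trt_step"],
                                coef(f2)["trt_step"])))
})

test_that("participation LPM detects an engagement uplift", {
  cfg <- sim_config(n_teams = 120, n_institutions = 40,
                    uplift_step = 0, uplift_sleep = 0.15,
                    dropout_hazard0 = 0)
  set.seed(30)
  tr <- simulate_trial(cfg)
  tw <- aggregate_team_week(tr$records, tr$interns, tr$assignments)
  fs <- wcls_participation(tw, "sleep")
  b <- coef(fs)["trt_any"]
  se <- sqrt(vcov(fs)["trt_any", "trt_any"])
  expect_gt(b, 0.15 - 3 * se)
  expect_lt(b, 0.15 + 3 * se)
  # no uplift: estimate near zero
  f0 <- wcls_participation(tw, "steps")
  expect_lt(abs(coef(f0)["trt_any"]),
            3 * sqrt(vcov(f0)["trt_any", "trt_any"]))
  # all rates 1.0: zero effect, zero variance
  tw$participation_rate_steps <- 1
  fz <- wcls_participation(tw, "steps")
  expect_equal(unname(coef(fz)["trt_any"]), 0, tolerance = 1e-9)
})
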