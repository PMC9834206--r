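test_that("team formation applies the program/institution/ineligible rule", {
  roster <- data.frame(
    intern_id = as.character(1:12),
    program_id = rep(c("A:x", "A:y", "A:z"), c(7, 3, 2)),
    institution_id = "A",
    specialty = rep(c("x", "y", "z"), c(7, 3, 2)),
    stringsAsFactors = FALSE)
  r <- form_teams(roster)
  expect_equal(nrow(r$teams), 2)
  expect_equal(sort(r$teams$n_members), c(5, 7))
  expect_setequal(r$teams$team_type, c("program", "institution"))
  expect_equal(r$teams$specialty[r$teams$team_type == "institution"], "MIXED")
  expect_length(r$ineligible, 0)

  # all programs large: no institution teams, no ineligible
  roster2 <- data.frame(
    intern_id = as.character(1:10),
    program_id = rep(c("A:x", "B:y"), each = 5),
    institution_id = rep(c("A", "B"), each = 5),
    specialty = rep(c("x", "y"), each = 5),
    stringsAsFactors = FALSE)
  r2 <- form_teams(roster2)
  expect_true(all(r2$teams$team_type == "program"))
  expect_length(r2$ineligible, 0)

  # too-small pool -> ineligible
  r3 <- form_teams(roster2[1:3, ])
  expect_equal(nrow(r3$teams), 0)
  expect_length(r3$ineligible, 3)

  # empty roster is empty output, not an error
  r0 <- form_teams(roster2[0, ])
  expect_equal(nrow(r0$teams), 0)
})

test_that("pairing output is a perfect matching with shared competition type", {
  set.seed(5)
  tm <- toy_teams(9, institutions = rep(c("H1", "H2", "H3"), 3),
                  specialties = rep(c("a", "b", "c"), each = 3))
  for (r in 1:200) {
    a <- randomize_week(tm, 0L)
    comp <- a[a$in_competition, ]
    if (nrow(comp) == 0) next
    expect_true(nrow(comp) %% 2 == 0)
    opp_row <- match(comp$opponent_team_id, a$team_id)
    expect_equal(a$opponent_team_id[opp_row], comp$team_id)
    expect_equal(a$competition_type[opp_row], comp$competition_type)
    expect_false(any(is.na(comp$competition_type)))
    # constrained rules share the constraint
    ii <- comp$pairing_rule == "intra_institution"
    expect_equal(tm$institution_id[match(comp$team_id[ii], tm$team_id)],
                 tm$institution_id[match(comp$opponent_team_id[ii], tm$team_id)])
    is_ <- comp$pairing_rule == "intra_specialty"
    expect_equal(tm$specialty[match(comp$team_id[is_], tm$team_id)],
                 tm$specialty[match(comp$opponent_team_id[is_], tm$team_id)])
    # non-competition rows carry no opponent or type
    non <- a[!a$in_competition, ]
    expect_true(all(is.na(non$opponent_team_id)))
    expect_true(all(is.na(non$competition_type)))
  }
})

test_that("odd competition pools return exactly one leftover under total rule", {
  set.seed(6)
  tm <- toy_teams(7)
  saw_odd <- FALSE
  for (r in 1:300) {
    a <- randomize_week(tm, 0L, rule = "total")
    drawn <- sum(a$in_competition) + sum(a$leftover)
    if (drawn %% 2 == 1) {
      saw_odd <- TRUE
      expect_equal(sum(a$leftover), 1)
    } else {
      expect_equal(sum(a$leftover), 0)
    }
    expect_false(any(a$in_competition & a$leftover))
  }
  expect_true(saw_odd)
})

test_that("all-distinct institutions make every drawn team unpairable", {
  set.seed(7)
  tm <- toy_teams(6, institutions = paste0("H", 1:6))
  for (r in 1:100) {
    a <- randomize_week(tm, 0L, rule = "intra_institution")
    expect_false(any(a$in_competition))
    # every drawn team is flagged leftover
    expect_equal(sum(a$leftover), sum(!is.na(a$pairing_rule)))
  }
})

test_that("two-team total-rule competition probability is 1/4 (enumeration)", {
  # both fair coins must land heads for a realized pair: 1/4 exactly
  set.seed(8)
  tm <- toy_teams(2)
  pr <- realized_treatment_probability(tm, rule = "total", n_reps = 8000)
  expect_true(all(abs(pr$prob - 0.25) < 3 * sqrt(0.25 * 0.75 / 8000)))

  # single team can never compete
  pr1 <- realized_treatment_probability(toy_teams(1), rule = "total",
                                        n_reps = 200)
  expect_equal(pr1$prob, 0)
})

test_that("realized probability approaches 1/2 from below as teams grow", {
  set.seed(9)
  p20 <- mean(realized_treatment_probability(toy_teams(20), rule = "total",
                                             n_reps = 2000)$prob)
  p4 <- mean(realized_treatment_probability(toy_teams(4), rule = "total",
                                            n_reps = 2000)$prob)
  expect_lt(p4, p20)
  expect_lt(p20, 0.5)
  expect_gt(p20, 0.44)
})

test_that("fewer than two teams never produces a competition", {
  set.seed(10)
  a <- randomize_week(toy_teams(1), 0L)
  expect_false(any(a$in_competition))
  a0 <- randomize_week(toy_teams(2)[0, ], 0L)
  expect_equal(nrow(a0), 0)
})
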