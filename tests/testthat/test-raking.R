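test_that("single-margin raking is one-shot post-stratification", {
  s <- data.frame(sex = rep(c("f", "m"), c(20, 10)))
  w <- rake(s, list(sex = c(f = 0.5, m = 0.5)))
  # closed form: target share / sample share, mean-1 normalized
  expect_equal(unique(round(w[s$sex == "f"], 10)), 0.75)
  expect_equal(unique(round(w[s$sex == "m"], 10)), 1.5)
  expect_true(attr(w, "converged"))
  # already matched margins: all weights 1 after one cycle
  s2 <- data.frame(sex = rep(c("f", "m"), each = 10))
  w2 <- rake(s2, list(sex = c(f = 0.5, m = 0.5)))
  expect_equal(as.numeric(w2), rep(1, 20))
  expect_lte(attr(w2, "iterations"), 1)
})

test_that("two-margin raking matches hand IPF on a 2x2 table", {
  # cells: (x,u)=2, (x,v)=1, (y,u)=1, (y,v)=2 units; targets a: .6/.4, b: .5/.5
  s <- data.frame(a = c("x", "x", "x", "y", "y", "y"),
                  b = c("u", "u", "v", "u", "v", "v"))
  tgt <- list(a = c(x = 0.6, y = 0.4), b = c(u = 0.5, v = 0.5))
  w <- rake(s, tgt, tol = 1e-10, max_iter = 500, normalize = FALSE)
  # hand IPF on the 2x2 cell table until stable
  tab <- matrix(c(2, 1, 1, 2), 2, byrow = TRUE,
                dimnames = list(c("x", "y"), c("u", "v")))
  cell <- tab
  for (k in 1:500) {
    cell <- cell * (c(x = 0.6, y = 0.4) * 6 / rowSums(cell))
    cell <- sweep(cell, 2, c(u = 0.5, v = 0.5) * 6 / colSums(cell), `*`)
  }
  wcell <- cell / tab                      # per-unit weight in each cell
  got <- tapply(w, paste(s$a, s$b), unique)
  expect_equal(got[["x u"]], wcell["x", "u"], tolerance = 1e-6)
  expect_equal(got[["x v"]], wcell["x", "v"], tolerance = 1e-6)
  expect_equal(got[["y u"]], wcell["y", "u"], tolerance = 1e-6)
  expect_equal(got[["y v"]], wcell["y", "v"], tolerance = 1e-6)
  # converged weighted margins hit the targets
  expect_lt(max(abs(tapply(w, s$a, sum) / sum(w) - tgt$a)), 1e-8)
  expect_lt(max(abs(tapply(w, s$b, sum) / sum(w) - tgt$b)), 1e-8)
})

test_that("raking is invariant to category relabeling", {
  set.seed(5)
  s <- data.frame(a = sample(c("p", "q"), 40, TRUE))
  w1 <- rake(s, list(a = c(p = 0.3, q = 0.7)))
  s2 <- data.frame(a = ifelse(s$a == "p", "P2", "Q2"))
  w2 <- rake(s2, list(a = c(P2 = 0.3, Q2 = 0.7)))
  expect_equal(as.numeric(w1), as.numeric(w2))
})

test_that("empty sample category with positive target mass fails loudly", {
  s <- data.frame(a = rep("x", 5))
  expect_error(rake(s, list(a = c(x = 0.5, y = 0.5))), "category y")
  expect_error(rake(s, list(a = c(x = 0.5, z = 0.5))), "cannot converge")
  # sample category absent from margins
  expect_error(rake(data.frame(a = c("x", "w")),
                    list(a = c(x = 1))), "missing from margins")
})

toy_margins <- function() {
  list(specialty = c(surgery = 0.25, obgyn = 0.25, psychiatry = 0.5),
       surgical_specialties = c("surgery", "obgyn"),
       sex = list(surgical = c(female = 0.5, male = 0.5),
                  nonsurgical = c(female = 0.5, male = 0.5)),
       race = list(surgical = c(white = 0.5, asian = 0.3, urm_other = 0.2),
                   nonsurgical = c(white = 0.5, asian = 0.3, urm_other = 0.2)))
}

test_that("a sample already matching the population gets unit weights", {
  s <- expand.grid(specialty = c("surgery", "obgyn", "psychiatry",
                                 "psychiatry"),
                   sex = c("female", "male"),
                   race = c("white", "white", "white", "white", "white",
                            "asian", "asian", "asian", "other", "other"),
                   stringsAsFactors = FALSE)
  ts <- two_step_weights(s, toy_margins())
  expect_true(all(abs(ts$w - 1) < 1e-8))
  expect_true(attr(ts, "converged"))
})

test_that("two-step weights are w1 * w2 with mean 1 and fix the sex margin", {
  set.seed(6)
  n <- 400
  s <- data.frame(
    specialty = sample(c("surgery", "obgyn", "psychiatry"), n, TRUE,
                       prob = c(0.2, 0.2, 0.6)),
    sex = sample(c("female", "male"), n, TRUE, prob = c(2 / 3, 1 / 3)),
    race = sample(c("white", "asian", "black", "other"), n, TRUE),
    stringsAsFactors = FALSE)
  ts <- two_step_weights(s, toy_margins())
  expect_equal(mean(ts$w), 1)
  expect_true(all(ts$w > 0))
  expect_equal(ts$w, ts$w1 * ts$w2 / mean(ts$w1 * ts$w2))
  # weighted sex margin within each group matches the 50/50 target
  grp <- ifelse(s$specialty %in% c("surgery", "obgyn"),
                "surgical", "nonsurgical")
  for (g in unique(grp)) {
    i <- grp == g
    sh <- tapply(ts$w[i], s$sex[i], sum) / sum(ts$w[i])
    expect_lt(max(abs(sh - 0.5)), 1e-6)
  }
})

test_that("step 2 preserves specialty margins when sex/race are independent", {
  set.seed(7)
  n <- 3000
  s <- data.frame(
    specialty = sample(c("surgery", "obgyn", "psychiatry"), n, TRUE,
                       prob = c(0.3, 0.2, 0.5)),
    sex = sample(c("female", "male"), n, TRUE, prob = c(0.6, 0.4)),
    race = sample(c("white", "asian", "other"), n, TRUE,
                  prob = c(0.5, 0.3, 0.2)),
    stringsAsFactors = FALSE)
  ts <- two_step_weights(s, toy_margins())
  sh <- tapply(ts$w, s$specialty, sum) / sum(ts$w)
  tgt <- toy_margins()$specialty
  expect_lt(max(abs(sh[names(tgt)] - tgt)), 0.03)
})

test_that("team aggregation of weights defaults to the member mean", {
  wdf <- data.frame(intern_id = c("a", "b", "c"), w = c(0.5, 1.5, 1.0))
  interns <- data.frame(intern_id = c("a", "b", "c"),
                        team_id = c("T1", "T1", "T2"))
  tw <- team_weights(wdf, interns)
  expect_equal(tw$w[tw$team_id == "T1"], 1.0)
  expect_equal(tw$w[tw$team_id == "T2"], 1.0)
})
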