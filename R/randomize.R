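#' Group interns into competition-eligible teams
#'
#' Applies the two-stage team-formation rule used for anonymity-preserving
#' team competition: programs (institution x specialty) with at least
#' `min_size` interns become program-based teams; the remaining interns
#' within each institution are pooled into a single institution-based team
#' (specialty `"MIXED"`) if the pool itself reaches `min_size`; everyone
#' else is ineligible for competition.
#'
#' @param interns data frame with columns `intern_id`, `program_id`,
#'   `institution_id`, `specialty`.
#' @param min_size minimum team size (default 5).
#' @return A list with `teams` (data frame: `team_id`, `institution_id`,
#'   `specialty`, `team_type`, `n_members`, `eligible`), `membership`
#'   (data frame `intern_id`, `team_id`), and `ineligible` (character
#'   vector of intern ids that could not be grouped).
#' @examples
#' r <- data.frame(intern_id = as.character(1:12),
#'                 program_id = rep(c("A:x", "A:y", "A:z"), c(7, 3, 2)),
#'                 institution_id = "A",
#'                 specialty = rep(c("x", "y", "z"), c(7, 3, 2)))
#' form_teams(r)$teams
#' @export
form_teams <- function(interns, min_size = 5) {
  need <- c("intern_id", "program_id", "institution_id", "specialty")
  miss <- setdiff(need, names(interns))
  if (length(miss))
    stop("interns is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  teams <- list(); membership <- list(); k <- 0L; j <- 0L
  ineligible <- character()

  if (nrow(interns)) {
    prog_n <- table(interns$program_id)
    big <- names(prog_n)[prog_n >= min_size]
    for (p in big) {
      k <- k + 1L
      rows <- interns[interns$program_id == p, ]
      tid <- sprintf("P%03d", k)
      teams[[length(teams) + 1L]] <- data.frame(
        team_id = tid, institution_id = rows$institution_id[1L],
        specialty = rows$specialty[1L], team_type = "program",
        n_members = nrow(rows), eligible = TRUE, stringsAsFactors = FALSE)
      membership[[length(membership) + 1L]] <- data.frame(
        intern_id = rows$intern_id, team_id = tid, stringsAsFactors = FALSE)
    }
    rest <- interns[!(interns$program_id %in% big), ]
    for (inst in unique(rest$institution_id)) {
      rows <- rest[rest$institution_id == inst, ]
      if (nrow(rows) >= min_size) {
        j <- j + 1L
        tid <- sprintf("X%03d", j)
        teams[[length(teams) + 1L]] <- data.frame(
          team_id = tid, institution_id = inst, specialty = "MIXED",
          team_type = "institution", n_members = nrow(rows), eligible = TRUE,
          stringsAsFactors = FALSE)
        membership[[length(membership) + 1L]] <- data.frame(
          intern_id = rows$intern_id, team_id = tid, stringsAsFactors = FALSE)
      } else {
        ineligible <- c(ineligible, rows$intern_id)
      }
    }
  }
  if (length(teams)) {
    teams <- do.call(rbind, teams)
    membership <- do.call(rbind, membership)
  } else {
    teams <- data.frame(team_id = character(), institution_id = character(),
                        specialty = character(), team_type = character(),
                        n_members = integer(), eligible = logical(),
                        stringsAsFactors = FALSE)
    membership <- data.frame(intern_id = character(), team_id = character(),
                             stringsAsFactors = FALSE)
  }
  list(teams = teams, membership = membership, ineligible = ineligible)
}

.pairing_rules <- c("total", "intra_institution", "intra_specialty")

#' Randomize one week of team competition
#'
#' Implements the weekly three-factor randomization: (1) each team enters
#' the competition arm independently with probability `p_comp`; (2) one
#' opponent-pairing rule for the week is drawn uniformly from total,
#' intra-institution and intra-specialty randomization (or per pair, see
#' `rule_scope`); (3) competition-arm teams are paired under the rule by
#' uniformly shuffling them and greedily matching each team to the next
#' unpaired team satisfying the constraint; any team left unpaired — the odd
#' leftover, or teams unpairable under a constrained rule — is returned to
#' the non-competition arm and flagged; (4) each realized pair flips a fair
#' coin between a step-count and a sleep-minutes competition.
#'
#' Leftover rows keep the week's pairing rule for bookkeeping; teams never
#' drawn into the competition arm have `NA` rule.  Opponents and competition
#' type are `NA` whenever `in_competition` is `FALSE`.
#'
#' @param teams data frame of eligible teams (`team_id`, `institution_id`,
#'   `specialty`).
#' @param week_index 0-based week number recorded in the output.
#' @param p_comp probability of entering the competition arm (default 1/2).
#' @param rule_scope `"week"` (default): one pairing rule drawn for the
#'   whole week; `"pair"`: the rule is redrawn for each successive pairing.
#' @param rule force this pairing rule instead of drawing one (design
#'   diagnostics only); `NULL` to draw.
#' @return Data frame with one row per team: `team_id`, `week_index`,
#'   `in_competition`, `pairing_rule`, `opponent_team_id`,
#'   `competition_type`, `leftover`.
#' @examples
#' tm <- data.frame(team_id = c("A", "B", "C"),
#'                  institution_id = c("H1", "H1", "H2"),
#'                  specialty = c("s1", "s2", "s1"))
#' set.seed(42)
#' randomize_week(tm, week_index = 0)
#' @export
randomize_week <- function(teams, week_index = 0L, p_comp = 0.5,
                           rule_scope = c("week", "pair"), rule = NULL) {
  rule_scope <- match.arg(rule_scope)
  if (!is.null(rule)) rule <- match.arg(rule, .pairing_rules)
  nt <- nrow(teams)
  out <- data.frame(
    team_id = teams$team_id,
    week_index = rep(as.integer(week_index), nt),
    in_competition = rep(FALSE, nt),
    pairing_rule = rep(NA_character_, nt),
    opponent_team_id = rep(NA_character_, nt),
    competition_type = rep(NA_character_, nt),
    leftover = rep(FALSE, nt),
    stringsAsFactors = FALSE
  )
  if (nt == 0L) return(out)

  drawn <- stats::runif(nt) < p_comp
  week_rule <- if (is.null(rule)) sample(.pairing_rules, 1L) else rule
  pool <- which(drawn)
  if (length(pool) < 2L) {
    out$leftover[pool] <- TRUE
    out$pairing_rule[pool] <- week_rule
    return(out)
  }

  pool <- pool[sample.int(length(pool))]   # uniform shuffle: exchangeable leftover
  paired <- logical(nt)
  for (i in seq_along(pool)) {
    a <- pool[i]
    if (paired[a]) next
    this_rule <- if (rule_scope == "pair" && is.null(rule))
      sample(.pairing_rules, 1L) else week_rule
    for (j in seq_along(pool)) {
      if (j <= i) next
      b <- pool[j]
      if (paired[b]) next
      ok <- switch(this_rule,
        total = TRUE,
        intra_institution =
          teams$institution_id[a] == teams$institution_id[b],
        intra_specialty = teams$specialty[a] == teams$specialty[b])
      if (ok) {
        paired[a] <- paired[b] <- TRUE
        out$in_competition[c(a, b)] <- TRUE
        out$pairing_rule[c(a, b)] <- this_rule
        out$opponent_team_id[a] <- teams$team_id[b]
        out$opponent_team_id[b] <- teams$team_id[a]
        out$competition_type[c(a, b)] <- sample(c("step", "sleep"), 1L)
        break
      }
    }
  }
  left <- pool[!paired[pool]]
  out$leftover[left] <- TRUE
  if (rule_scope == "week" || !is.null(rule))
    out$pairing_rule[left] <- week_rule
  out
}

#' Randomize a full study of weekly competitions
#'
#' Calls [randomize_week()] once per week and stacks the assignments.
#'
#' @inheritParams randomize_week
#' @param n_weeks number of weekly episodes.
#' @return Data frame of assignments, `n_weeks` rows per team.
#' @export
randomize_trial <- function(teams, n_weeks = 12, p_comp = 0.5,
                            rule_scope = c("week", "pair")) {
  rule_scope <- match.arg(rule_scope)
  do.call(rbind, lapply(seq_len(n_weeks) - 1L, function(w)
    randomize_week(teams, w, p_comp = p_comp, rule_scope = rule_scope)))
}

#' Realized per-team competition probability under the leftover rule
#'
#' The odd-leftover rule makes the realized probability of being in a
#' competition strictly below the nominal coin probability.  This design
#' diagnostic estimates the per-team realized probability by Monte Carlo.
#'
#' @param teams data frame of teams.
#' @param rule force one pairing rule every simulated week (one of
#'   `"total"`, `"intra_institution"`, `"intra_specialty"`), or `NULL`
#'   to draw a rule per week as in the trial.
#' @param n_reps number of simulated weeks (>= 1).
#' @param p_comp nominal coin probability.
#' @return Data frame: `team_id`, `prob` (empirical in-competition
#'   probability), `se` (binomial standard error).
#' @examples
#' tm <- data.frame(team_id = c("A", "B"), institution_id = "H1",
#'                  specialty = "s")
#' set.seed(7)
#' realized_treatment_probability(tm, rule = "total", n_reps = 2000)
#' @export
realized_treatment_probability <- function(teams, rule = NULL, n_reps = 1000,
                                           p_comp = 0.5) {
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  hits <- numeric(nrow(teams))
  for (r in seq_len(n_reps)) {
    a <- randomize_week(teams, 0L, p_comp = p_comp, rule = rule)
    hits <- hits + a$in_competition
  }
  p <- hits / n_reps
  data.frame(team_id = teams$team_id, prob = p,
             se = sqrt(p * (1 - p) / n_reps), stringsAsFactors = FALSE)
}
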