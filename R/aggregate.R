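#' Collapse daily records to the team-week analysis table
#'
#' The team is the unit of randomization and of analysis: all inference
#' runs on one row per team per week.  Outcome summaries average members'
#' weekly means; participation rates count observed person-days against the
#' full member-week denominator; team-level baseline covariates and lagged
#' (previous-week) outcomes are attached as control variables, with week 0
#' anchored at the team's pre-internship baseline averages.
#'
#' Two definitions of the team-week outcome mean are supported.  The
#' default, `"member_mean"`, averages the weekly means of members with at
#' least one observed day, so each intern contributes equally regardless of
#' how many days they recorded.  `"pooled"` averages over all observed
#' person-days.  The two coincide on complete (or imputed) data.
#'
#' @param records daily records (long, `NA` = missing).
#' @param interns intern table (membership, sex, baseline covariates).
#' @param assignments weekly treatment assignments from [randomize_trial()].
#' @param method team-week mean definition, see Details.
#' @return Data frame, one row per team-week, sorted by team then week:
#'   outcome means (`mean_daily_steps`, `mean_daily_sleep_min`,
#'   `mean_mood`), participation rates, member counts, team covariates
#'   (`pct_female`, `baseline_mean_steps`, `baseline_mean_sleep`,
#'   `baseline_mean_phq9`), previous-week outcomes (`prev_week_steps`,
#'   `prev_week_sleep`, `prev_week_mood`; `prev_is_baseline` flags week 0),
#'   the assignment columns, and 0/1 treatment indicators `trt_step`
#'   (competing on steps), `trt_sleep`, `trt_any`, plus pairing-moderator
#'   flags `intra_institution`, `intra_specialty` (0 in non-competition
#'   weeks).
#' @examples
#' set.seed(3)
#' tr <- simulate_trial(sim_config(n_teams = 4, n_institutions = 2,
#'                                 n_weeks = 2))
#' tw <- aggregate_team_week(tr$records, tr$interns, tr$assignments)
#' head(tw[, c("team_id", "week_index", "mean_daily_steps",
#'             "participation_rate_steps", "trt_step")])
#' @export
aggregate_team_week <- function(records, interns, assignments,
                                method = c("member_mean", "pooled")) {
  method <- match.arg(method)
  team_ids <- sort(unique(interns$team_id))
  W <- max(records$week_index) + 1L
  if (!all(records$intern_id %in% interns$intern_id))
    stop("records contain interns not in the roster", call. = FALSE)
  memb_n <- table(factor(interns$team_id, levels = team_ids))
  if (any(memb_n == 0))
    stop("team(s) with zero members: ",
         paste(team_ids[memb_n == 0], collapse = ", "), call. = FALSE)

  ii <- match(records$intern_id, interns$intern_id)
  tw_team <- interns$team_id[ii]
  # intern-week grouping
  gi <- (ii - 1L) * W + records$week_index + 1L
  n_iw <- nrow(interns) * W
  iw_team <- rep(interns$team_id, each = W)
  iw_week <- rep(0:(W - 1L), nrow(interns))
  # team-week grouping of intern-weeks
  gtw <- (match(iw_team, team_ids) - 1L) * W + iw_week + 1L
  n_tw <- length(team_ids) * W

  out <- data.frame(
    team_id = rep(team_ids, each = W),
    week_index = rep(0:(W - 1L), length(team_ids)),
    stringsAsFactors = FALSE)

  sum_by <- function(x, g, n) {
    r <- rep(0, n); s <- rowsum(x, g); r[as.integer(rownames(s))] <- s; r
  }

  outcome_cols <- c(steps = "steps", sleep = "sleep_min", mood = "mood")
  out_names <- c(steps = "mean_daily_steps", sleep = "mean_daily_sleep_min",
                 mood = "mean_mood")
  for (o in names(outcome_cols)) {
    y <- records[[outcome_cols[[o]]]]
    obs <- !is.na(y)
    s_iw <- sum_by(ifelse(obs, y, 0), gi, n_iw)
    c_iw <- sum_by(as.numeric(obs), gi, n_iw)
    if (method == "member_mean") {
      m_iw <- ifelse(c_iw > 0, s_iw / c_iw, NA_real_)
      s_tw <- sum_by(ifelse(c_iw > 0, m_iw, 0), gtw, n_tw)
      k_tw <- sum_by(as.numeric(c_iw > 0), gtw, n_tw)
      out[[out_names[[o]]]] <- ifelse(k_tw > 0, s_tw / k_tw, NA_real_)
    } else {
      s_tw <- sum_by(s_iw, gtw, n_tw)
      c_tw <- sum_by(c_iw, gtw, n_tw)
      out[[out_names[[o]]]] <- ifelse(c_tw > 0, s_tw / c_tw, NA_real_)
    }
    if (o != "mood") {
      c_tw_days <- sum_by(c_iw, gtw, n_tw)
      denom <- 7 * as.numeric(memb_n)[match(out$team_id, team_ids)]
      out[[paste0("participation_rate_", o)]] <- c_tw_days / denom
    }
  }
  out$n_members <- as.numeric(memb_n)[match(out$team_id, team_ids)]

  # team-level baseline covariates
  tt <- match(interns$team_id, team_ids)
  agg_team <- function(x) as.numeric(tapply(x, factor(tt, 1:length(team_ids)),
                                            mean))
  cov <- data.frame(
    team_id = team_ids,
    pct_female = agg_team(as.numeric(interns$sex == "female")),
    baseline_mean_steps = agg_team(interns$baseline_steps),
    baseline_mean_sleep = agg_team(interns$baseline_sleep),
    baseline_mean_phq9 = agg_team(interns$phq9),
    baseline_mean_mood = agg_team(
      if (is.null(interns$baseline_mood)) rep(NA_real_, nrow(interns))
      else interns$baseline_mood),
    stringsAsFactors = FALSE)
  out <- merge(out, cov, by = "team_id", sort = FALSE)

  # previous-week outcomes; week 0 anchored at the baseline team means
  lag1 <- function(cur, base) {
    prev <- c(NA_real_, cur[-length(cur)])
    prev[out$week_index == 0] <- base[out$week_index == 0]
    prev
  }
  out <- out[order(out$team_id, out$week_index), ]
  out$prev_week_steps <- lag1(out$mean_daily_steps, out$baseline_mean_steps)
  out$prev_week_sleep <- lag1(out$mean_daily_sleep_min,
                              out$baseline_mean_sleep)
  out$prev_week_mood <- lag1(out$mean_mood, out$baseline_mean_mood)
  out$prev_is_baseline <- out$week_index == 0

  akey <- paste(assignments$team_id, assignments$week_index)
  arow <- match(paste(out$team_id, out$week_index), akey)
  if (anyNA(arow))
    stop("assignments missing for some team-weeks", call. = FALSE)
  out$in_competition <- assignments$in_competition[arow]
  out$competition_type <- assignments$competition_type[arow]
  out$pairing_rule <- assignments$pairing_rule[arow]
  out$leftover <- assignments$leftover[arow]
  out$trt_any <- as.numeric(out$in_competition)
  out$trt_step <- as.numeric(out$in_competition &
                             !is.na(out$competition_type) &
                             out$competition_type == "step")
  out$trt_sleep <- as.numeric(out$in_competition &
                              !is.na(out$competition_type) &
                              out$competition_type == "sleep")
  out$intra_institution <- as.numeric(out$in_competition &
                                      !is.na(out$pairing_rule) &
                                      out$pairing_rule == "intra_institution")
  out$intra_specialty <- as.numeric(out$in_competition &
                                    !is.na(out$pairing_rule) &
                                    out$pairing_rule == "intra_specialty")
  out$week <- out$week_index
  rownames(out) <- NULL
  out
}
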