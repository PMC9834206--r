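#' Raking (iterative proportional fitting) of survey weights
#'
#' Reweights a sample so that the weighted marginal distribution of each
#' raking variable matches a population target.  Starting from the base
#' weights, the algorithm cycles over the listed variables, multiplying the
#' weights in each category by `target share / weighted sample share`,
#' until the largest relative deviation of any weighted margin from its
#' target is below `tol` or `max_iter` cycles are reached.  With a single
#' raking variable this is one-shot post-stratification.
#'
#' @param sample data frame holding the raking variables.
#' @param margins named list: for each raking variable, a named vector of
#'   target shares (normalized internally to sum to 1).
#' @param vars which variables to rake on (default: all of `names(margins)`).
#' @param base_weights starting weights (default 1).
#' @param tol convergence tolerance on the maximum relative margin
#'   deviation (default 1e-8).
#' @param max_iter maximum number of full cycles.
#' @param normalize if `TRUE` (default) scale the result to mean 1.
#' @return Numeric weight vector with attributes `converged`, `iterations`
#'   and `max_dev`.
#' @examples
#' s <- data.frame(sex = c("f", "f", "m"))
#' w <- rake(s, list(sex = c(f = 0.5, m = 0.5)))
#' round(tapply(w, s$sex, sum) / sum(w), 6)
#' @export
rake <- function(sample, margins, vars = names(margins), base_weights = 1,
                 tol = 1e-8, max_iter = 100, normalize = TRUE) {
  n <- nrow(sample)
  w <- rep_len(base_weights, n)
  if (any(w <= 0)) stop("base weights must be positive", call. = FALSE)
  for (v in vars) {
    if (!v %in% names(sample))
      stop("raking variable '", v, "' not in sample", call. = FALSE)
    tgt <- margins[[v]]
    if (is.null(tgt) || is.null(names(tgt)))
      stop("margins for '", v, "' must be a named vector", call. = FALSE)
    extra <- setdiff(unique(as.character(sample[[v]])), names(tgt))
    if (length(extra))
      stop("sample categories of '", v, "' missing from margins: ",
           paste(extra, collapse = ", "), call. = FALSE)
    absent <- names(tgt)[tgt > 0 &
                         !(names(tgt) %in% as.character(sample[[v]]))]
    if (length(absent))
      stop("cannot converge: no sample units in '", v, "' category ",
           paste(absent, collapse = ", "), " with positive target mass",
           call. = FALSE)
  }

  max_dev <- Inf; it <- 0L
  dev_of <- function(w) {
    devs <- vapply(vars, function(v) {
      tgt <- margins[[v]] / sum(margins[[v]])
      sh <- tapply(w, factor(as.character(sample[[v]]), names(tgt)), sum)
      sh[is.na(sh)] <- 0
      sh <- sh / sum(w)
      max(abs(sh - tgt) / pmax(tgt, .Machine$double.eps))
    }, numeric(1))
    max(devs)
  }
  while (it < max_iter) {
    it <- it + 1L
    for (v in vars) {
      tgt <- margins[[v]] / sum(margins[[v]])
      f <- factor(as.character(sample[[v]]), names(tgt))
      sh <- tapply(w, f, sum)
      sh[is.na(sh)] <- 0
      sh <- sh / sum(w)
      adj <- as.numeric(ifelse(sh > 0, tgt / sh, 1))
      w <- as.numeric(w * adj[as.integer(f)])
    }
    max_dev <- dev_of(w)
    if (max_dev < tol) break
  }
  if (normalize) w <- w / mean(w)
  attr(w, "converged") <- max_dev < tol
  attr(w, "iterations") <- it
  attr(w, "max_dev") <- max_dev
  w
}

#' Two-step post-stratification raking weights
#'
#' Builds the final weight `w = w1 * w2` matching a convenience sample to
#' reference population margins in two steps: `w1` rakes on specialty;
#' then, separately within the surgical and nonsurgical specialty groups,
#' `w2` rakes on sex and race starting from the `w1`-weighted sample.
#' Sample race categories outside the reference categories (White, Asian,
#' underrepresented minority) are collapsed into `"urm_other"` by
#' `race_map`.
#'
#' @param interns intern table with `specialty`, `sex`, `race`.
#' @param margins list with components:
#'   \describe{
#'     \item{specialty}{named target shares over specialties.}
#'     \item{surgical_specialties}{character vector of specialty names
#'       counted as surgical.}
#'     \item{sex}{list with named target vectors `surgical` and
#'       `nonsurgical` over `c("female", "male")`.}
#'     \item{race}{list with named target vectors `surgical` and
#'       `nonsurgical` over `c("white", "asian", "urm_other")`.}
#'   }
#' @param race_map named character vector mapping sample race categories to
#'   reference categories; unmapped categories collapse to `"urm_other"`.
#' @param trim quantile pair for optional weight trimming (e.g.
#'   `c(0.01, 0.99)`); `NULL` (default) for no trimming.
#' @param tol,max_iter passed to [rake()].
#' @return Data frame: `intern_id` (if present), `w1`, `w2`, `w`
#'   (normalized to mean 1), with attribute `converged`.
#' @export
two_step_weights <- function(interns, margins,
                             race_map = c(white = "white", asian = "asian"),
                             trim = NULL, tol = 1e-8, max_iter = 100) {
  need <- c("specialty", "sex", "race")
  miss <- setdiff(need, names(interns))
  if (length(miss))
    stop("interns missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  race3 <- race_map[as.character(interns$race)]
  race3[is.na(race3)] <- "urm_other"

  w1 <- rake(interns, list(specialty = margins$specialty),
             tol = tol, max_iter = max_iter, normalize = FALSE)
  conv <- attr(w1, "converged")

  grp <- ifelse(interns$specialty %in% margins$surgical_specialties,
                "surgical", "nonsurgical")
  w <- as.numeric(w1)
  for (g in unique(grp)) {
    i <- grp == g
    sub <- data.frame(sex = interns$sex[i], race = race3[i],
                      stringsAsFactors = FALSE)
    wg <- rake(sub, list(sex = margins$sex[[g]], race = margins$race[[g]]),
               base_weights = w1[i], tol = tol, max_iter = max_iter,
               normalize = FALSE)
    conv <- conv && attr(wg, "converged")
    w[i] <- as.numeric(wg)
  }
  w2 <- w / as.numeric(w1)
  wf <- w / mean(w)
  if (!is.null(trim)) {
    q <- stats::quantile(wf, trim)
    wf <- pmin(pmax(wf, q[1]), q[2])
    wf <- wf / mean(wf)
  }
  out <- data.frame(w1 = as.numeric(w1), w2 = w2, w = wf)
  if ("intern_id" %in% names(interns))
    out <- cbind(intern_id = interns$intern_id, out, stringsAsFactors = FALSE)
  attr(out, "converged") <- conv
  out
}

#' Aggregate intern-level weights to team-level analysis weights
#'
#' Team-level fits take one weight per team-week row; the default
#' aggregation is the mean of member weights.
#'
#' @param weights data frame from [two_step_weights()] with `intern_id`.
#' @param interns intern table with `intern_id`, `team_id`.
#' @param fun aggregation function (default `mean`).
#' @return Data frame `team_id`, `w`.
#' @export
team_weights <- function(weights, interns, fun = mean) {
  w <- weights$w[match(interns$intern_id, weights$intern_id)]
  agg <- tapply(w, interns$team_id, fun)
  data.frame(team_id = names(agg), w = as.numeric(agg),
             stringsAsFactors = FALSE)
}
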