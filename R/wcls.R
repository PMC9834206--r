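#' Weighted-and-centered least squares for proximal causal excursion effects
#'
#' Fits the weighted-and-centered least squares (WCLS) estimator of the
#' proximal causal excursion effect of a binary, sequentially randomized
#' treatment on a cluster-level longitudinal outcome, with a cluster-robust
#' sandwich variance.  The model has two parts: a working model for the
#' controls (the right-hand side of `formula`, coefficients \eqn{\alpha})
#' and the causal part \eqn{(A - \tilde p)(\beta_0 + \beta' S)} built from
#' the centered treatment and the moderators in `moderator`.  Each row is
#' weighted by \eqn{\tilde p / p} when treated and
#' \eqn{(1-\tilde p)/(1-p)} otherwise, which makes the \eqn{\beta}
#' coefficients consistent for the moderated causal effect even when the
#' control working model is misspecified.  With constant
#' `prob == prob_tilde` all weights equal 1 and the fit reduces exactly to
#' ordinary least squares on the centered treatment columns.
#'
#' Inference uses the sandwich variance with independence working
#' correlation, clustered on `cluster` (here, the team): this is the
#' generalized-estimating-equation fit with independent working correlation
#' and robust standard errors.  No small-sample correction is applied by
#' default; `vcov_type = "mancl-derouen"` applies the Mancl–DeRouen
#' bias-corrected meat.
#'
#' @param formula outcome ~ control terms (the working model; an intercept
#'   is included unless removed in the formula).
#' @param data a team-week data frame, one row per cluster-period, e.g.
#'   from [aggregate_team_week()].
#' @param treatment name of the binary (0/1 or logical) treatment column.
#' @param cluster name of the cluster id column (unit of randomization).
#' @param moderator one-sided formula of effect moderators `S`
#'   (default `~ 1`: marginal effect only).
#' @param prob randomization probability \eqn{p}: scalar or per-row vector.
#' @param prob_tilde centering probability \eqn{\tilde p}: scalar or
#'   per-row vector in (0, 1).
#' @param weights optional extra per-row analysis weights (e.g. team-level
#'   post-stratification weights), multiplied into the WCLS weights.
#' @param vcov_type `"none"` (plain cluster sandwich, default) or
#'   `"mancl-derouen"`.
#' @param drop_aliased if `TRUE`, drop collinear/inestimable columns with a
#'   message instead of failing; dropped names are recorded in the fit.
#' @return An object of class `"wcls"` with methods [print()],
#'   [summary()], [coef()], [vcov()], [confint()], [residuals()],
#'   [fitted()], [predict()] and [plot()].  Causal (`beta`) coefficient
#'   names are prefixed with the treatment column name.
#' @examples
#' set.seed(5)
#' tr <- simulate_trial(sim_config(n_teams = 30, n_institutions = 10),
#'                      missingness = FALSE)
#' tw <- aggregate_team_week(tr$records, tr$interns, tr$assignments)
#' fit <- wcls(mean_daily_steps ~ week + pct_female + baseline_mean_steps +
#'               prev_week_steps,
#'             data = tw, treatment = "trt_step", cluster = "team_id",
#'             moderator = ~ week)
#' summary(fit)
#' @export
wcls <- function(formula, data, treatment, cluster, moderator = ~ 1,
                 prob = 0.5, prob_tilde = 0.5, weights = NULL,
                 vcov_type = c("none", "mancl-derouen"),
                 drop_aliased = FALSE) {
  vcov_type <- match.arg(vcov_type)
  cl_call <- match.call()
  if (!treatment %in% names(data))
    stop("treatment column '", treatment, "' not found", call. = FALSE)
  if (!cluster %in% names(data))
    stop("cluster column '", cluster, "' not found", call. = FALSE)

  A <- data[[treatment]]
  if (is.logical(A)) A <- as.numeric(A)
  if (!all(A %in% c(0, 1) | is.na(A)))
    stop("treatment must be binary 0/1", call. = FALSE)

  n0 <- nrow(data)
  p <- rep_len(prob, n0)
  pt <- rep_len(prob_tilde, n0)
  if (any(p <= 0 | p >= 1) || any(pt <= 0 | pt >= 1))
    stop("prob and prob_tilde must lie in (0, 1)", call. = FALSE)
  uw <- if (is.null(weights)) rep(1, n0) else rep_len(weights, n0)

  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  Xc <- stats::model.matrix(stats::terms(formula, data = data), mf)
  Xm <- stats::model.matrix(moderator, stats::model.frame(
    moderator, data, na.action = stats::na.pass))

  keep <- stats::complete.cases(y, Xc, Xm, A, data[[cluster]], uw)
  n_dropped <- sum(!keep)
  y <- y[keep]; Xc <- Xc[keep, , drop = FALSE]
  Xm <- Xm[keep, , drop = FALSE]
  A <- A[keep]; p <- p[keep]; pt <- pt[keep]; uw <- uw[keep]
  cl <- data[[cluster]][keep]
  n <- length(y)
  if (n == 0L) stop("no complete rows to fit", call. = FALSE)

  Ac <- A - pt
  Xb <- Xm * Ac
  bn <- colnames(Xm)
  colnames(Xb) <- ifelse(bn == "(Intercept)", treatment,
                         paste(treatment, bn, sep = ":"))
  X <- cbind(Xc, Xb)
  alpha_idx <- seq_len(ncol(Xc))
  w <- uw * ifelse(A == 1, pt / p, (1 - pt) / (1 - p))

  sw <- sqrt(w)
  qrx <- qr(X * sw)
  rank <- qrx$rank
  dropped <- character()
  if (rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(rank + 1L):ncol(X)]]
    if (!drop_aliased)
      stop("singular design; collinear/inestimable term(s): ",
           paste(aliased, collapse = ", "), call. = FALSE)
    message("dropping inestimable term(s): ", paste(aliased, collapse = ", "))
    dropped <- aliased
    keep_col <- setdiff(colnames(X), aliased)
    X <- X[, keep_col, drop = FALSE]
    alpha_idx <- which(keep_col %in% colnames(Xc))
    qrx <- qr(X * sw)
  }

  beta_hat <- qr.coef(qrx, y * sw)
  e <- y - drop(X %*% beta_hat)
  XtWX <- crossprod(X * sw)
  bread <- chol2inv(chol(XtWX))
  dimnames(bread) <- list(colnames(X), colnames(X))

  if (vcov_type == "mancl-derouen") {
    U <- matrix(0, length(unique(cl)), ncol(X),
                dimnames = list(unique(cl), colnames(X)))
    for (g in unique(cl)) {
      i <- which(cl == g)
      Xg <- X[i, , drop = FALSE]
      Hg <- Xg %*% bread %*% t(Xg * w[i])
      eg <- solve(diag(length(i)) - Hg, e[i])
      U[g, ] <- colSums(Xg * (w[i] * eg))
    }
    meat <- crossprod(U)
  } else {
    U <- rowsum(X * (w * e), group = cl)
    meat <- crossprod(as.matrix(U))
  }
  V <- bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))

  fit <- list(
    coefficients = stats::setNames(beta_hat, colnames(X)),
    vcov = V,
    alpha_terms = colnames(X)[alpha_idx],
    beta_terms = setdiff(colnames(X), colnames(X)[alpha_idx]),
    residuals = e,
    fitted.values = drop(X %*% beta_hat),
    weights = w,
    prob = p, prob_tilde = pt,
    treatment = treatment, cluster = cluster,
    n = n, n_clusters = length(unique(cl)), n_dropped_rows = n_dropped,
    dropped_terms = dropped,
    formula = formula, moderator = moderator,
    X = X, y = y, cluster_id = cl,
    vcov_type = vcov_type,
    call = cl_call
  )
  class(fit) <- "wcls"
  fit
}

#' @export
coef.wcls <- function(object, ...) object$coefficients

#' @export
vcov.wcls <- function(object, ...) object$vcov

#' @export
residuals.wcls <- function(object, ...) object$residuals

#' @export
fitted.wcls <- function(object, ...) object$fitted.values

#' @export
confint.wcls <- function(object, parm, level = 0.95, ...) {
  cf <- coef(object)
  se <- sqrt(diag(vcov(object)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(cf - z * se, cf + z * se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.wcls <- function(x, digits = 4, ...) {
  cat("Weighted-and-centered least squares (cluster-robust)\n")
  cat("  clusters:", x$n_clusters, "  rows:", x$n,
      if (x$n_dropped_rows) paste0("  (", x$n_dropped_rows,
                                   " incomplete rows dropped)") else "", "\n")
  cat("Causal (beta) coefficients:\n")
  print(round(coef(x)[x$beta_terms], digits))
  invisible(x)
}

#' @rdname wcls
#' @param object,x a fitted `"wcls"` object.
#' @param ... unused.
#' @export
summary.wcls <- function(object, ...) {
  cf <- coef(object)
  se <- sqrt(diag(vcov(object)))
  z <- cf / se
  z[se == 0 & cf == 0] <- 0
  p <- 2 * stats::pnorm(-abs(z))
  tab <- cbind(Estimate = cf, `Robust SE` = se,
               `CI lower` = cf - 1.96 * se, `CI upper` = cf + 1.96 * se,
               `z value` = z, `Pr(>|z|)` = p)
  out <- list(coefficients = tab, beta_terms = object$beta_terms,
              alpha_terms = object$alpha_terms,
              n = object$n, n_clusters = object$n_clusters,
              treatment = object$treatment, call = object$call,
              dropped_terms = object$dropped_terms)
  class(out) <- "summary.wcls"
  out
}

#' @export
print.summary.wcls <- function(x, digits = 4, ...) {
  cat("Weighted-and-centered least squares fit\n")
  cat("Call: "); print(x$call)
  cat(sprintf("%d rows in %d clusters; Wald tests on cluster-robust SEs\n\n",
              x$n, x$n_clusters))
  cat("Causal effect terms (beta):\n")
  stats::printCoefmat(x$coefficients[x$beta_terms, , drop = FALSE],
                      digits = digits, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nControl terms (alpha):\n")
  stats::printCoefmat(x$coefficients[x$alpha_terms, , drop = FALSE],
                      digits = digits, P.values = TRUE, has.Pvalue = TRUE)
  if (length(x$dropped_terms))
    cat("\nDropped (inestimable):", paste(x$dropped_terms, collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
predict.wcls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  stop("predict on new data is not supported; refit with the new rows",
       call. = FALSE)
}

#' Extract the estimated causal effect curve over weeks
#'
#' For a fit whose moderator set includes the week-in-study, evaluates the
#' estimated causal excursion effect \eqn{\beta' f(w)} on a grid of weeks
#' with delta-method pointwise confidence intervals.
#'
#' @param fit a `"wcls"` fit with moderator terms that are functions of
#'   `week` (e.g. `~ week` or a spline basis).
#' @param weeks integer grid (default `0:11`).
#' @param level confidence level.
#' @return Data frame of class `"effect_curve"`: `week`, `estimate`, `se`,
#'   `lower`, `upper`.
#' @export
effect_curve <- function(fit, weeks = 0:11, level = 0.95) {
  stopifnot(inherits(fit, "wcls"))
  Xm <- stats::model.matrix(fit$moderator, data.frame(week = weeks))
  bt <- fit$beta_terms
  B <- coef(fit)[bt]
  Vb <- vcov(fit)[bt, bt, drop = FALSE]
  est <- drop(Xm %*% B)
  se <- sqrt(rowSums((Xm %*% Vb) * Xm))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(week = weeks, estimate = est, se = se,
                    lower = est - z * se, upper = est + z * se)
  class(out) <- c("effect_curve", "data.frame")
  out
}

#' @export
plot.wcls <- function(x, weeks = 0:11, ...) {
  ec <- effect_curve(x, weeks)
  plot(ec, ...)
  invisible(x)
}

#' @export
plot.effect_curve <- function(x, ylab = "causal effect", xlab = "week in study",
                              ...) {
  plot(x$week, x$estimate, type = "l", ylim = range(x$lower, x$upper),
       xlab = xlab, ylab = ylab, ...)
  graphics::lines(x$week, x$lower, lty = 2)
  graphics::lines(x$week, x$upper, lty = 2)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}
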