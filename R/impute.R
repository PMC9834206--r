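#' Multiple imputation of daily outcomes by chained predictive mean matching
#'
#' Imputes missing daily step counts, sleep minutes and mood scores with
#' chained equations and predictive mean matching (PMM).  For each target,
#' a linear regression on the predictor set is fit over the observed rows;
#' each imputation draws regression parameters from their Bayesian
#' posterior (or a bootstrap refit), computes predicted means for observed
#' and missing rows, matches every missing row to its `k_donors` nearest
#' observed predicted means, and copies one randomly chosen donor's
#' observed value — so imputed values always lie within the observed
#' support.  The chained sweep cycles steps, then sleep, then mood,
#' `n_sweeps` times per dataset, and `M` independent datasets are produced.
#'
#' The predictor set for every target is: the three outcomes lagged 1-3
#' days (lags before the study start use the intern's pre-internship
#' baselines), the previous week's intern mean of each outcome, sex,
#' PHQ-9, neuroticism, early family environment, and the intern's
#' institution and specialty.  Institution and specialty enter as grouped
#' mean-encoded predictors (the observed target mean of the group) rather
#' than indicator blocks, which keeps the within-trial regression stable
#' with ~90 institutions.  Lags that cross missing cells use the sweep's
#' current completed data, so autocorrelation in the outcomes is exploited.
#'
#' @param records daily records with `NA` for missing cells (long format,
#'   columns `intern_id`, `day_index`, `week_index`, `steps`, `sleep_min`,
#'   `mood`).
#' @param interns intern table with the baseline predictors
#'   (`sex`, `phq9`, `neuroticism`, `early_family_env`, `institution_id`,
#'   `specialty`, `baseline_steps`, `baseline_sleep`, optionally
#'   `baseline_mood`).
#' @param M number of imputed datasets (default 20).
#' @param n_sweeps chained-equation sweeps per dataset (default 10).
#' @param k_donors PMM donor-pool size (default 5).
#' @param draw `"bayes"` (posterior draw of the regression parameters,
#'   proper MI; default), `"boot"` (bootstrap refit), or `"mle"` (no draw;
#'   deterministic predicted means, useful for diagnostics).
#' @return A list of `M` completed record data frames (observed cells
#'   untouched).
#' @seealso [pool_rubin()] to combine per-imputation estimates.
#' @export
impute_pmm <- function(records, interns, M = 20, n_sweeps = 10, k_donors = 5,
                       draw = c("bayes", "boot", "mle")) {
  draw <- match.arg(draw)
  stopifnot(M >= 1, k_donors >= 1, n_sweeps >= 1)
  targets <- c(steps = "steps", sleep = "sleep_min", mood = "mood")
  base_col <- c(steps = "baseline_steps", sleep = "baseline_sleep",
                mood = "baseline_mood")

  ord <- order(match(records$intern_id, interns$intern_id),
               records$day_index)
  records <- records[ord, ]
  n <- nrow(interns)
  D <- length(unique(records$day_index))
  W <- max(records$week_index) + 1L
  stopifnot(nrow(records) == n * D)
  week_of_day <- records$week_index[seq_len(D)]

  Yobs <- lapply(targets, function(col) matrix(records[[col]], D, n))
  obs <- lapply(Yobs, function(m) !is.na(m))
  for (t in names(targets)) {
    if (!any(obs[[t]]))
      stop("unimputable: no observed values for '", targets[[t]], "'",
           call. = FALSE)
  }
  if (all(vapply(obs, all, logical(1))))
    return(replicate(M, records, simplify = FALSE))

  # static predictors (per intern, recycled over days)
  static <- cbind(
    female = as.numeric(interns$sex == "female"),
    phq9 = interns$phq9,
    neuroticism = interns$neuroticism,
    early_family_env = interns$early_family_env)
  drop_static <- apply(static, 2, function(x) all(is.na(x)) ||
                         stats::sd(x, na.rm = TRUE) == 0)
  if (any(is.na(static))) {
    warning("static predictor(s) with missing values dropped: ",
            paste(colnames(static)[colSums(is.na(static)) > 0],
                  collapse = ", "))
    drop_static <- drop_static | colSums(is.na(static)) > 0
  }
  static <- static[, !drop_static, drop = FALSE]

  # grouped mean encoding of institution and specialty per target
  enc <- function(group, t) {
    y <- Yobs[[t]]
    gsum <- tapply(colSums(y * obs[[t]], na.rm = TRUE), group, sum)
    gcnt <- tapply(colSums(obs[[t]]), group, sum)
    gm <- ifelse(gcnt > 0, gsum / gcnt, NA)
    gm[is.na(gm)] <- sum(y[obs[[t]]]) / sum(obs[[t]])
    as.numeric(gm[match(group, names(gm))])
  }
  inst_enc <- lapply(names(targets), function(t) enc(interns$institution_id, t))
  spec_enc <- lapply(names(targets), function(t) enc(interns$specialty, t))
  names(inst_enc) <- names(spec_enc) <- names(targets)

  baselines <- lapply(names(targets), function(t) {
    b <- interns[[base_col[[t]]]]
    if (is.null(b)) b <- rep(mean(Yobs[[t]][obs[[t]]]), n)
    b
  })
  names(baselines) <- names(targets)

  lag_mat <- function(Y, k, base) cbind(matrix(base, n, k),
                                        t(Y)[, seq_len(D - k), drop = FALSE])
  prevweek_mat <- function(Y, base) {
    wk_mean <- t(rowsum(Y, group = week_of_day) /
                   as.vector(table(week_of_day)))       # n x W
    prev <- cbind(base, wk_mean[, -W, drop = FALSE])    # lag one week
    prev[, week_of_day + 1L, drop = FALSE]              # expand to days, n x D
  }

  build_X <- function(Ycur) {
    # returns (n*D) x p predictor matrix, rows in day-within-intern order
    parts <- list(intercept = rep(1, n * D))
    for (t in names(targets)) {
      for (k in 1:3)
        parts[[paste0(t, "_lag", k)]] <-
          as.vector(t(lag_mat(Ycur[[t]], k, baselines[[t]])))
      parts[[paste0(t, "_prevweek")]] <-
        as.vector(t(prevweek_mat(Ycur[[t]], baselines[[t]])))
    }
    X <- do.call(cbind, parts)
    X <- cbind(X, static[rep(seq_len(n), each = D), , drop = FALSE])
    X
  }

  out <- vector("list", M)
  for (m in seq_len(M)) {
    Ycur <- lapply(names(targets), function(t) {
      Y <- Yobs[[t]]
      nm <- sum(!obs[[t]])
      Y[!obs[[t]]] <- sample(Y[obs[[t]]], nm, replace = TRUE)
      Y
    })
    names(Ycur) <- names(targets)
    for (s in seq_len(n_sweeps)) {
      for (t in names(targets)) {
        mis <- !obs[[t]]
        if (!any(mis)) next
        X <- build_X(Ycur)
        X <- cbind(X, inst = inst_enc[[t]][rep(seq_len(n), each = D)],
                   spec = spec_enc[[t]][rep(seq_len(n), each = D)])
        yv <- as.vector(Ycur[[t]])          # D x n, column-wise = record order
        ov <- as.vector(obs[[t]])
        Ycur[[t]] <- fill_pmm(X, yv, ov, as.vector(Yobs[[t]]),
                              k_donors, draw, n, D)
      }
    }
    filled <- records
    for (t in names(targets)) filled[[targets[[t]]]] <- as.vector(Ycur[[t]])
    out[[m]] <- filled
  }
  out
}

# one PMM update for one target; returns the refilled D x n matrix
fill_pmm <- function(X, y, ov, y_obs_orig, k, draw, n, D) {
  # guard against constant/collinear columns
  keep <- c(TRUE, apply(X[ov, -1, drop = FALSE], 2,
                        function(z) stats::sd(z) > 0))
  X <- X[, keep, drop = FALSE]
  Xo <- X[ov, , drop = FALSE]
  yo <- y_obs_orig[ov]
  qx <- qr(Xo)
  if (qx$rank < ncol(Xo)) {
    cols <- qx$pivot[seq_len(qx$rank)]
    X <- X[, cols, drop = FALSE]
    Xo <- Xo[, cols, drop = FALSE]
    qx <- qr(Xo)
  }
  beta <- qr.coef(qx, yo)
  yhat_obs <- drop(Xo %*% beta)
  beta_star <- beta
  if (draw == "bayes") {
    df <- max(length(yo) - ncol(Xo), 1)
    rss <- sum((yo - yhat_obs)^2)
    sigma2 <- rss / stats::rchisq(1, df)
    R <- qr.R(qx)
    beta_star <- beta + backsolve(R, stats::rnorm(ncol(Xo))) * sqrt(sigma2)
  } else if (draw == "boot") {
    idx <- sample.int(length(yo), replace = TRUE)
    beta_star <- qr.coef(qr(Xo[idx, , drop = FALSE]), yo[idx])
    beta_star[is.na(beta_star)] <- 0
  }
  yhat_mis <- drop(X[!ov, , drop = FALSE] %*% beta_star)

  o <- order(yhat_obs)
  so <- yhat_obs[o]
  vo <- yo[o]
  nobs <- length(so)
  kk <- min(k, nobs)
  nm <- length(yhat_mis)
  pos <- findInterval(yhat_mis, so)
  offs <- seq(-kk, kk - 1L)
  cand <- pmin(pmax(outer(pos, offs, `+`) + 1L, 1L), nobs)
  dmat <- abs(matrix(so[cand], nrow = nm) - yhat_mis)
  # rank the kk nearest candidates per row without a per-row sort
  usel <- sample.int(kk, nm, replace = TRUE)
  pick <- integer(nm)
  for (j in seq_len(kk)) {
    mj <- max.col(-dmat, ties.method = "first")
    hit <- usel == j
    pick[hit] <- cand[cbind(which(hit), mj[hit])]
    dmat[cbind(seq_len(nm), mj)] <- Inf
  }
  y[!ov] <- vo[pick]
  matrix(y, D, n)
}
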