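# Hansen-style panel threshold regression: fixed-effects within estimation,
# grid search for the threshold over observed values of the threshold
# variable, and bootstrap F-tests for the existence of one and two
# thresholds.

# assemble within-demeaned pieces for the threshold search; controls are
# demeaned and QR-factorized once so the grid search only touches the
# regime columns
threshold_stack <- function(y_panel, q_panel, controls = NULL,
                            yvar = if ("D" %in% names(y_panel)) "D" else "y") {
  key <- paste(y_panel$unit, y_panel$year)
  iq <- match(key, paste(q_panel$unit, q_panel$year))
  if (anyNA(iq)) stop_ccd("threshold variable does not cover all unit-years",
                          class = "invalid_config")
  q <- q_panel$q[iq]
  C <- NULL
  if (!is.null(controls)) {
    vars <- setdiff(names(controls), c("unit", "year"))
    ic <- match(key, paste(controls$unit, controls$year))
    if (anyNA(ic)) stop_ccd("controls do not cover all unit-years",
                            class = "invalid_config")
    C <- as.matrix(controls[ic, vars, drop = FALSE])
  }
  id <- as.integer(factor(y_panel$unit))
  if (min(table(id)) < 2L) stop_ccd("need at least two years per unit",
                                    class = "invalid_config")
  Cw <- if (!is.null(C)) apply(C, 2, demean_by, id = id)
  qrC <- if (!is.null(Cw)) qr(Cw)
  list(y = y_panel[[yvar]], q = q, C = C, Cw = Cw, qrC = qrC, id = id,
       n = length(unique(id)), N = length(id), kc = if (is.null(C)) 0L else ncol(C))
}

# project a matrix off the demeaned controls
proj_off_controls <- function(ts, M) {
  if (is.null(ts$qrC)) M else qr.resid(ts$qrC, M)
}

# regime-split columns q * 1(regime r) for thresholds gammas, within-demeaned
regime_columns <- function(ts, gammas) {
  gammas <- sort(gammas)
  reg <- findInterval(ts$q, gammas, left.open = TRUE) + 1L  # q <= g1 -> 1
  Xr <- vapply(seq_len(length(gammas) + 1L),
               function(r) ts$q * (reg == r), numeric(ts$N))
  apply(Xr, 2, demean_by, id = ts$id)
}

# RSS of the within regression [controls, regime columns] for outcome y,
# via Frisch-Waugh on the precomputed control projection
rss_at <- function(ts, y_perp, gammas) {
  Xp <- proj_off_controls(ts, regime_columns(ts, gammas))
  XtX <- crossprod(Xp)
  Xty <- crossprod(Xp, y_perp)
  b <- tryCatch(solve(XtX, Xty), error = function(e) NULL)
  if (is.null(b)) return(Inf)  # empty regime: candidate not admissible
  sum(y_perp^2) - drop(crossprod(b, Xty))
}

# full within regression at chosen thresholds, for reporting
regime_fit <- function(ts, gammas, y = ts$y) {
  Xw <- cbind(ts$Cw, regime_columns(ts, gammas))
  yw <- demean_by(y, ts$id)
  f <- stats::.lm.fit(Xw, yw)
  list(rss = sum(f$residuals^2), coef = f$coefficients, k = ncol(Xw),
       Xw = Xw, yw = yw, residuals = f$residuals)
}

# grid of RSS values over single-threshold candidates; `pre` optionally
# carries projected regime columns precomputed per candidate
grid_rss <- function(ts, y_perp, grid, pre = NULL) {
  if (is.null(pre)) {
    return(vapply(grid, function(g) rss_at(ts, y_perp, g), numeric(1)))
  }
  yy <- sum(y_perp^2)
  vapply(seq_along(grid), function(i) {
    Xty <- crossprod(pre$Xp[[i]], y_perp)
    yy - drop(crossprod(solve(pre$XtX[[i]], Xty), Xty))
  }, numeric(1))
}

precompute_grid <- function(ts, grid) {
  Xp <- lapply(grid, function(g) proj_off_controls(ts, regime_columns(ts, g)))
  XtX <- lapply(Xp, crossprod)
  list(Xp = Xp, XtX = XtX)
}

#' Fit a fixed-effects panel threshold regression (single threshold)
#'
#' The slope on the threshold variable q switches at an estimated location
#' gamma: y_it = mu_i + controls delta + beta_1 q 1(q <= gamma) +
#' beta_2 q 1(q > gamma) + e_it. After the within transformation, gamma is
#' chosen to minimize the residual sum of squares over the grid of observed
#' q values with a fraction trimmed from each tail.
#'
#' @param y_panel Data frame `unit`, `year` and the outcome column.
#' @param q_panel Data frame `unit`, `year`, `q` (threshold variable).
#' @param controls Optional data frame `unit`, `year` plus control columns.
#' @param trim Fraction of the support of q trimmed from each tail.
#' @param yvar Outcome column name.
#' @return An object of class `threshold_fit`: `gamma`, `rss`, `mse`,
#'   `rss_linear`, `coefficients` (regime slopes and controls with standard
#'   errors), `grid`, `rss_grid`, `df`, `n`, `N`.
#' @export
fit_threshold <- function(y_panel, q_panel, controls = NULL, trim = 0.05,
                          yvar = if ("D" %in% names(y_panel)) "D" else "y") {
  check_number(trim, "trim", lower = 0, upper = 0.45)
  ts <- threshold_stack(y_panel, q_panel, controls, yvar)
  lo <- stats::quantile(ts$q, trim, names = FALSE)
  hi <- stats::quantile(ts$q, 1 - trim, names = FALSE)
  grid <- sort(unique(ts$q[ts$q >= lo & ts$q < hi]))
  if (length(grid) == 0L) stop_ccd("no candidate thresholds after trimming",
                                   class = "trim_error")
  yw <- demean_by(ts$y, ts$id)
  y_perp <- proj_off_controls(ts, matrix(yw))
  rss_g <- grid_rss(ts, y_perp, grid)
  gamma <- grid[which.min(rss_g)]
  best <- regime_fit(ts, gamma)

  # linear (no-threshold) comparison fit on the identical data
  Xlw <- cbind(ts$Cw, demean_by(ts$q, ts$id))
  fl <- stats::.lm.fit(Xlw, yw)
  rss_lin <- sum(fl$residuals^2)

  df <- ts$N - ts$n - best$k
  mse <- best$rss / df
  XtX <- crossprod(best$Xw)
  Vc <- tryCatch(solve(XtX) * mse, error = function(e) pinv(XtX) * mse)
  se <- sqrt(pmax(diag(Vc), 0))
  nm <- c(if (ts$kc) colnames(ts$C), "q_low", "q_high")
  est <- best$coef
  tv <- est / se
  coefficients <- data.frame(term = nm, estimate = est, se = se, t = tv,
                             p = 2 * stats::pt(-abs(tv), df),
                             row.names = NULL, stringsAsFactors = FALSE)

  structure(list(gamma = gamma, rss = best$rss, mse = mse,
                 rss_linear = rss_lin, coefficients = coefficients,
                 grid = grid, rss_grid = rss_g, df = df,
                 n = ts$n, N = ts$N, trim = trim, stack = ts),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("threshold_fit: gamma = %.4g, RSS = %.4g (linear %.4g), MSE = %.4g\n",
              x$gamma, x$rss, x$rss_linear, x$mse))
  print(x$coefficients, digits = 4)
  invisible(x)
}

# resample whole unit residual blocks (panel residual bootstrap), keeping
# each replacement block aligned with the receiving unit's rows
resample_blocks <- function(resid_null, id, n, N) {
  pick <- sample.int(n, n, replace = TRUE)
  blocks <- split(resid_null, id)
  slots <- split(seq_len(N), id)
  e_star <- numeric(N)
  for (j in seq_len(n)) e_star[slots[[j]]] <- blocks[[pick[j]]]
  e_star
}

#' Bootstrap F-test for the existence of a threshold
#'
#' F = (RSS_linear - RSS_threshold) / MSE_threshold. Its null distribution
#' is approximated by a residual bootstrap under the no-threshold model:
#' residual blocks are resampled by unit, the outcome regenerated from the
#' linear fit, and the threshold re-estimated on each replicate. The
#' p-value is the fraction of bootstrap F values at or above the observed
#' one; the 90/95/99% bootstrap quantiles are the reported critical values.
#'
#' @param fit A `threshold_fit`.
#' @param n_bootstrap Number of bootstrap replicates (warns below 50).
#' @param seed Integer seed; the same seed reproduces the p-value exactly.
#' @return A list of class `threshold_test`: `F_stat`, `p`, `crit`,
#'   `n_bootstrap`.
#' @export
bootstrap_f_test <- function(fit, n_bootstrap = 300L, seed = 1L) {
  stopifnot(inherits(fit, "threshold_fit"))
  n_bootstrap <- check_count(n_bootstrap, "n_bootstrap")
  if (n_bootstrap < 50L) {
    warning("fewer than 50 bootstrap replicates; p-value is coarse",
            call. = FALSE)
  }
  ts <- fit$stack
  F_obs <- (fit$rss_linear - fit$rss) / fit$mse

  # null model: linear within fit
  qw <- demean_by(ts$q, ts$id)
  Xlw <- cbind(ts$Cw, qw)
  yw <- demean_by(ts$y, ts$id)
  fl <- stats::.lm.fit(Xlw, yw)
  resid_null <- fl$residuals
  fitted_null <- ts$y - resid_null   # keeps unit means in the regenerated y
  dfb <- ts$N - ts$n - (ts$kc + 2L)

  pre <- precompute_grid(ts, fit$grid)
  set.seed(stage_seed(seed, "threshold_bootstrap"))
  sims <- vapply(seq_len(n_bootstrap), function(b) {
    ystar <- fitted_null + resample_blocks(resid_null, ts$id, ts$n, ts$N)
    ysw <- demean_by(ystar, ts$id)
    y_perp <- proj_off_controls(ts, matrix(ysw))
    rss1 <- min(grid_rss(ts, y_perp, fit$grid, pre))
    rss0 <- sum(stats::.lm.fit(Xlw, ysw)$residuals^2)
    (rss0 - rss1) / (rss1 / dfb)
  }, numeric(1))
  structure(list(F_stat = F_obs,
                 p = mean(sims >= F_obs),
                 crit = stats::quantile(sims, c(0.90, 0.95, 0.99),
                                        names = FALSE),
                 n_bootstrap = n_bootstrap),
            class = "threshold_test")
}

#' @export
print.threshold_test <- function(x, ...) {
  cat(sprintf("F = %.3f, bootstrap p = %.4f (crit 10/5/1%%: %.2f / %.2f / %.2f, B = %d)\n",
              x$F_stat, x$p, x$crit[1], x$crit[2], x$crit[3], x$n_bootstrap))
  invisible(x)
}

#' Sequential estimation and test of a second threshold
#'
#' Given the single-threshold estimate, the second threshold is searched
#' conditional on the first, the first is then refined conditional on the
#' second, and the 2-vs-1 F statistic is assessed by the same unit-block
#' residual bootstrap, regenerating the outcome under the single-threshold
#' model.
#'
#' @param fit A single-threshold `threshold_fit`.
#' @param n_bootstrap Bootstrap replicates for the 2-vs-1 test.
#' @param seed Integer seed.
#' @return A list of class `threshold_fit2`: `gammas` (both thresholds),
#'   `rss`, `mse`, `F_stat`, `p`, `crit`, `n_bootstrap`.
#' @export
sequential_thresholds <- function(fit, n_bootstrap = 300L, seed = 1L) {
  stopifnot(inherits(fit, "threshold_fit"))
  ts <- fit$stack
  grid <- fit$grid
  yw <- demean_by(ts$y, ts$id)
  y_perp <- proj_off_controls(ts, matrix(yw))

  search_second <- function(yp, g1) {
    cand <- setdiff(grid, g1)
    rss <- vapply(cand, function(g) rss_at(ts, yp, c(g1, g)), numeric(1))
    list(g = cand[which.min(rss)], rss = min(rss))
  }
  g1 <- fit$gamma
  s2 <- search_second(y_perp, g1)
  g2 <- s2$g
  # refinement of the first threshold conditional on the second
  cand1 <- setdiff(grid, g2)
  rss1r <- vapply(cand1, function(g) rss_at(ts, y_perp, sort(c(g, g2))),
                  numeric(1))
  g1 <- cand1[which.min(rss1r)]
  best <- regime_fit(ts, c(g1, g2))
  df <- ts$N - ts$n - best$k
  mse <- best$rss / df
  F_obs <- (fit$rss - best$rss) / mse

  # bootstrap under the single-threshold null
  single <- regime_fit(ts, fit$gamma)
  resid_null <- single$residuals
  fitted_null <- ts$y - resid_null
  pre <- precompute_grid(ts, grid)
  set.seed(stage_seed(seed, "double_threshold_bootstrap"))
  sims <- vapply(seq_len(n_bootstrap), function(b) {
    ystar <- fitted_null + resample_blocks(resid_null, ts$id, ts$n, ts$N)
    ysw <- demean_by(ystar, ts$id)
    yp <- proj_off_controls(ts, matrix(ysw))
    rg1 <- grid_rss(ts, yp, grid, pre)
    b_g1 <- grid[which.min(rg1)]
    s1 <- min(rg1)
    sec <- search_second(yp, b_g1)
    (s1 - sec$rss) / (sec$rss / df)
  }, numeric(1))

  structure(list(gammas = sort(c(g1, g2)), rss = best$rss, mse = mse,
                 F_stat = F_obs, p = mean(sims >= F_obs),
                 crit = stats::quantile(sims, c(0.90, 0.95, 0.99),
                                        names = FALSE),
                 n_bootstrap = n_bootstrap),
            class = "threshold_fit2")
}
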