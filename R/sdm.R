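# Panel spatial econometrics: SDM/SAR/SEM by concentrated maximum likelihood
# with eigenvalue log-determinants, pooled / fixed (within) / random
# (error-component) effects, plus the specification battery (VIF, LM and
# robust LM, LR, Wald, Hausman).

# assemble a balanced year-major stacked panel aligned with the weight matrix
panel_stack <- function(y_panel, X_panel, w, yvar = "D") {
  stopifnot(inherits(w, "spatial_weights"))
  units <- w$units
  years <- sort(unique(y_panel$year))
  n <- length(units); T <- length(years)
  key_y <- paste(y_panel$unit, y_panel$year)
  key_x <- paste(X_panel$unit, X_panel$year)
  vars <- setdiff(names(X_panel), c("unit", "year"))
  want <- paste(rep(units, T), rep(years, each = n))
  iy <- match(want, key_y); ix <- match(want, key_x)
  if (anyNA(iy) || anyNA(ix)) {
    stop_ccd("panel is not balanced over the weight matrix units",
             class = "invalid_config")
  }
  y <- y_panel[[yvar]][iy]
  X <- as.matrix(X_panel[ix, vars, drop = FALSE])
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    stop_ccd("regressors are not full rank", class = "invalid_config")
  }
  # per-year application of W to a stacked vector/matrix
  apply_W <- function(M) {
    M <- as.matrix(M)
    out <- M
    for (t in seq_len(T)) {
      idx <- ((t - 1) * n + 1):(t * n)
      out[idx, ] <- w$W %*% M[idx, , drop = FALSE]
    }
    out
  }
  ev <- eigen(w$W, only.values = TRUE)$values
  list(y = y, X = X, vars = vars, n = n, T = T, units = units, years = years,
       apply_W = apply_W, ev = ev, W = w$W,
       unit_id = rep(seq_len(n), T))
}

# log|I - theta*W| per period times T, from precomputed eigenvalues
logdet_term <- function(theta, ev, T) {
  T * sum(log(Mod(1 - theta * ev)))
}

# admissible interval for the spatial parameter
spat_interval <- function(ev) {
  re <- Re(ev[abs(Im(ev)) < 1e-8])
  lo <- if (any(re < 0)) 1 / min(re) else -0.999
  hi <- if (any(re > 0)) 1 / max(re) else 0.999
  c(lo + 1e-6, hi - 1e-6)
}

# pseudo-inverse via SVD (for Hausman contrasts that are not quite PD)
pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Fit a panel spatial model (SDM, SAR, SEM or OLS) by maximum likelihood
#'
#' The spatial Durbin model y = rho W y + X beta + W X theta + u is
#' estimated by concentrating the likelihood over the spatial parameter,
#' with the log-determinant of (I - rho W) evaluated from the precomputed
#' eigenvalues of W (exact at regional panel sizes). Fixed effects use the
#' within transformation before the spatial step; random effects use the
#' error-component quasi-demeaning y* = y - psi * ybar_i with
#' psi = 1 - 1/sqrt(1 + T phi), phi = sigma_mu^2 / sigma_e^2, jointly
#' maximized over (rho, phi). The spatial-error model applies (I - lambda W)
#' to y and X first (for random effects this is the error-component spatial
#' SEM in which the unit effects share the spatial process, so the same
#' quasi-demeaning applies after the spatial transform).
#'
#' @param y_panel Data frame with `unit`, `year` and the outcome column.
#' @param X_panel Data frame with `unit`, `year` and regressor columns.
#' @param w A `spatial_weights` object (row-standardized recommended).
#' @param effects `"random"`, `"fixed"` or `"pooled"`.
#' @param model `"sdm"`, `"sar"`, `"sem"` or `"ols"`.
#' @param yvar Name of the outcome column in `y_panel`.
#' @param fixed_rho Hold the spatial parameter at this value instead of
#'   maximizing over it (profile evaluation; slopes and variance are still
#'   concentrated out).
#' @param se Compute standard errors from the numerical observed
#'   information; disable for fast profile evaluations.
#' @return An object of class `sdm_fit`: coefficient table `coefficients`
#'   (estimate, se, z, p), `rho` (or `lambda`), `sigma2`, `phi` (random
#'   effects), `logLik`, `R2`, `model`, `effects`, `n`, `T`.
#' @export
fit_sdm <- function(y_panel, X_panel, w,
                    effects = c("random", "fixed", "pooled"),
                    model = c("sdm", "sar", "sem", "ols"),
                    yvar = if ("D" %in% names(y_panel)) "D" else "y",
                    fixed_rho = NULL, se = TRUE) {
  effects <- match.arg(effects)
  model <- match.arg(model)
  ps <- panel_stack(y_panel, X_panel, w, yvar = yvar)
  n <- ps$n; T <- ps$T; N <- n * T
  has_lag <- model %in% c("sdm", "sar")
  has_err <- model == "sem"
  has_wx <- model == "sdm"

  Z0 <- ps$X
  znames <- ps$vars
  if (has_wx) {
    Z0 <- cbind(Z0, ps$apply_W(ps$X))
    znames <- c(znames, paste0("Wx_", ps$vars))
  }
  if (effects != "fixed") {
    Z0 <- cbind(Z0, 1)
    znames <- c(znames, "(Intercept)")
  }
  colnames(Z0) <- znames
  y0 <- ps$y
  Wy0 <- if (has_lag) drop(ps$apply_W(ps$y)) else NULL

  within <- function(M) apply(as.matrix(M), 2, demean_by, id = ps$unit_id)
  quasi <- function(M, psi) {
    M <- as.matrix(M)
    M - psi * apply(M, 2, function(col) ave(col, ps$unit_id, FUN = mean))
  }

  # residual sum of squares and delta-hat for given transform + spatial par
  fit_inner <- function(theta, psi) {
    if (has_err && theta != 0) {
      B <- function(M) as.matrix(M) - theta * ps$apply_W(M)
      yt <- B(y0); Zt <- B(Z0)
    } else {
      yt <- y0; Zt <- Z0
    }
    resp <- drop(yt) - if (has_lag) theta * Wy0 else 0
    if (effects == "fixed") {
      resp <- drop(within(resp)); Zt <- within(Zt)
      if (has_lag) resp <- drop(within(drop(yt))) - theta * drop(within(Wy0))
    } else if (psi > 0) {
      resp <- drop(quasi(resp, psi)); Zt <- quasi(Zt, psi)
    }
    f <- stats::lm.fit(Zt, resp)
    list(delta = f$coefficients, rss = sum(f$residuals^2),
         resp = resp, Z = Zt, fitted = f$fitted.values)
  }

  loglik <- function(theta, phi) {
    psi <- if (effects == "random") 1 - 1 / sqrt(1 + T * phi) else 0
    fi <- fit_inner(theta, psi)
    s2 <- fi$rss / N
    ll <- -N / 2 * (log(2 * pi * s2) + 1)
    if (has_lag || has_err) ll <- ll + logdet_term(theta, ps$ev, T)
    if (effects == "random") ll <- ll - n / 2 * log(1 + T * phi)
    ll
  }

  iv <- spat_interval(ps$ev)
  if (!is.null(fixed_rho)) {
    theta <- check_number(fixed_rho, "fixed_rho", lower = iv[1], upper = iv[2])
    if (model == "ols") theta <- 0
    phi <- if (effects == "random") {
      op <- stats::optimize(function(lphi) -loglik(theta, exp(lphi)),
                            interval = c(-12, 6))
      exp(op$minimum)
    } else 0
  } else if (model == "ols") {
    if (effects == "random") {
      op <- stats::optimize(function(lphi) -loglik(0, exp(lphi)),
                            interval = c(-12, 6))
      phi <- exp(op$minimum); theta <- 0
    } else {
      phi <- 0; theta <- 0
    }
  } else if (effects == "random") {
    op <- stats::optim(c(0.1, 0), function(p) {
      if (p[1] <= iv[1] || p[1] >= iv[2]) return(1e10)
      -loglik(p[1], exp(p[2]))
    }, method = "Nelder-Mead",
    control = list(maxit = 2000, reltol = 1e-12))
    if (op$convergence != 0) {
      stop_ccd("spatial ML did not converge (code ", op$convergence, ")",
               class = "estimation_error")
    }
    theta <- op$par[1]; phi <- exp(op$par[2])
  } else if (has_lag) {
    # concentrated RSS is exactly quadratic in rho: locate the maximizer by
    # a bracketing search, then polish with the analytic score equation
    yt <- if (effects == "fixed") drop(within(y0)) else y0
    Wyt <- if (effects == "fixed") drop(within(Wy0)) else Wy0
    Zt <- if (effects == "fixed") within(Z0) else Z0
    qz <- qr(Zt)
    e0 <- qr.resid(qz, yt); edv <- qr.resid(qz, Wyt)
    aa <- sum(e0^2); bb <- sum(e0 * edv); cc <- sum(edv^2)
    ll_rho <- function(r) {
      -N / 2 * (log(2 * pi * (aa - 2 * bb * r + cc * r^2) / N) + 1) +
        logdet_term(r, ps$ev, T)
    }
    score <- function(r) {
      N * (bb - cc * r) / (aa - 2 * bb * r + cc * r^2) -
        T * sum(Re(ps$ev / (1 - r * ps$ev)))
    }
    op <- stats::optimize(function(r) -ll_rho(r), interval = iv, tol = 1e-8)
    theta <- op$minimum
    h <- 1e-3
    lo <- max(iv[1], theta - h); hi <- min(iv[2], theta + h)
    while (score(lo) * score(hi) > 0 && (hi - lo) < (iv[2] - iv[1])) {
      lo <- max(iv[1], lo - 10 * h); hi <- min(iv[2], hi + 10 * h)
    }
    if (score(lo) * score(hi) <= 0) {
      theta <- stats::uniroot(score, c(lo, hi), tol = 1e-14)$root
    }
    phi <- 0
  } else {
    op <- stats::optimize(function(th) -loglik(th, 0), interval = iv,
                          tol = 1e-10)
    theta <- op$minimum; phi <- 0
  }
  if ((has_lag || has_err) && is.null(fixed_rho) &&
      (theta < iv[1] + 1e-4 || theta > iv[2] - 1e-4)) {
    warning("spatial parameter at the boundary of its interval", call. = FALSE)
  }

  psi <- if (effects == "random") 1 - 1 / sqrt(1 + T * phi) else 0
  fi <- fit_inner(theta, psi)
  delta <- fi$delta
  sigma2 <- fi$rss / N
  ll <- loglik(theta, phi)

  # observed information from the numerical Hessian of the full negative LL
  full_nll <- function(par) {
    d <- par[seq_along(delta)]
    th <- if (has_lag || has_err) par[length(delta) + 1L] else 0
    s2 <- exp(par[length(par) - (effects == "random")])
    ph <- if (effects == "random") exp(par[length(par)]) else 0
    ps_i <- if (effects == "random") 1 - 1 / sqrt(1 + T * ph) else 0
    if (has_err && th != 0) {
      B <- function(M) as.matrix(M) - th * ps$apply_W(M)
      yt <- drop(B(y0)); Zt <- B(Z0)
    } else { yt <- y0; Zt <- Z0 }
    resp <- yt - if (has_lag) th * Wy0 else 0
    if (effects == "fixed") { resp <- drop(within(resp)); Zt <- within(Zt) }
    else if (ps_i > 0) { resp <- drop(quasi(resp, ps_i)); Zt <- quasi(Zt, ps_i) }
    e <- resp - drop(Zt %*% d)
    nll <- N / 2 * log(2 * pi * s2) + sum(e^2) / (2 * s2)
    if (has_lag || has_err) nll <- nll - logdet_term(th, ps$ev, T)
    if (effects == "random") nll <- nll + n / 2 * log(1 + T * ph)
    nll
  }
  par <- c(delta,
           if (has_lag || has_err) theta,
           log(sigma2),
           if (effects == "random") log(max(phi, 1e-12)))
  V <- matrix(NA_real_, length(par), length(par))
  if (se) {
    H <- tryCatch(stats::optimHess(par, full_nll), error = function(e) NULL)
    if (!is.null(H)) V <- tryCatch(solve(H), error = function(e) pinv(H))
  }
  se <- sqrt(pmax(diag(V), 0))[seq_along(delta)]
  se_theta <- if (has_lag || has_err) sqrt(max(V[length(delta) + 1L,
                                                length(delta) + 1L], 0)) else NA_real_

  est <- delta
  zv <- est / se
  coef_tab <- data.frame(term = znames, estimate = est, se = se, z = zv,
                         p = 2 * stats::pnorm(-abs(zv)),
                         row.names = NULL, stringsAsFactors = FALSE)
  if (has_lag || has_err) {
    zt <- theta / se_theta
    coef_tab <- rbind(coef_tab,
                      data.frame(term = if (has_lag) "rho" else "lambda",
                                 estimate = theta, se = se_theta, z = zt,
                                 p = 2 * stats::pnorm(-abs(zt))))
  }
  R2 <- stats::cor(fi$resp, fi$fitted)^2

  structure(list(coefficients = coef_tab,
                 rho = if (has_lag) theta else NA_real_,
                 lambda = if (has_err) theta else NA_real_,
                 beta = delta[ps$vars],
                 theta = if (has_wx) delta[paste0("Wx_", ps$vars)] else NULL,
                 sigma2 = sigma2, phi = phi, logLik = ll, R2 = R2,
                 vcov = V, par_names = c(znames,
                                         if (has_lag) "rho" else if (has_err) "lambda",
                                         "log_sigma2",
                                         if (effects == "random") "log_phi"),
                 model = model, effects = effects, n = n, T = T,
                 vars = ps$vars),
            class = "sdm_fit")
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("%s (%s effects): n = %d, T = %d, logLik = %.3f, R2 = %.4f\n",
              toupper(x$model), x$effects, x$n, x$T, x$logLik, x$R2))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from the auxiliary regression of regressor j on
#' the remaining regressors (with intercept).
#'
#' @param X Data frame or matrix of regressors (numeric columns).
#' @return A list with `vif` (named vector) and `mean`.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  k <- ncol(X)
  if (k < 2L) stop_ccd("need at least 2 regressors", class = "invalid_config")
  out <- numeric(k)
  for (j in seq_len(k)) {
    f <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(f$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 > 1 - 1e-12) {
      stop_ccd("perfect collinearity involving column ",
               colnames(X)[j] %||% j, class = "infinite_vif")
    }
    out[j] <- 1 / (1 - r2)
  }
  names(out) <- colnames(X)
  list(vif = out, mean = mean(out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Lagrange-multiplier tests for spatial lag and spatial error dependence
#'
#' The standard LM-lag / LM-error statistics and their robust counterparts,
#' computed from pooled OLS residuals with the block-diagonal panel weight
#' matrix I_T (x) W; all four are chi-square(1) under their nulls.
#'
#' @inheritParams fit_sdm
#' @return A data frame with `test`, `statistic`, `p`.
#' @export
lm_tests <- function(y_panel, X_panel, w,
                     yvar = if ("D" %in% names(y_panel)) "D" else "y") {
  ps <- panel_stack(y_panel, X_panel, w, yvar = yvar)
  N <- ps$n * ps$T
  Z <- cbind(1, ps$X)
  f <- stats::lm.fit(Z, ps$y)
  e <- f$residuals
  s2 <- sum(e^2) / N
  We <- drop(ps$apply_W(e))
  Wy <- drop(ps$apply_W(ps$y))
  # trace term tr(W'W + W^2), scaled by T for the block-diagonal panel W
  trW <- ps$T * (sum(ps$W * ps$W) + sum(ps$W * t(ps$W)))
  d_err <- sum(e * We) / s2
  d_lag <- sum(e * Wy) / s2
  Wxb <- drop(ps$apply_W(f$fitted.values))
  MWxb <- Wxb - drop(Z %*% stats::lm.fit(Z, Wxb)$coefficients)
  J <- sum(Wxb * MWxb) / s2 + trW

  lm_err <- d_err^2 / trW
  lm_lag <- d_lag^2 / J
  rob_lag <- (d_lag - d_err)^2 / (J - trW)
  rob_err <- (d_err - (trW / J) * d_lag)^2 / (trW - trW^2 / J)
  stat <- c(`LM-lag` = lm_lag, `Robust LM-lag` = rob_lag,
            `LM-error` = lm_err, `Robust LM-error` = rob_err)
  data.frame(test = names(stat), statistic = unname(stat),
             p = stats::pchisq(unname(stat), df = 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Likelihood-ratio, Wald and Hausman tests for the SDM specification
#'
#' LR tests compare the SDM against its SAR (theta = 0) and SEM
#' (common-factor) simplifications under the same effects; Wald-lag tests
#' theta = 0 jointly and Wald-error tests the common-factor restriction
#' theta + rho beta = 0 by the delta method; the Hausman statistic
#' contrasts the fixed- and random-effects SDM slope vectors with the
#' standard quadratic form.
#'
#' @inheritParams fit_sdm
#' @param effects Effects used for the SDM/SAR/SEM fits (the Hausman test
#'   always contrasts fixed vs random).
#' @return A data frame with `test`, `statistic`, `df`, `p`.
#' @export
lr_wald_hausman <- function(y_panel, X_panel, w, effects = "random",
                            yvar = if ("D" %in% names(y_panel)) "D" else "y") {
  sdm <- fit_sdm(y_panel, X_panel, w, effects = effects, model = "sdm", yvar = yvar)
  sar <- fit_sdm(y_panel, X_panel, w, effects = effects, model = "sar", yvar = yvar)
  sem <- fit_sdm(y_panel, X_panel, w, effects = effects, model = "sem", yvar = yvar)
  k <- length(sdm$vars)

  lr_lag <- max(0, 2 * (sdm$logLik - sar$logLik))
  lr_err <- max(0, 2 * (sdm$logLik - sem$logLik))

  # Wald-lag: joint significance of the Wx coefficients
  tn <- paste0("Wx_", sdm$vars)
  ix_t <- match(tn, sdm$par_names)
  Vt <- sdm$vcov[ix_t, ix_t, drop = FALSE]
  th <- sdm$theta
  wald_lag <- drop(t(th) %*% pinv(Vt) %*% th)

  # Wald-error: common factor theta + rho * beta = 0 via the delta method
  ix_b <- match(sdm$vars, sdm$par_names)
  ix_r <- match("rho", sdm$par_names)
  idx <- c(ix_b, ix_t, ix_r)
  Vfull <- sdm$vcov[idx, idx, drop = FALSE]
  g <- sdm$theta + sdm$rho * sdm$beta
  G <- cbind(diag(sdm$rho, k), diag(1, k), matrix(sdm$beta, k, 1))
  wald_err <- drop(t(g) %*% pinv(G %*% Vfull %*% t(G)) %*% g)

  fe <- if (effects == "fixed") sdm else
    fit_sdm(y_panel, X_panel, w, effects = "fixed", model = "sdm", yvar = yvar)
  re <- if (effects == "random") sdm else
    fit_sdm(y_panel, X_panel, w, effects = "random", model = "sdm", yvar = yvar)
  common <- c(sdm$vars, tn)
  d <- fe$coefficients$estimate[match(common, fe$coefficients$term)] -
       re$coefficients$estimate[match(common, re$coefficients$term)]
  Vd <- fe$vcov[match(common, fe$par_names), match(common, fe$par_names)] -
        re$vcov[match(common, re$par_names), match(common, re$par_names)]
  hausman <- abs(drop(t(d) %*% pinv(Vd) %*% d))

  data.frame(
    test = c("LR-lag", "LR-error", "Wald-lag", "Wald-error", "Hausman"),
    statistic = c(lr_lag, lr_err, wald_lag, wald_err, hausman),
    df = c(k, k, k, k, 2 * k),
    p = stats::pchisq(c(lr_lag, lr_err, wald_lag, wald_err, hausman),
                      df = c(k, k, k, k, 2 * k), lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Robustness variants of a baseline SDM fit
#'
#' Re-fits the model with (a) an alternative outcome (e.g. the
#' entropy-weighted CCD) and (b) a subset excluding flagged units, with the
#' weight matrix rebuilt on the subset, and reports coefficient-sign
#' agreement with the baseline.
#'
#' @inheritParams fit_sdm
#' @param alt_y Optional alternative outcome panel (same shape as
#'   `y_panel`).
#' @param exclude Character vector of unit ids to drop for the subsample
#'   variant.
#' @return A list of class `sdm_robustness`: `baseline`, `alt_outcome`,
#'   `subsample` (each an `sdm_fit` or `NULL`), `sign_agreement`.
#' @export
robustness_suite <- function(y_panel, X_panel, w, alt_y = NULL,
                             exclude = character(), effects = "random",
                             yvar = if ("D" %in% names(y_panel)) "D" else "y") {
  base <- fit_sdm(y_panel, X_panel, w, effects = effects, yvar = yvar)
  alt <- if (!is.null(alt_y)) {
    fit_sdm(alt_y, X_panel, w, effects = effects, yvar = yvar)
  }
  subf <- NULL
  if (length(exclude)) {
    keep <- setdiff(w$units, exclude)
    if (length(keep) <= length(base$vars) + 2L) {
      stop_ccd("subset leaves too few units for the regressor count",
               class = "degrees_of_freedom_error")
    }
    ws <- subset_weights(w, keep)
    subf <- fit_sdm(y_panel[y_panel$unit %in% keep, ],
                    X_panel[X_panel$unit %in% keep, ],
                    ws, effects = effects, yvar = yvar)
  }
  agree <- function(f) {
    if (is.null(f)) return(NA_real_)
    b0 <- c(base$beta, base$theta, rho = base$rho)
    b1 <- c(f$beta, f$theta, rho = f$rho)
    mean(sign(b0) == sign(b1))
  }
  structure(list(baseline = base, alt_outcome = alt, subsample = subf,
                 sign_agreement = c(alt_outcome = agree(alt),
                                    subsample = agree(subf))),
            class = "sdm_robustness")
}
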