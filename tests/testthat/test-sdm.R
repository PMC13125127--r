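# shared small geography for the spatial regression tests
sdm_setup <- function(n = 31, seed = 3, vars = c("GDP", "GHI")) {
  geo <- synthetic_geography(n)
  w <- build_weights(adjacency = geo$adjacency, centroids = geo$centroids,
                     units = geo$centroids$unit)
  cfg <- sim_config(n_units = n, seed = seed)
  X <- generate_covariate_panel(cfg, geo$centroids$unit)
  for (v in c("GDP", "GHI", "Urb", "Edu", "Old")) X[[v]] <- scale(X[[v]])[, 1]
  list(w = w, X = X[, c("unit", "year", vars)], geo = geo)
}

test_that("with rho = 0, theta = 0 and vanishing noise the SDM reduces to OLS", {
  s <- sdm_setup()
  dgp <- generate_sdm_outcome(s$w, s$X, rho = 0, betas = c(1, -0.5),
                              theta = c(0, 0), sigma = 1e-9, seed = 2)
  fit <- fit_sdm(dgp$outcome, s$X, s$w, effects = "pooled", yvar = "y")
  df <- merge(dgp$outcome, s$X, by = c("unit", "year"))
  ols <- stats::lm(y ~ GDP + GHI, data = df)
  # with y = X beta exactly, Wy = WX beta is collinear with the Wx block, so
  # rho is not identified -- but the X slopes are pinned regardless
  expect_equal(unname(fit$beta), unname(coef(ols)[c("GDP", "GHI")]),
               tolerance = 1e-6)
})

test_that("degenerate generating processes behave as forced", {
  s <- sdm_setup(n = 16)
  # rho = 0, theta = 0, sigma = 0: y equals X beta exactly
  dgp <- generate_sdm_outcome(s$w, s$X, rho = 0, betas = c(2, 1),
                              theta = c(0, 0), sigma = 0, seed = 5)
  df <- merge(dgp$outcome, s$X, by = c("unit", "year"))
  expect_equal(df$y, 2 * df$GDP + 1 * df$GHI, tolerance = 1e-12)

  # zero weight matrix: outcome independent of rho
  w0 <- structure(list(W = matrix(0, 16, 16, dimnames = list(s$w$units, s$w$units)),
                       kind = "contiguity", row_standardized = FALSE,
                       S0 = 0, units = s$w$units, repaired = character()),
                  class = "spatial_weights")
  d1 <- generate_sdm_outcome(w0, s$X, rho = 0.7, betas = c(2, 1),
                             theta = c(1, 1), sigma = 0, seed = 5)
  d2 <- generate_sdm_outcome(w0, s$X, rho = 0, betas = c(2, 1),
                             theta = c(1, 1), sigma = 0, seed = 5)
  expect_equal(d1$outcome$y, d2$outcome$y, tolerance = 1e-12)

  # singular (I - rho W) is refused with the offending rho named
  expect_error(generate_sdm_outcome(s$w, s$X, rho = 1, betas = c(1, 1),
                                    theta = c(0, 0), sigma = 0),
               "rho = 1", class = "generation_error")
})

test_that("concentrated likelihood optimum matches a dense rho grid search", {
  s <- sdm_setup(n = 8)
  X <- s$X[s$X$year <= 3, ]
  dgp <- generate_sdm_outcome(s$w, X, rho = 0.3, betas = c(1, -1),
                              theta = c(0.5, 0), sigma = 0.3, seed = 7)
  fit <- fit_sdm(dgp$outcome, X, s$w, effects = "pooled", yvar = "y")

  # dense grid over rho: concentrated LL by brute force
  grid <- seq(-0.9, 0.99, by = 1e-3)
  ll <- vapply(grid, function(r) {
    fit_sdm(dgp$outcome, X, s$w, effects = "pooled", yvar = "y",
            fixed_rho = r, se = FALSE)$logLik
  }, numeric(1))
  expect_lt(abs(fit$rho - grid[which.max(ll)]), 1.5e-3)
})

test_that("unit relabelling with a consistently permuted W leaves estimates unchanged", {
  s <- sdm_setup(n = 12)
  dgp <- generate_sdm_outcome(s$w, s$X, rho = 0.4, betas = c(1, -0.5),
                              theta = c(0.2, 0.1), sigma = 0.4, seed = 9)
  f1 <- fit_sdm(dgp$outcome, s$X, s$w, effects = "pooled", yvar = "y")
  # permute unit order in the weights object; panels are matched by unit id
  perm <- sample(seq_along(s$w$units))
  wp <- s$w
  wp$units <- s$w$units[perm]
  wp$W <- s$w$W[perm, perm]
  f2 <- fit_sdm(dgp$outcome, s$X, wp, effects = "pooled", yvar = "y")
  expect_equal(f1$rho, f2$rho, tolerance = 1e-10)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-8)
})

test_that("fixed and random effects variants recover a moderate spatial signal", {
  s <- sdm_setup()
  dgp <- generate_sdm_outcome(s$w, s$X, rho = 0.4, betas = c(1, -0.5),
                              theta = c(0.2, 0.1), sigma = 0.5, seed = 13)
  fe <- fit_sdm(dgp$outcome, s$X, s$w, effects = "fixed", yvar = "y")
  re <- fit_sdm(dgp$outcome, s$X, s$w, effects = "random", yvar = "y")
  for (f in list(fe, re)) {
    expect_gt(f$rho, 0.1)
    expect_lt(f$rho, 0.7)
    expect_equal(unname(f$beta), c(1, -0.5), tolerance = 0.2)
  }
  # likelihood at the optimum dominates the rho = 0 profile of the same spec
  ll0 <- fit_sdm(dgp$outcome, s$X, s$w, effects = "fixed", yvar = "y",
                 fixed_rho = 0, se = FALSE)$logLik
  expect_gte(fe$logLik, ll0 - 1e-8)
})

test_that("VIF matches the auxiliary-regression oracle and flags collinearity", {
  set.seed(30)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("v", 1:4)))
  v <- vif(X)
  for (j in 1:4) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(unname(v$vif[j]), 1 / (1 - r2), tolerance = 1e-10)
  }
  # centered orthogonal columns: VIF exactly 1
  Q <- stats::poly(1:20, 3)
  colnames(Q) <- paste0("q", 1:3)
  expect_equal(unname(vif(Q)$vif), rep(1, 3), tolerance = 1e-8)
  # near-duplicated column: VIF explodes
  Xc <- cbind(X, v5 = X[, 1] + rnorm(50, 0, 1e-4))
  expect_gt(max(vif(Xc)$vif), 10)
  Xp <- cbind(X, v5 = X[, 1])
  expect_error(vif(Xp), class = "infinite_vif")
})

test_that("LM statistics are nonnegative and detect a strong spatial lag", {
  s <- sdm_setup()
  dgp <- generate_sdm_outcome(s$w, s$X, rho = 0.7, betas = c(1, -0.5),
                              theta = c(0, 0), sigma = 0.3, seed = 17)
  lt <- lm_tests(dgp$outcome, s$X, s$w, yvar = "y")
  expect_true(all(lt$statistic >= 0))
  expect_lt(lt$p[lt$test == "LM-lag"], 1e-4)

  null <- generate_sdm_outcome(s$w, s$X, rho = 0, betas = c(1, -0.5),
                               theta = c(0, 0), sigma = 0.3, seed = 18)
  ltn <- lm_tests(null$outcome, s$X, s$w, yvar = "y")
  expect_true(all(ltn$statistic >= 0))
})

test_that("LR, Wald and Hausman battery behaves on an SDM generating process", {
  s <- sdm_setup()
  dgp <- generate_sdm_outcome(s$w, s$X, rho = 0.4, betas = c(1, -0.5),
                              theta = c(0.8, -0.6), sigma = 0.3, seed = 21)
  bat <- lr_wald_hausman(dgp$outcome, s$X, s$w, effects = "pooled", yvar = "y")
  expect_true(all(bat$statistic >= 0))
  # strong Wx signal: SDM rejects the SAR simplification
  expect_lt(bat$p[bat$test == "LR-lag"], 0.01)
  expect_lt(bat$p[bat$test == "Wald-lag"], 0.01)
  expect_true(is.finite(bat$statistic[bat$test == "Hausman"]))
})

test_that("robustness variants track the baseline", {
  s <- sdm_setup(n = 16)
  dgp <- generate_sdm_outcome(s$w, s$X, rho = 0.5, betas = c(1, -0.5),
                              theta = c(0.2, 0.1), sigma = 0.3, seed = 23)
  # alternative outcome: mild perturbation of the baseline outcome
  alt <- dgp$outcome
  set.seed(24)
  alt$y <- alt$y + rnorm(nrow(alt), 0, 0.02)
  rs <- robustness_suite(dgp$outcome, s$X, s$w, alt_y = alt,
                         exclude = s$w$units[1:2], effects = "pooled",
                         yvar = "y")
  expect_equal(sign(rs$alt_outcome$rho), sign(rs$baseline$rho))
  expect_gte(rs$sign_agreement["alt_outcome"], 0.8)
  # rebuilt subset W keeps unit row sums at 1
  ws <- subset_weights(s$w, setdiff(s$w$units, s$w$units[1:2]))
  expect_equal(unname(rowSums(ws$W)), rep(1, 14), tolerance = 1e-12)
  # empty exclusion and no alternative outcome: fit equals baseline
  rs0 <- robustness_suite(dgp$outcome, s$X, s$w, effects = "pooled", yvar = "y")
  expect_equal(rs0$baseline$coefficients, rs$baseline$coefficients)
  expect_null(rs0$subsample)
})
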