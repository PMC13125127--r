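test_that("Gaussian KDE matches the kernel at a single point and integrates to 1", {
  k1 <- gaussian_kde(0, h = 1, allow_single = TRUE, grid_size = 101L)
  at0 <- k1$density[which.min(abs(k1$grid))]
  expect_equal(at0, 1 / sqrt(2 * pi), tolerance = 1e-10)

  set.seed(14)
  x <- c(rnorm(40, 0, 0.5), rnorm(40, 4, 0.3))
  kd <- gaussian_kde(x)
  expect_true(all(kd$density >= 0))
  integral <- sum(diff(kd$grid) * (head(kd$density, -1) + tail(kd$density, -1)) / 2)
  expect_gte(integral, 0.99)
  expect_lte(integral, 1.01)
})

test_that("well-separated clusters produce two local maxima", {
  set.seed(9)
  x <- c(rnorm(30, 0, 0.2), rnorm(30, 5, 0.2))
  kd <- gaussian_kde(x)
  d <- kd$density
  local_max <- which(diff(sign(diff(d))) == -2) + 1L
  modes <- kd$grid[local_max][d[local_max] > 0.05 * max(d)]
  expect_gte(length(modes), 2)
})

test_that("vectorized KDE equals the scalar double-loop oracle", {
  set.seed(2)
  x <- runif(37)
  kd <- gaussian_kde(x, h = 0.1, grid_size = 64L)
  expect_equal(kd$density, kde_oracle(x, kd$grid, 0.1), tolerance = 1e-12)
  expect_error(gaussian_kde(x, h = -1), class = "bandwidth_error")
})

test_that("quartile tiers follow the stated percentile and tie conventions", {
  tp <- assign_tiers(as.numeric(1:8))
  expect_equal(tp$tiers$tier, rep(1:4, each = 2))
  expect_error(assign_tiers(rep(1, 10)), class = "partition_error")
  # rank invariance under a monotone transform
  set.seed(6)
  v <- runif(20)
  expect_equal(assign_tiers(v)$tiers$tier, assign_tiers(exp(3 * v))$tiers$tier)
})

test_that("transition matrix counts year-over-year moves correctly", {
  tp <- tier_panel(list(c(1, 1, 2, 2, 3)))
  tm <- transition_matrix(tp)
  expect_equal(tm$prob["I", "I"], 0.5)
  expect_equal(tm$prob["I", "II"], 0.5)
  expect_equal(tm$prob["II", "II"], 0.5)
  expect_equal(tm$prob["II", "III"], 0.5)
  expect_equal(unname(tm$n[1:2]), c(2, 2))
  expect_error(transition_matrix(tier_panel(list(1))), class = "estimation_error")
})

test_that("retention probabilities equal stays over visits", {
  # one unit visiting tier 4 seventy-one times with a single down-move
  path_iv <- c(rep(4, 71), 3)
  tm <- transition_matrix(tier_panel(list(path_iv)))
  expect_equal(unname(tm$n["IV"]), 71)
  expect_equal(tm$prob["IV", "IV"], 70 / 71, tolerance = 1e-12)
  expect_equal(round(tm$prob["IV", "IV"], 4), 0.9859)

  # tier 1: 83 visits, 71 stays, 12 one-tier upgrades, over several units
  paths <- c(replicate(12, c(rep(1, 6), 2), simplify = FALSE),
             list(rep(1, 12)))
  tm1 <- transition_matrix(tier_panel(paths))
  expect_equal(unname(tm1$n["I"]), 83)
  expect_equal(round(tm1$prob["I", "I"], 4), 0.8554)
})

test_that("spatial lag behaves like a neighbour average", {
  adj <- grid_adjacency(2, 2)
  w <- build_weights(adjacency = adj, units = grid_units(2, 2))
  ccd <- data.frame(unit = rep(w$units, 2), year = rep(1:2, each = 4),
                    D = c(rep(0.7, 4), c(0.1, 0.2, 0.3, 0.4)))
  lag <- spatial_lag(ccd, w)
  expect_equal(lag$lag[lag$year == 1], rep(0.7, 4))

  # a unit with one neighbour inherits that neighbour's value
  adj2 <- data.frame(unit_a = c("a", "b"), unit_b = c("b", "c"))
  w2 <- build_weights(adjacency = adj2, units = c("a", "b", "c"))
  ccd2 <- data.frame(unit = c("a", "b", "c"), year = 1, D = c(0.2, 0.5, 0.9))
  l2 <- spatial_lag(ccd2, w2)
  expect_equal(l2$lag[l2$unit == "a"], 0.5)
  expect_equal(l2$lag[l2$unit == "c"], 0.5)
  expect_equal(l2$lag[l2$unit == "b"], (0.2 + 0.9) / 2)

  # permutation equivariance: relabel-stable values
  perm <- c("c", "a", "b")
  w3 <- build_weights(adjacency = adj2, units = perm)
  l3 <- spatial_lag(ccd2, w3)
  expect_equal(l3$lag[match(c("a", "b", "c"), l3$unit)],
               l2$lag[match(c("a", "b", "c"), l2$unit)])
})

test_that("conditioned transition counts partition the unconditional counts", {
  set.seed(33)
  n <- 16; T <- 8
  adj <- grid_adjacency(4, 4)
  w <- build_weights(adjacency = adj, units = grid_units(4, 4))
  ccd <- data.frame(unit = rep(w$units, T), year = rep(1:T, each = n),
                    D = runif(n * T))
  tiers <- assign_tiers(ccd)
  lag <- spatial_lag(ccd, w); lag$D <- lag$lag
  lag_tiers <- assign_tiers(lag)
  sts <- spatial_transition_matrices(tiers, lag_tiers)
  cond_sum <- Reduce(`+`, lapply(sts$conditional, `[[`, "counts"))
  expect_equal(cond_sum, sts$unconditional$counts)
  # rows with visits are proper distributions
  for (g in names(sts$conditional)) {
    tm <- sts$conditional[[g]]
    live <- tm$n > 0
    if (any(live)) expect_equal(unname(rowSums(tm$prob[live, , drop = FALSE])),
                                rep(1, sum(live)), tolerance = 1e-12)
  }
})

test_that("a single shared neighbourhood tier reproduces the unconditional matrix", {
  # constant lag values put every transition in one conditioning bin
  paths <- list(c(1, 2, 3, 4, 4), c(2, 2, 3, 3, 4), c(1, 1, 2, 2, 3),
                c(3, 4, 4, 4, 4))
  tdf <- tier_panel(paths)
  ldf <- tdf; ldf$tier <- 2L
  sts <- spatial_transition_matrices(tdf, ldf)
  expect_equal(sts$conditional[["II"]]$counts, sts$unconditional$counts)
  expect_equal(sum(sts$conditional[["I"]]$counts), 0)
})

test_that("re-estimating from a simulated chain recovers the matrix", {
  P <- matrix(c(0.8, 0.2, 0.0, 0.0,
                0.1, 0.7, 0.2, 0.0,
                0.0, 0.1, 0.8, 0.1,
                0.0, 0.0, 0.2, 0.8), 4, 4, byrow = TRUE)
  set.seed(77)
  steps <- 10000L
  path <- integer(steps + 1L); path[1] <- 1L
  for (t in seq_len(steps)) {
    path[t + 1L] <- sample.int(4, 1, prob = P[path[t], ])
  }
  tm <- transition_matrix(tier_panel(list(path)))
  expect_lt(max(abs(tm$prob - P)), 0.05)
  # birth-death generator: no two-tier jumps ever observed
  expect_equal(tm$counts[cbind(c(1, 1, 2, 4, 3, 4), c(3, 4, 4, 1, 1, 2))],
               rep(0, 6))
})
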