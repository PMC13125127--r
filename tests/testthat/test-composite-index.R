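test_that("min-max standardization maps endpoints and honours direction", {
  units <- c("a", "b", "c")
  panel <- make_panel(c(2, 4, 6), units, 1L, "x1")
  schema <- data.frame(indicator = "x1", subsystem = "s", direction = "+")
  std <- standardize(panel, schema)
  expect_equal(std$std, c(0, 0.5, 1))

  schema$direction <- "-"
  std_neg <- standardize(panel, schema)
  expect_equal(std_neg$std, c(1, 0.5, 0))
  # unit-year holding the raw maximum receives 0 under a negative direction
  expect_equal(std_neg$std[which.max(panel$value)], 0)

  panel$value <- c(5, 5, 5)
  expect_error(standardize(panel, schema), class = "degenerate_indicator")
})

test_that("standardization pool controls the min-max reference set", {
  units <- c("a", "b")
  panel <- rbind(make_panel(c(0, 1), units, 1L, "x1"),
                 make_panel(c(2, 4), units, 2L, "x1"))
  schema <- data.frame(indicator = "x1", subsystem = "s", direction = "+")
  whole <- standardize(panel, schema, pool = "panel")
  expect_equal(range(whole$std), c(0, 1))
  expect_equal(whole$std, c(0, 0.25, 0.5, 1))
  by_year <- standardize(panel, schema, pool = "year")
  expect_equal(by_year$std, c(0, 1, 0, 1))
})

test_that("CRITIC weights reproduce the hand-computed two-column case", {
  std <- std_from_columns(list(x1 = c(0, 0.5, 1), x2 = c(1, 0, 0.5)))
  cw <- critic_weights(std, c("x1", "x2"))
  expect_equal(unname(cw$r[1, 2]), -0.5, tolerance = 1e-12)
  expect_equal(unname(cw$sigma), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(unname(cw$conflict), c(1.5, 1.5), tolerance = 1e-12)
  expect_equal(unname(cw$info), unname(cw$sigma * cw$conflict))
  expect_equal(unname(cw$weights), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("CRITIC weights match a scalar brute-force oracle on small blocks", {
  set.seed(11)
  for (rep in 1:5) {
    p <- sample(2:4, 1)
    m <- sample(4:6, 1)
    cols <- lapply(seq_len(p), function(j) {
      v <- runif(m)
      (v - min(v)) / (max(v) - min(v))
    })
    names(cols) <- paste0("x", seq_len(p))
    std <- std_from_columns(cols)
    cw <- critic_weights(std, names(cols))
    expect_equal(unname(cw$weights), critic_oracle(do.call(cbind, cols)),
                 tolerance = 1e-12)
    expect_equal(sum(cw$weights), 1, tolerance = 1e-10)
    expect_true(all(cw$weights > 0))
  }
})

test_that("totally redundant blocks are rejected", {
  std <- std_from_columns(list(x1 = c(0, 0.5, 1), x2 = c(0, 0.5, 1)))
  expect_error(critic_weights(std, c("x1", "x2")), class = "undefined_weights")
})

test_that("weights are invariant to positive rescaling of a raw indicator", {
  units <- sprintf("u%d", 1:5)
  set.seed(3)
  v1 <- runif(5); v2 <- runif(5)
  schema <- tiny_schema()
  build <- function(scale1) {
    rbind(make_panel(v1 * scale1, units, 1L, "x1"),
          make_panel(v2, units, 1L, "x2"))
  }
  w_a <- critic_weights(standardize(build(1), schema), c("x1", "x2"))
  w_b <- critic_weights(standardize(build(37.5), schema), c("x1", "x2"))
  expect_equal(w_a$weights, w_b$weights, tolerance = 1e-12)
  expect_equal(w_a$sigma, w_b$sigma, tolerance = 1e-12)
  expect_equal(w_a$r, w_b$r, tolerance = 1e-12)
})

test_that("entropy weights: no-information column gets 0, symmetry, sum 1", {
  # hand-built standardized panel: x2 constant, so its shares are uniform,
  # its entropy is exactly 1 and its weight exactly 0
  units <- sprintf("u%d", 1:4)
  std <- rbind(
    data.frame(unit = units, year = 1L, indicator = "x1",
               std = c(0, 0.25, 0.5, 1)),
    data.frame(unit = units, year = 1L, indicator = "x2", std = 0.5)
  )
  ew <- entropy_weights(std, c("x1", "x2"))
  expect_equal(unname(ew$entropy["x2"]), 1, tolerance = 1e-12)
  expect_equal(unname(ew$weights["x2"]), 0)
  expect_equal(sum(ew$weights), 1, tolerance = 1e-10)

  sym <- std_from_columns(list(x1 = c(0, 0.5, 1), x2 = c(1, 0.5, 0)))
  ews <- entropy_weights(sym, c("x1", "x2"))
  expect_equal(unname(ews$weights[1]), unname(ews$weights[2]), tolerance = 1e-10)
})

test_that("composite scores are convex combinations with expected arithmetic", {
  units <- sprintf("u%d", 1:4)
  schema <- tiny_schema()
  panel <- rbind(make_panel(c(1, 2, 3, 4), units, 1L, "x1"),
                 make_panel(c(4, 1, 3, 2), units, 1L, "x2"))
  std <- standardize(panel, schema)
  sc <- composite_scores(std, schema)
  expect_true(all(sc$scores$healthcare >= 0 & sc$scores$healthcare <= 1))
  # manual weighted sum for one unit-year
  w <- sc$weights$healthcare$weights
  m <- std_matrix_check <- std[std$unit == "u1", ]
  u1 <- sum(w[m$indicator] * m$std)
  expect_equal(sc$scores$healthcare[sc$scores$unit == "u1"], u1,
               tolerance = 1e-12)
  # permuting indicator rows leaves scores unchanged
  std_perm <- std[rev(seq_len(nrow(std))), ]
  sc_perm <- composite_scores(std_perm, schema)
  expect_equal(sc$scores, sc_perm$scores, tolerance = 1e-12)
})

test_that("raising a negative-direction indicator never raises a score", {
  units <- sprintf("u%d", 1:5)
  schema <- tiny_schema(directions = c("+", "-"))
  set.seed(8)
  v1 <- runif(5)
  v2 <- c(0.1, 0.9, 0.4, 0.5, 0.6)
  base <- rbind(make_panel(v1, units, 1L, "x1"), make_panel(v2, units, 1L, "x2"))
  bumped <- base
  # bump u3 while staying inside the pool range, so only its cell rescales
  bumped$value[bumped$indicator == "x2" & bumped$unit == "u3"] <- 0.7
  std_b <- standardize(base, schema)
  std_p <- standardize(bumped, schema)
  cell <- function(s, u) s$std[s$indicator == "x2" & s$unit == u]
  expect_lt(cell(std_p, "u3"), cell(std_b, "u3"))
  for (u in setdiff(units, "u3")) expect_equal(cell(std_p, u), cell(std_b, u))
  # holding weights fixed, no unit's composite score increases
  w <- critic_weights(std_b, c("x1", "x2"))$weights
  score <- function(s) {
    vapply(units, function(u) {
      sum(w[s$indicator[s$unit == u]] * s$std[s$unit == u])
    }, numeric(1))
  }
  expect_true(all(score(std_p) <= score(std_b) + 1e-12))
})
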