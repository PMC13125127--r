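# shared fixtures, all built in code

# long panel from a matrix of raw values (rows = unit-years for one indicator)
make_panel <- function(values, units, years, indicator) {
  data.frame(unit = rep(units, length(years)),
             year = rep(years, each = length(units)),
             indicator = indicator,
             value = values,
             stringsAsFactors = FALSE)
}

# two-indicator single-subsystem schema
tiny_schema <- function(directions = c("+", "+"), subsystem = "healthcare") {
  data.frame(indicator = paste0("x", seq_along(directions)),
             subsystem = subsystem, direction = directions,
             stringsAsFactors = FALSE)
}

# rook adjacency for an r x c grid; units in column-major cell order
grid_adjacency <- function(r, c) {
  id <- function(i, j) sprintf("C%02d", (j - 1) * r + i)
  out <- list()
  for (j in seq_len(c)) for (i in seq_len(r)) {
    if (i < r) out[[length(out) + 1L]] <- c(id(i, j), id(i + 1, j))
    if (j < c) out[[length(out) + 1L]] <- c(id(i, j), id(i, j + 1))
  }
  m <- do.call(rbind, out)
  data.frame(unit_a = m[, 1], unit_b = m[, 2], stringsAsFactors = FALSE)
}

grid_units <- function(r, c) sprintf("C%02d", seq_len(r * c))

# standardized panel wrapper for hand-made standardized columns: builds a
# raw panel whose min-max standardization reproduces the given columns
std_from_columns <- function(cols) {
  # cols: named list of numeric vectors in [0,1], one per indicator
  units <- sprintf("u%d", seq_along(cols[[1]]))
  schema <- data.frame(indicator = names(cols), subsystem = "s",
                       direction = "+", stringsAsFactors = FALSE)
  panel <- do.call(rbind, lapply(names(cols), function(ind) {
    data.frame(unit = units, year = 1L, indicator = ind,
               value = cols[[ind]], stringsAsFactors = FALSE)
  }))
  standardize(panel, schema)
}

# brute-force scalar CRITIC computation (independent oracle)
critic_oracle <- function(M) {
  m <- nrow(M); p <- ncol(M)
  sigma <- numeric(p); r <- matrix(0, p, p)
  for (j in 1:p) {
    mu <- sum(M[, j]) / m
    sigma[j] <- sqrt(sum((M[, j] - mu)^2) / (m - 1))
  }
  for (j in 1:p) for (l in 1:p) {
    mj <- sum(M[, j]) / m; ml <- sum(M[, l]) / m
    num <- sum((M[, j] - mj) * (M[, l] - ml))
    r[j, l] <- num / sqrt(sum((M[, j] - mj)^2) * sum((M[, l] - ml)^2))
  }
  cj <- numeric(p)
  for (j in 1:p) for (l in 1:p) cj[j] <- cj[j] + (1 - r[l, j])
  info <- sigma * cj
  info / sum(info)
}

# explicit double-sum Moran's I (independent oracle)
moran_oracle <- function(y, W) {
  n <- length(y); zbar <- mean(y)
  num <- 0
  for (i in 1:n) for (j in 1:n) {
    num <- num + W[i, j] * (y[i] - zbar) * (y[j] - zbar)
  }
  n * num / (sum(W) * sum((y - zbar)^2))
}

# scalar double-loop KDE (independent oracle)
kde_oracle <- function(values, grid, h) {
  N <- length(values)
  out <- numeric(length(grid))
  for (g in seq_along(grid)) {
    s <- 0
    for (i in seq_len(N)) {
      u <- (values[i] - grid[g]) / h
      s <- s + exp(-u^2 / 2) / sqrt(2 * pi)
    }
    out[g] <- s / (N * h)
  }
  out
}

# tier panel from per-unit tier paths (list of integer vectors)
tier_panel <- function(paths) {
  do.call(rbind, lapply(seq_along(paths), function(i) {
    data.frame(unit = sprintf("u%02d", i), year = seq_along(paths[[i]]),
               tier = paths[[i]], stringsAsFactors = FALSE)
  }))
}
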