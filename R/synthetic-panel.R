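#' Default indicator schema for the three health subsystems
#'
#' A compact schema mirroring the structure of provincial health evaluation
#' systems: ten healthcare, eleven insurance and eight pharmaceutical
#' indicators, with a mix of positive and negative directions (mortality and
#' incidence rates, contribution burdens).
#'
#' @return Data frame `indicator`, `subsystem`, `dimension`, `direction`.
#' @export
default_indicator_schema <- function() {
  rbind(
    data.frame(indicator = paste0("hc", 1:10), subsystem = "healthcare",
               dimension = rep(c("resources", "service_scale", "efficiency",
                                 "prevention"), c(4, 2, 2, 2)),
               direction = c(rep("+", 8), "-", "-"),
               stringsAsFactors = FALSE),
    data.frame(indicator = paste0("ins", 1:11), subsystem = "insurance",
               dimension = rep(c("funding", "compensation", "coverage",
                                 "sustainability"), c(4, 3, 2, 2)),
               direction = c("-", "-", rep("+", 9)),
               stringsAsFactors = FALSE),
    data.frame(indicator = paste0("ph", 1:8), subsystem = "pharma",
               dimension = rep(c("scale", "economic", "innovation"),
                               c(2, 3, 3)),
               direction = rep("+", 8),
               stringsAsFactors = FALSE)
  )
}

#' Synthetic geography: units on a grid in three longitudinal bands
#'
#' Places `n_units` on an integer grid whose columns form three bands
#' standing in for the eastern, central and western regional tiers, and
#' derives queen contiguity (Chebyshev distance 1) between occupied cells.
#'
#' @param n_units Number of units (default 31).
#' @return A list: `centroids` (`unit`, `x`, `y`, `region`), `adjacency`
#'   (`unit_a`, `unit_b`), `region` (named character vector).
#' @export
synthetic_geography <- function(n_units = 31L) {
  n_units <- check_count(n_units, "n_units")
  n_cols <- max(3L, ceiling(sqrt(n_units)))
  n_rows <- ceiling(n_units / n_cols)
  cells <- expand.grid(y = seq_len(n_rows), x = seq_len(n_cols))
  cells <- cells[order(cells$x, cells$y), ][seq_len(n_units), ]
  # three longitudinal bands: low x = west, high x = east
  band <- cut(cells$x, breaks = stats::quantile(seq_len(n_cols), c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE, labels = c("west", "central", "east"))
  units <- sprintf("U%02d", seq_len(n_units))
  centroids <- data.frame(unit = units, x = cells$x, y = cells$y,
                          region = as.character(band), stringsAsFactors = FALSE)
  pairs <- which(outer(seq_len(n_units), seq_len(n_units), function(i, j) {
    i < j & pmax(abs(cells$x[i] - cells$x[j]), abs(cells$y[i] - cells$y[j])) == 1
  }), arr.ind = TRUE)
  adjacency <- data.frame(unit_a = units[pairs[, 1]], unit_b = units[pairs[, 2]],
                          stringsAsFactors = FALSE)
  list(centroids = centroids, adjacency = adjacency,
       region = stats::setNames(centroids$region, units))
}

#' Simulation configuration for the synthetic panel
#'
#' Collects and validates every knob of the generator: panel dimensions,
#' region level offsets (east above central above west), positive annual
#' drift per subsystem, noise level, the spatial autocorrelation injected
#' into the latent qualities, covariate ranges matching provincial
#' magnitudes, and an optional threshold data-generating process.
#'
#' @param n_units,n_years Panel dimensions.
#' @param indicator_schema Schema data frame (see
#'   [default_indicator_schema()]).
#' @param region_level_offsets Named list of per-region additive offsets on
#'   the latent subsystem qualities.
#' @param annual_drift Named per-subsystem positive yearly drift.
#' @param noise_sd Standard deviation of both the latent disturbance and the
#'   indicator measurement noise.
#' @param spatial_rho_dgp Spatial autoregressive coefficient applied to the
#'   latent disturbances, in (-1, 1).
#' @param covariate_ranges Named list of `c(min, max)` per covariate.
#' @param threshold_dgp Optional list `gamma`, `beta_low`, `beta_high`.
#' @param seed Integer seed.
#' @return Validated config list of class `sim_config`.
#' @export
sim_config <- function(n_units = 31L, n_years = 11L,
                       indicator_schema = default_indicator_schema(),
                       region_level_offsets = list(east = 0.15, central = 0,
                                                   west = -0.15),
                       annual_drift = c(healthcare = 0.02, insurance = 0.025,
                                        pharma = 0.03),
                       noise_sd = 0.05,
                       spatial_rho_dgp = 0.4,
                       covariate_ranges = list(
                         GDP = c(22400, 216700),
                         GHI = c(3.97, 13.93),
                         Urb = c(23.97, 89.58),
                         Edu = c(0.89, 4.37),
                         Old = c(7.01, 30.6)),
                       threshold_dgp = NULL,
                       seed = 1L) {
  n_units <- check_count(n_units, "n_units")
  n_years <- check_count(n_years, "n_years")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(spatial_rho_dgp, "spatial_rho_dgp", lower = -0.999, upper = 0.999)
  check_count(seed, "seed", lower = 0L)
  if (!all(c("indicator", "subsystem", "direction") %in% names(indicator_schema))) {
    stop_ccd("indicator_schema needs indicator, subsystem, direction columns",
             class = "invalid_config")
  }
  if (anyDuplicated(indicator_schema$indicator)) {
    stop_ccd("duplicate indicator ids in schema", class = "invalid_config")
  }
  if (!all(indicator_schema$direction %in% c("+", "-"))) {
    stop_ccd("directions must be '+' or '-'", class = "invalid_config")
  }
  subs <- unique(indicator_schema$subsystem)
  if (!all(subs %in% names(annual_drift)) || any(annual_drift <= 0)) {
    stop_ccd("annual_drift must be positive and name every subsystem",
             class = "invalid_config")
  }
  if (!is.null(threshold_dgp) &&
      !all(c("gamma", "beta_low", "beta_high") %in% names(threshold_dgp))) {
    stop_ccd("threshold_dgp needs gamma, beta_low, beta_high",
             class = "invalid_config")
  }
  structure(list(n_units = n_units, n_years = n_years,
                 indicator_schema = indicator_schema,
                 region_level_offsets = region_level_offsets,
                 annual_drift = annual_drift, noise_sd = noise_sd,
                 spatial_rho_dgp = spatial_rho_dgp,
                 covariate_ranges = covariate_ranges,
                 threshold_dgp = threshold_dgp, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic indicator panel with known regional structure
#'
#' Each unit-year carries a latent quality per subsystem: a base level plus
#' the region offset, a positive annual drift, and a spatially smoothed
#' disturbance (I - rho W)^(-1) eps scaled by `noise_sd`. Indicators are
#' noisy affine transforms of the latent quality; negative-direction
#' indicators receive a sign flip before noise so that higher raw values
#' mean worse underlying quality.
#'
#' @param cfg A `sim_config`.
#' @param geography Optional output of [synthetic_geography()]; generated
#'   from `cfg$n_units` when absent.
#' @return A list of class `synthetic_panel`: `panel` (long data frame
#'   `unit`, `year`, `indicator`, `value`), `schema`, `geography`,
#'   `covariates`, `latent` (unit x year x subsystem array), `config`.
#' @export
generate_indicator_panel <- function(cfg, geography = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(geography)) geography <- synthetic_geography(cfg$n_units)
  units <- geography$centroids$unit
  region <- geography$region[units]
  subs <- unique(cfg$indicator_schema$subsystem)
  years <- seq_len(cfg$n_years)

  set.seed(stage_seed(cfg$seed, "indicator_panel"))
  w <- build_weights(adjacency = geography$adjacency,
                     centroids = geography$centroids,
                     units = units, kind = "contiguity")
  Ainv <- solve(diag(cfg$n_units) - cfg$spatial_rho_dgp * w$W)

  offsets <- unlist(cfg$region_level_offsets)[region]
  latent <- array(NA_real_, dim = c(cfg$n_units, cfg$n_years, length(subs)),
                  dimnames = list(units, years, subs))
  for (s in seq_along(subs)) {
    for (t in years) {
      eps <- stats::rnorm(cfg$n_units, 0, cfg$noise_sd)
      latent[, t, s] <- 0.5 + offsets + cfg$annual_drift[subs[s]] * (t - 1) +
        drop(Ainv %*% eps)
    }
  }

  schema <- cfg$indicator_schema
  # per-indicator affine loadings, fixed across unit-years
  a_j <- stats::runif(nrow(schema), -0.1, 0.1)
  b_j <- stats::runif(nrow(schema), 0.8, 1.2)
  rows <- vector("list", nrow(schema))
  for (j in seq_len(nrow(schema))) {
    s <- match(schema$subsystem[j], subs)
    sgn <- if (schema$direction[j] == "+") 1 else -1
    vals <- a_j[j] + sgn * b_j[j] * latent[, , s] +
      matrix(stats::rnorm(cfg$n_units * cfg$n_years, 0, cfg$noise_sd),
             cfg$n_units, cfg$n_years)
    rows[[j]] <- data.frame(unit = rep(units, cfg$n_years),
                            year = rep(years, each = cfg$n_units),
                            indicator = schema$indicator[j],
                            value = as.vector(vals),
                            stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, rows)
  panel <- panel[order(panel$unit, panel$year, panel$indicator), ]
  rownames(panel) <- NULL

  covariates <- generate_covariate_panel(cfg, units)
  structure(list(panel = panel, schema = schema, geography = geography,
                 covariates = covariates, latent = latent, config = cfg),
            class = "synthetic_panel")
}

#' Generate a covariate panel within configured ranges
#'
#' Unit baselines are drawn uniformly within each covariate's min-max range;
#' years evolve by a mild AR(1) (persistence 0.8) around the baseline with
#' innovations scaled to 5% of the range, clipped back into the range.
#'
#' @param cfg A `sim_config`.
#' @param units Character unit ids.
#' @return Data frame `unit`, `year`, one column per covariate.
#' @export
generate_covariate_panel <- function(cfg, units) {
  set.seed(stage_seed(cfg$seed, "covariates"))
  n <- length(units)
  out <- data.frame(unit = rep(units, cfg$n_years),
                    year = rep(seq_len(cfg$n_years), each = n),
                    stringsAsFactors = FALSE)
  for (v in names(cfg$covariate_ranges)) {
    rng <- cfg$covariate_ranges[[v]]
    base <- stats::runif(n, rng[1], rng[2])
    X <- matrix(NA_real_, n, cfg$n_years)
    X[, 1] <- base
    innov_sd <- 0.05 * diff(rng)
    for (t in seq_len(cfg$n_years)[-1]) {
      X[, t] <- base + 0.8 * (X[, t - 1] - base) + stats::rnorm(n, 0, innov_sd)
    }
    X <- pmin(pmax(X, rng[1]), rng[2])
    out[[v]] <- as.vector(X)
  }
  out[order(out$unit, out$year), , drop = FALSE]
}

#' Simulate an outcome panel from a spatial Durbin generating process
#'
#' Per year t: y_t = (I - rho W)^(-1) (X_t beta + W X_t theta + eps_t) with
#' eps ~ N(0, sigma^2). The ground truth used is recorded alongside the
#' outcome for recovery testing.
#'
#' @param w A `spatial_weights` object (row-standardized recommended).
#' @param X Covariate panel (`unit`, `year`, covariate columns).
#' @param rho Spatial autoregressive coefficient; (I - rho W) must be
#'   invertible.
#' @param betas,theta Coefficient vectors on X and WX (recycled/matched to
#'   the covariate columns).
#' @param sigma Disturbance standard deviation.
#' @param seed Integer seed.
#' @return A list of class `sdm_dgp`: `outcome` (`unit`, `year`, `y`),
#'   `ground_truth` (list `true_rho`, `true_betas`, `true_theta`,
#'   `sigma`).
#' @export
generate_sdm_outcome <- function(w, X, rho, betas, theta, sigma, seed = 1L) {
  stopifnot(inherits(w, "spatial_weights"))
  W <- w$W
  n <- nrow(W)
  vars <- setdiff(names(X), c("unit", "year"))
  k <- length(vars)
  betas <- rep_len(betas, k); theta <- rep_len(theta, k)
  ev <- eigen(W, only.values = TRUE)$values
  ev <- Re(ev[abs(Im(ev)) < 1e-8])
  if (any(abs(1 - rho * ev) < 1e-8)) {
    stop_ccd("(I - rho W) singular at rho = ", rho, class = "generation_error")
  }
  A <- diag(n) - rho * W
  Ainv <- solve(A)
  set.seed(stage_seed(seed, "sdm_outcome"))
  out <- lapply(split(X, X$year), function(xt) {
    if (nrow(xt) != n) stop_ccd("covariate panel does not match W",
                                class = "shape_error")
    xt <- xt[match(w$units, xt$unit), , drop = FALSE]
    Xm <- as.matrix(xt[, vars, drop = FALSE])
    eps <- stats::rnorm(n, 0, sigma)
    y <- drop(Ainv %*% (Xm %*% betas + W %*% Xm %*% theta + eps))
    data.frame(unit = xt$unit, year = xt$year, y = y, stringsAsFactors = FALSE)
  })
  outcome <- do.call(rbind, out)
  rownames(outcome) <- NULL
  structure(list(outcome = outcome[order(outcome$unit, outcome$year), ],
                 ground_truth = list(true_rho = rho,
                                     true_betas = stats::setNames(betas, vars),
                                     true_theta = stats::setNames(theta, vars),
                                     sigma = sigma)),
            class = "sdm_dgp")
}

#' Simulate a regime-switching outcome for threshold-regression testing
#'
#' y_it = mu_i + controls delta + beta_low q 1(q <= gamma) +
#' beta_high q 1(q > gamma) + eps, with unit fixed effects mu_i ~ N(0, 0.5).
#'
#' @param q Data frame `unit`, `year`, `q` — the threshold variable.
#' @param gamma Threshold location, strictly inside the observed range of q.
#' @param beta_low,beta_high Regime slopes on q.
#' @param controls Optional data frame `unit`, `year` plus control columns.
#' @param delta Coefficients on the controls.
#' @param sigma Noise standard deviation.
#' @param seed Integer seed.
#' @return A list of class `threshold_dgp`: `outcome` (`unit`, `year`,
#'   `y`), `ground_truth` (`true_gamma`, `true_regime_betas`, `delta`,
#'   `sigma`, `unit_effects`).
#' @export
generate_threshold_outcome <- function(q, gamma, beta_low, beta_high,
                                       controls = NULL, delta = NULL,
                                       sigma = 0.1, seed = 1L) {
  if (gamma <= min(q$q) || gamma >= max(q$q)) {
    stop_ccd("gamma must lie strictly inside the observed range of q",
             class = "invalid_config")
  }
  set.seed(stage_seed(seed, "threshold_outcome"))
  units <- sort(unique(q$unit))
  mu <- stats::setNames(stats::rnorm(length(units), 0, 0.5), units)
  y <- mu[as.character(q$unit)] +
    ifelse(q$q <= gamma, beta_low, beta_high) * q$q +
    stats::rnorm(nrow(q), 0, sigma)
  if (!is.null(controls)) {
    vars <- setdiff(names(controls), c("unit", "year"))
    delta <- rep_len(if (is.null(delta)) 0 else delta, length(vars))
    key <- paste(q$unit, q$year)
    idx <- match(key, paste(controls$unit, controls$year))
    if (anyNA(idx)) stop_ccd("controls do not cover all unit-years",
                             class = "invalid_config")
    y <- y + drop(as.matrix(controls[idx, vars, drop = FALSE]) %*% delta)
  }
  structure(list(outcome = data.frame(unit = q$unit, year = q$year, y = y,
                                      stringsAsFactors = FALSE),
                 ground_truth = list(true_gamma = gamma,
                                     true_regime_betas = c(low = beta_low,
                                                           high = beta_high),
                                     delta = delta, sigma = sigma,
                                     unit_effects = mu)),
            class = "threshold_dgp")
}

#' Write the synthetic artefacts of a simulation to CSV/JSON files
#'
#' @param sim A `synthetic_panel`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_synthetic_panel <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(panel = file.path(dir, "indicator_panel.csv"),
             schema = file.path(dir, "schema.csv"),
             covariates = file.path(dir, "covariates.csv"),
             centroids = file.path(dir, "centroids.csv"),
             adjacency = file.path(dir, "adjacency.csv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  utils::write.csv(sim$panel, paths["panel"], row.names = FALSE)
  utils::write.csv(sim$schema, paths["schema"], row.names = FALSE)
  utils::write.csv(sim$covariates, paths["covariates"], row.names = FALSE)
  utils::write.csv(sim$geography$centroids, paths["centroids"], row.names = FALSE)
  utils::write.csv(sim$geography$adjacency, paths["adjacency"], row.names = FALSE)
  gt <- list(spatial_rho_dgp = sim$config$spatial_rho_dgp,
             region_level_offsets = sim$config$region_level_offsets,
             annual_drift = as.list(sim$config$annual_drift),
             noise_sd = sim$config$noise_sd,
             seed = sim$config$seed)
  jsonlite::write_json(gt, paths["ground_truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
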