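# Orchestration: simulate -> weights -> scores -> CCD -> dynamics ->
# spatial tests -> SDM -> threshold, as a configured, logged run writing
# CSV tables with provenance headers.

#' Build and validate a pipeline run configuration
#'
#' @param out_dir Output directory for all tables.
#' @param seed Run-level seed; per-stage seeds are derived with
#'   [stage_seed()].
#' @param stages Character vector of stages to run, in dependency order.
#' @param weighting `"critic"` or `"entropy"`.
#' @param pool Standardization pool, `"panel"` or `"year"`.
#' @param quartile_scheme `"pooled"` or `"per_year"` for the Markov tiers.
#' @param moran_kind,sdm_kind Weight-matrix constructions for the
#'   autocorrelation analyses (contiguity default) and the SDM
#'   (inverse-distance default).
#' @param n_permutations Permutations for the LISA analysis.
#' @param n_bootstrap Bootstrap replicates for the threshold tests.
#' @param alpha Significance level for LISA classes.
#' @param sim Optional `sim_config` for the simulate stage.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir = "ccd_run", seed = 1L,
                       stages = c("simulate", "weights", "ccd", "kde",
                                  "markov", "moran", "lisa", "sdm",
                                  "threshold"),
                       weighting = c("critic", "entropy"),
                       pool = c("panel", "year"),
                       quartile_scheme = c("pooled", "per_year"),
                       moran_kind = "contiguity",
                       sdm_kind = "inverse_distance",
                       n_permutations = 999L, n_bootstrap = 300L,
                       alpha = 0.05, sim = NULL) {
  weighting <- match.arg(weighting)
  pool <- match.arg(pool)
  quartile_scheme <- match.arg(quartile_scheme)
  known <- c("simulate", "weights", "ccd", "kde", "markov", "moran",
             "lisa", "sdm", "threshold")
  if (!all(stages %in% known)) {
    stop_ccd("unknown stages: ", paste(setdiff(stages, known), collapse = ", "),
             class = "invalid_config")
  }
  structure(list(out_dir = out_dir, seed = check_count(seed, "seed", 0L),
                 stages = known[known %in% stages], weighting = weighting,
                 pool = pool, quartile_scheme = quartile_scheme,
                 moran_kind = moran_kind, sdm_kind = sdm_kind,
                 n_permutations = check_count(n_permutations, "n_permutations"),
                 n_bootstrap = check_count(n_bootstrap, "n_bootstrap"),
                 alpha = alpha,
                 sim = if (is.null(sim)) sim_config(seed = seed) else sim),
            class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- unclass(cfg)
  plain$out_dir <- NULL   # hash the analysis settings, not the target path
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

write_table <- function(df, path, cfg, hash) {
  con <- file(path, "w")
  writeLines(c(sprintf("# healthccd pipeline table"),
               sprintf("# config_hash: %s", hash),
               sprintf("# seed: %d", cfg$seed)), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  path
}

#' Validate pipeline inputs
#'
#' Checks panel balance, schema coverage, direction labels and geography
#' completeness; issues are collected into a report rather than failing at
#' the first problem.
#'
#' @param panel Long indicator panel (`unit`, `year`, `indicator`,
#'   `value`).
#' @param schema Indicator schema (`indicator`, `subsystem`, `direction`).
#' @param geography List with `centroids` and/or `adjacency` (as produced
#'   by [synthetic_geography()]), or `NULL` to skip geography checks.
#' @return Data frame of issues (`check`, `detail`); zero rows when valid.
#' @export
validate_inputs <- function(panel, schema, geography = NULL) {
  issues <- list()
  add <- function(check, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(check = check, detail = detail,
                                                 stringsAsFactors = FALSE)
  }
  need <- c("unit", "year", "indicator", "value")
  if (!all(need %in% names(panel))) {
    add("panel_columns", paste("missing:", paste(setdiff(need, names(panel)),
                                                 collapse = ", ")))
    return(do.call(rbind, issues))
  }
  units <- sort(unique(panel$unit)); years <- sort(unique(panel$year))
  inds <- sort(unique(as.character(panel$indicator)))
  have <- unique(panel[c("unit", "year")])
  want <- expand.grid(unit = units, year = years, stringsAsFactors = FALSE)
  miss <- want[!paste(want$unit, want$year) %in% paste(have$unit, have$year), ]
  for (i in seq_len(nrow(miss))) {
    add("balance", sprintf("missing unit-year: %s %s", miss$unit[i], miss$year[i]))
  }
  tab <- table(paste(panel$unit, panel$year))
  if (length(unique(tab)) > 1L) {
    add("balance", "unequal indicator counts across unit-years")
  }
  uncovered <- setdiff(inds, as.character(schema$indicator))
  for (ind in uncovered) add("schema", sprintf("indicator without schema row: %s", ind))
  if ("direction" %in% names(schema)) {
    bad <- schema$indicator[!schema$direction %in% c("+", "-")]
    for (ind in bad) add("schema", sprintf("indicator without valid direction: %s", ind))
  } else {
    add("schema", "schema has no direction column")
  }
  if (!is.null(geography)) {
    geo_units <- unique(c(as.character(geography$centroids$unit),
                          as.character(geography$adjacency$unit_a),
                          as.character(geography$adjacency$unit_b)))
    for (u in setdiff(units, geo_units)) {
      add("geography", sprintf("unit missing from geography: %s", u))
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(check = character(), detail = character(),
                  stringsAsFactors = FALSE)
}

#' Run the full coupling-coordination pipeline
#'
#' Executes the requested stages in dependency order on a synthetic panel
#' (or one supplied through `sim_data`), writing one CSV table per stage to
#' `cfg$out_dir`. Every table carries a provenance header with the config
#' hash and seed, so two runs with the same configuration are file-hash
#' identical.
#'
#' @param cfg A `run_config`.
#' @param sim_data Optional pre-built `synthetic_panel` (the simulate stage
#'   is then a no-op re-use).
#' @return Invisibly, a run report: list with `files`, `timings`,
#'   `results`.
#' @export
run_pipeline <- function(cfg, sim_data = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  files <- character(); timings <- numeric(); results <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    v
  }
  need <- function(what, stage) {
    if (is.null(results[[what]])) {
      stop_ccd("stage '", stage, "' needs upstream artefact '", what, "'",
               class = "dependency_error")
    }
    results[[what]]
  }

  if ("simulate" %in% cfg$stages || !is.null(sim_data)) {
    sim <- tick("simulate",
      if (is.null(sim_data)) generate_indicator_panel(cfg$sim) else sim_data)
    results$sim <- sim
    files["panel"] <- write_table(sim$panel,
                                  file.path(cfg$out_dir, "indicator_panel.csv"),
                                  cfg, hash)
    files["covariates"] <- write_table(sim$covariates,
                                       file.path(cfg$out_dir, "covariates.csv"),
                                       cfg, hash)
  }

  if ("weights" %in% cfg$stages) {
    t0 <- proc.time()[["elapsed"]]
    sim <- need("sim", "weights")
    std <- standardize(sim$panel, sim$schema, pool = cfg$pool)
    scores <- composite_scores(std, sim$schema, method = cfg$weighting)
    results$std <- std; results$scores <- scores
    wt <- do.call(rbind, lapply(names(scores$weights), function(s) {
      w <- scores$weights[[s]]
      data.frame(subsystem = s, indicator = names(w$weights),
                 weight = unname(w$weights), stringsAsFactors = FALSE)
    }))
    files["weights"] <- write_table(wt, file.path(cfg$out_dir, "weights.csv"),
                                    cfg, hash)

    timings["weights"] <- proc.time()[["elapsed"]] - t0
  }

  if ("ccd" %in% cfg$stages) {
    t0 <- proc.time()[["elapsed"]]
    scores <- need("scores", "ccd")
    ccd <- ccd_table(scores)
    results$ccd <- ccd
    files["ccd"] <- write_table(ccd, file.path(cfg$out_dir, "ccd.csv"),
                                cfg, hash)

    timings["ccd"] <- proc.time()[["elapsed"]] - t0
  }

  w_moran <- function(sim) build_weights(adjacency = sim$geography$adjacency,
                                         centroids = sim$geography$centroids,
                                         units = sim$geography$centroids$unit,
                                         kind = cfg$moran_kind)
  w_sdm <- function(sim) build_weights(adjacency = sim$geography$adjacency,
                                       centroids = sim$geography$centroids,
                                       units = sim$geography$centroids$unit,
                                       kind = cfg$sdm_kind)

  if ("kde" %in% cfg$stages) {
    t0 <- proc.time()[["elapsed"]]
    ccd <- need("ccd", "kde")
    years <- range(ccd$year)
    kt <- do.call(rbind, lapply(years, function(yr) {
      k <- gaussian_kde(ccd$D[ccd$year == yr])
      data.frame(year = yr, x = k$grid, density = k$density, h = k$h)
    }))
    results$kde <- kt
    files["kde"] <- write_table(kt, file.path(cfg$out_dir, "kde.csv"),
                                cfg, hash)

    timings["kde"] <- proc.time()[["elapsed"]] - t0
  }

  if ("markov" %in% cfg$stages) {
    t0 <- proc.time()[["elapsed"]]
    ccd <- need("ccd", "markov"); sim <- need("sim", "markov")
    w <- w_moran(sim)
    tiers <- assign_tiers(ccd, scheme = cfg$quartile_scheme)
    lag <- spatial_lag(ccd, w)
    lag$D <- lag$lag
    lag_tiers <- assign_tiers(lag, scheme = cfg$quartile_scheme)
    sts <- spatial_transition_matrices(tiers, lag_tiers)
    results$markov <- sts
    files["markov"] <- write_table(transition_table(sts),
                                   file.path(cfg$out_dir, "markov.csv"),
                                   cfg, hash)

    timings["markov"] <- proc.time()[["elapsed"]] - t0
  }

  if ("moran" %in% cfg$stages) {
    t0 <- proc.time()[["elapsed"]]
    ccd <- need("ccd", "moran"); sim <- need("sim", "moran")
    w <- w_moran(sim)
    mt <- do.call(rbind, lapply(sort(unique(ccd$year)), function(yr) {
      y <- ccd$D[ccd$year == yr][match(w$units, ccd$unit[ccd$year == yr])]
      m <- global_moran(y, w)
      data.frame(year = yr, I = m$I, EI = m$expectation, SDI = m$sd,
                 z = m$z, p = m$p)
    }))
    results$moran <- mt
    files["moran"] <- write_table(mt, file.path(cfg$out_dir, "moran.csv"),
                                  cfg, hash)

    timings["moran"] <- proc.time()[["elapsed"]] - t0
  }

  if ("lisa" %in% cfg$stages) {
    t0 <- proc.time()[["elapsed"]]
    ccd <- need("ccd", "lisa"); sim <- need("sim", "lisa")
    w <- w_moran(sim)
    yr <- max(ccd$year)
    y <- ccd$D[ccd$year == yr][match(w$units, ccd$unit[ccd$year == yr])]
    ls <- local_moran(y, w, alpha = cfg$alpha,
                      n_permutations = cfg$n_permutations,
                      seed = stage_seed(cfg$seed, "lisa"))
    results$lisa <- ls
    files["lisa"] <- write_table(cbind(year = yr, ls$stats),
                                 file.path(cfg$out_dir, "lisa.csv"),
                                 cfg, hash)

    timings["lisa"] <- proc.time()[["elapsed"]] - t0
  }

  if ("sdm" %in% cfg$stages) {
    t0 <- proc.time()[["elapsed"]]
    ccd <- need("ccd", "sdm"); sim <- need("sim", "sdm")
    w <- w_sdm(sim)
    fit <- fit_sdm(ccd, sim$covariates, w, effects = "random")
    results$sdm <- fit
    tab <- fit$coefficients
    tab <- rbind(tab, data.frame(term = c("R2", "logLik", "N"),
                                 estimate = c(fit$R2, fit$logLik, fit$n * fit$T),
                                 se = NA, z = NA, p = NA))
    files["sdm"] <- write_table(tab, file.path(cfg$out_dir, "sdm.csv"),
                                cfg, hash)

    timings["sdm"] <- proc.time()[["elapsed"]] - t0
  }

  if ("threshold" %in% cfg$stages) {
    t0 <- proc.time()[["elapsed"]]
    ccd <- need("ccd", "threshold"); sim <- need("sim", "threshold")
    cov <- sim$covariates
    q <- data.frame(unit = cov$unit, year = cov$year, q = cov$Old)
    controls <- cov[, c("unit", "year", "GDP", "GHI", "Urb", "Edu")]
    fit <- fit_threshold(ccd, q, controls)
    tst <- bootstrap_f_test(fit, n_bootstrap = cfg$n_bootstrap,
                            seed = stage_seed(cfg$seed, "threshold_test"))
    results$threshold <- list(fit = fit, test = tst)
    tab <- data.frame(kind = "single", gamma = fit$gamma, RSS = fit$rss,
                      MSE = fit$mse, F_stat = tst$F_stat, p = tst$p,
                      crit10 = tst$crit[1], crit5 = tst$crit[2],
                      crit1 = tst$crit[3])
    files["threshold"] <- write_table(tab,
                                      file.path(cfg$out_dir, "threshold.csv"),
                                      cfg, hash)
    files["threshold_coef"] <- write_table(fit$coefficients,
                                           file.path(cfg$out_dir,
                                                     "threshold_coefficients.csv"),
                                           cfg, hash)

    timings["threshold"] <- proc.time()[["elapsed"]] - t0
  }

  invisible(list(files = files, timings = timings, results = results,
                 config_hash = hash))
}
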