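#' Ten-level coupling coordination classification table
#'
#' Left-closed, right-open intervals tiling \[0, 1\]; the top interval is
#' closed at 1 so that a perfect score classifies.
#'
#' @return A data frame with `lower`, `upper`, `level`.
#' @export
coordination_levels <- function() {
  data.frame(
    lower = seq(0, 0.9, by = 0.1),
    upper = seq(0.1, 1, by = 0.1),
    level = c("Extreme imbalance", "Severe imbalance", "Moderate imbalance",
              "Mild imbalance", "Borderline imbalance", "Barely coordinated",
              "Basic coordination", "Intermediate coordination",
              "Good coordination", "Excellent coordination"),
    stringsAsFactors = FALSE
  )
}

#' Coupling degree of three subsystem scores
#'
#' C = 3 (U1 U2 U3)^(1/3) / (U1 + U2 + U3). By the AM-GM inequality C lies
#' in \[0, 1\] with equality to 1 iff all three scores are equal; C is 0
#' whenever any score is 0. Vectorized over unit-years.
#'
#' @param u1,u2,u3 Nonnegative subsystem scores.
#' @return Coupling degree(s) in \[0, 1\].
#' @export
coupling_degree <- function(u1, u2, u3) {
  if (any(u1 < 0 | u2 < 0 | u3 < 0)) {
    stop_ccd("subsystem scores must be nonnegative", class = "range_error")
  }
  s <- u1 + u2 + u3
  if (any(s == 0)) {
    stop_ccd("coupling degree undefined when all subsystem scores are zero",
             class = "undefined_coupling")
  }
  3 * (u1 * u2 * u3)^(1 / 3) / s
}

#' Classify a coupling coordination degree into its ten-level label
#'
#' @param d Coupling coordination degree(s) in \[0, 1\].
#' @return Character vector of level labels.
#' @export
classify_level <- function(d) {
  if (any(d < 0 | d > 1 | !is.finite(d))) {
    stop_ccd("D must lie in [0, 1]", class = "range_error")
  }
  lv <- coordination_levels()
  idx <- pmin(findInterval(d, lv$lower), nrow(lv))
  lv$level[idx]
}

#' Coupling coordination degree with classification
#'
#' Combines the coupling degree C with the comprehensive coordination index
#' T = alpha U1 + beta U2 + lambda U3 into D = sqrt(C * T), and attaches the
#' ten-level label.
#'
#' @inheritParams coupling_degree
#' @param alpha,beta,lambda Nonnegative weights summing to 1; defaults treat
#'   the three subsystems as equally important.
#' @return A data frame with columns `C`, `T`, `D`, `level`.
#' @export
coupling_coordination <- function(u1, u2, u3,
                                  alpha = 1 / 3, beta = 1 / 3, lambda = 1 / 3) {
  if (alpha < 0 || beta < 0 || lambda < 0 ||
      abs(alpha + beta + lambda - 1) > 1e-8) {
    stop_ccd("alpha, beta, lambda must be nonnegative and sum to 1",
             class = "invalid_config")
  }
  C <- coupling_degree(u1, u2, u3)
  Tn <- alpha * u1 + beta * u2 + lambda * u3
  D <- sqrt(C * Tn)
  data.frame(C = C, T = Tn, D = D, level = classify_level(D),
             stringsAsFactors = FALSE)
}

#' Per unit-year coupling coordination table from subsystem scores
#'
#' @param scores A `subsystem_scores` object (see [composite_scores()]); the
#'   first three subsystem columns after `unit`, `year` are used in order.
#' @inheritParams coupling_coordination
#' @return Data frame `unit`, `year`, `U1`, `U2`, `U3`, `C`, `T`, `D`,
#'   `level`.
#' @export
ccd_table <- function(scores, alpha = 1 / 3, beta = 1 / 3, lambda = 1 / 3) {
  df <- if (inherits(scores, "subsystem_scores")) scores$scores else scores
  subs <- setdiff(names(df), c("unit", "year"))
  if (length(subs) < 3L) stop_ccd("need three subsystem columns",
                                  class = "invalid_config")
  cc <- coupling_coordination(df[[subs[1]]], df[[subs[2]]], df[[subs[3]]],
                              alpha, beta, lambda)
  out <- data.frame(unit = df$unit, year = df$year,
                    U1 = df[[subs[1]]], U2 = df[[subs[2]]], U3 = df[[subs[3]]],
                    stringsAsFactors = FALSE)
  cbind(out, cc)
}

#' Average annual growth rate (geometric CAGR)
#'
#' 100 * ((last / first)^(1 / n_intervals) - 1), the compound annual growth
#' rate across `n_intervals` year-to-year steps.
#'
#' @param first,last Endpoint values; `first` must be positive.
#' @param n_intervals Number of year-to-year intervals (years - 1).
#' @return Growth rate in percent.
#' @export
average_annual_growth <- function(first, last, n_intervals) {
  check_number(first, "first")
  if (first <= 0) stop_ccd("first endpoint must be positive",
                           class = "domain_error")
  check_count(n_intervals, "n_intervals")
  100 * ((last / first)^(1 / n_intervals) - 1)
}

#' Group units into four trajectory categories by final-year CCD
#'
#' Default rule: quartiles of final-year D; top quartile is Leading, then
#' Advantageous, CatchingUp, and Lagging for the bottom quartile. Ranks are
#' broken deterministically by unit id. The rule is pluggable through
#' `rule`, a function mapping the final-year data frame to a character
#' vector of labels.
#'
#' @param ccd A CCD table from [ccd_table()].
#' @param year_first,year_last Anchor years; both must be present for every
#'   unit.
#' @param rule Optional replacement grouping function.
#' @return Data frame `unit`, `d_first`, `d_last`, `group`.
#' @export
trajectory_groups <- function(ccd, year_first, year_last, rule = NULL) {
  first <- ccd[ccd$year == year_first, c("unit", "D")]
  last <- ccd[ccd$year == year_last, c("unit", "D")]
  units <- sort(unique(ccd$unit))
  if (!all(units %in% first$unit) || !all(units %in% last$unit)) {
    stop_ccd("every unit needs both anchor years", class = "completeness_error")
  }
  df <- data.frame(unit = units,
                   d_first = first$D[match(units, first$unit)],
                   d_last = last$D[match(units, last$unit)],
                   stringsAsFactors = FALSE)
  if (!is.null(rule)) {
    df$group <- rule(df)
    return(df)
  }
  ord <- order(-df$d_last, df$unit)   # ties broken by unit id
  rk <- integer(nrow(df)); rk[ord] <- seq_len(nrow(df))
  qsize <- nrow(df) / 4
  grp <- ceiling(rk / qsize)
  df$group <- c("Leading", "Advantageous", "CatchingUp", "Lagging")[grp]
  df
}
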