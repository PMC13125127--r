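#' Min-max standardization with indicator directions
#'
#' Maps each indicator onto \[0, 1\] with the direction-aware min-max
#' transform: positive indicators by (x - min) / (max - min), negative
#' indicators by (max - x) / (max - min), so that after standardization
#' larger is always better. The pool over which min and max are taken is
#' either the whole panel (default, so scores are comparable across years)
#' or each year separately.
#'
#' @param panel Long-format data frame with columns `unit`, `year`,
#'   `indicator`, `value`.
#' @param schema Data frame with columns `indicator`, `subsystem`,
#'   `direction` (`"+"` or `"-"`), optionally `dimension`.
#' @param pool `"panel"` (all unit-years jointly) or `"year"`.
#' @return A data frame like `panel` with an extra column `std` in \[0, 1\],
#'   carrying the schema columns, of class `standardized_panel`.
#' @export
standardize <- function(panel, schema, pool = c("panel", "year")) {
  pool <- match.arg(pool)
  need <- c("unit", "year", "indicator", "value")
  if (!all(need %in% names(panel))) {
    stop_ccd("panel must have columns ", paste(need, collapse = ", "),
             class = "invalid_config")
  }
  if (!all(c("indicator", "subsystem", "direction") %in% names(schema))) {
    stop_ccd("schema must have columns indicator, subsystem, direction",
             class = "invalid_config")
  }
  if (!all(schema$direction %in% c("+", "-"))) {
    stop_ccd("schema directions must be '+' or '-'", class = "invalid_config")
  }
  m <- match(as.character(panel$indicator), as.character(schema$indicator))
  if (anyNA(m)) {
    bad <- unique(panel$indicator[is.na(m)])
    stop_ccd("indicators missing from schema: ", paste(bad, collapse = ", "),
             class = "invalid_config")
  }
  dir <- schema$direction[m]
  grp <- if (pool == "panel") as.character(panel$indicator)
         else paste(panel$indicator, panel$year, sep = "\r")
  lo <- ave(panel$value, grp, FUN = min)
  hi <- ave(panel$value, grp, FUN = max)
  rng <- hi - lo
  if (any(rng == 0)) {
    bad <- unique(panel$indicator[rng == 0])
    stop_ccd("degenerate (constant) indicator within pool: ",
             paste(bad, collapse = ", "), class = "degenerate_indicator")
  }
  std <- ifelse(dir == "+", (panel$value - lo) / rng, (hi - panel$value) / rng)
  out <- panel
  out$subsystem <- as.character(schema$subsystem[m])
  out$direction <- dir
  out$std <- std
  class(out) <- c("standardized_panel", class(out))
  out
}

# wide unit-year x indicator matrix of standardized values for one block
std_matrix <- function(std, indicators) {
  sub <- std[std$indicator %in% indicators, , drop = FALSE]
  key <- paste(sub$unit, sub$year, sep = "\r")
  rows <- sort(unique(key))
  M <- matrix(NA_real_, length(rows), length(indicators),
              dimnames = list(rows, indicators))
  M[cbind(match(key, rows), match(as.character(sub$indicator), indicators))] <- sub$std
  if (anyNA(M)) stop_ccd("unbalanced panel: missing unit-year x indicator cells",
                         class = "invalid_config")
  M
}

#' CRITIC objective weights for a block of indicators
#'
#' Computes, on standardized values, each indicator's contrast intensity
#' (sample standard deviation, (m-1) denominator), its conflict with the
#' other indicators (the sum of one minus the pairwise Pearson correlations,
#' with the self term contributing zero), the information capacity
#' I_j = sigma_j * c_j, and weights W_j = I_j / sum(I_j).
#'
#' @param std A `standardized_panel` from [standardize()].
#' @param indicators Character vector naming the block (typically one
#'   subsystem's indicators). A single-indicator block gets weight 1 with a
#'   warning.
#' @return A list of class `critic_weights` with `sigma`, `r` (correlation
#'   matrix), `conflict`, `info`, `weights`, `method = "critic"`.
#' @export
critic_weights <- function(std, indicators) {
  M <- std_matrix(std, indicators)
  p <- ncol(M)
  if (p == 1L) {
    warning("single-indicator block: weight fixed at 1", call. = FALSE)
    return(structure(list(sigma = stats::sd(M[, 1]), r = matrix(1, 1, 1),
                          conflict = 0, info = 0,
                          weights = stats::setNames(1, indicators),
                          method = "critic"),
                     class = "critic_weights"))
  }
  sigma <- apply(M, 2, stats::sd)
  if (any(sigma == 0)) {
    stop_ccd("zero-variance standardized column in block: ",
             paste(indicators[sigma == 0], collapse = ", "),
             class = "degenerate_indicator")
  }
  r <- stats::cor(M)
  conflict <- colSums(1 - r)
  info <- sigma * conflict
  tot <- sum(info)
  if (tot <= 0) {
    stop_ccd("all information capacities are zero (totally redundant block)",
             class = "undefined_weights")
  }
  structure(list(sigma = sigma, r = r, conflict = conflict, info = info,
                 weights = info / tot, method = "critic"),
            class = "critic_weights")
}

#' Entropy weights for a block of indicators
#'
#' Robustness alternative to [critic_weights()]: shares p_ij of each
#' indicator column (after shifting zeros by a small offset), entropy
#' e_j = -(1 / ln m) sum p ln p, and weights proportional to 1 - e_j.
#'
#' @inheritParams critic_weights
#' @param offset Small positive shift applied before computing shares so
#'   that zero standardized values do not produce log(0).
#' @return A list of class `critic_weights` with `entropy`, `weights`,
#'   `method = "entropy"`.
#' @export
entropy_weights <- function(std, indicators, offset = 1e-4) {
  M <- std_matrix(std, indicators) + offset
  m <- nrow(M)
  P <- sweep(M, 2, colSums(M), "/")
  e <- -colSums(P * log(P)) / log(m)
  d <- pmax(1 - e, 0)
  if (sum(d) <= 0) {
    stop_ccd("all entropy redundancies are zero", class = "undefined_weights")
  }
  structure(list(entropy = e, weights = d / sum(d), method = "entropy"),
            class = "critic_weights")
}

#' Composite subsystem development indices
#'
#' Weighted sums U = sum_j W_j X'_ij of standardized indicator values within
#' each subsystem block. Weights default to CRITIC; entropy weights are the
#' robustness alternative. Because weights are convex and X' lies in
#' \[0, 1\], every index lies in \[0, 1\].
#'
#' @param std A `standardized_panel`.
#' @param schema The indicator schema used for standardization.
#' @param method `"critic"` or `"entropy"`.
#' @return A list of class `subsystem_scores`: `scores` (data frame with
#'   `unit`, `year`, one column per subsystem), `weights` (named list of
#'   weight objects per subsystem) and `method`.
#' @export
composite_scores <- function(std, schema, method = c("critic", "entropy")) {
  method <- match.arg(method)
  subsystems <- unique(as.character(schema$subsystem))
  wfun <- if (method == "critic") critic_weights else entropy_weights
  weights <- list()
  pieces <- list()
  for (s in subsystems) {
    ind <- as.character(schema$indicator[schema$subsystem == s])
    w <- wfun(std, ind)
    weights[[s]] <- w
    M <- std_matrix(std, ind)
    pieces[[s]] <- drop(M %*% w$weights[ind])
  }
  rows <- names(pieces[[1]])
  uy <- do.call(rbind, strsplit(rows, "\r", fixed = TRUE))
  scores <- data.frame(unit = uy[, 1],
                       year = as.integer(uy[, 2]),
                       stringsAsFactors = FALSE)
  for (s in subsystems) scores[[s]] <- pieces[[s]][rows]
  scores <- scores[order(scores$unit, scores$year), , drop = FALSE]
  rownames(scores) <- NULL
  structure(list(scores = scores, weights = weights, method = method),
            class = "subsystem_scores")
}
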