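#' Partition CCD values into quartile tiers
#'
#' Cut points are the 25/50/75 percentiles (linear interpolation, R type 7)
#' of either the pooled unit-year distribution (default) or each year
#' separately. Values equal to a cut point go to the lower tier, so the
#' partition is deterministic under ties.
#'
#' @param ccd CCD table with columns `unit`, `year`, `D` (or a numeric
#'   vector when `scheme = "pooled"` and only labels are needed).
#' @param scheme `"pooled"` or `"per_year"`.
#' @return A list of class `tier_partition`: `tiers` (data frame `unit`,
#'   `year`, `D`, `tier` with tiers 1-4, labelled I-IV), `cuts` (the cut
#'   points; a matrix per year for `per_year`), `scheme`.
#' @export
assign_tiers <- function(ccd, scheme = c("pooled", "per_year")) {
  scheme <- match.arg(scheme)
  if (is.numeric(ccd)) {
    ccd <- data.frame(unit = seq_along(ccd), year = 1L, D = ccd)
  }
  d <- ccd$D
  if (length(unique(d)) < 4L) {
    stop_ccd("need at least 4 distinct values to form quartile tiers",
             class = "partition_error")
  }
  tier_of <- function(x, q) 1L + (x > q[1]) + (x > q[2]) + (x > q[3])
  if (scheme == "pooled") {
    cuts <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
    tier <- tier_of(d, cuts)
  } else {
    cuts <- t(vapply(split(d, ccd$year),
                     function(v) stats::quantile(v, c(0.25, 0.5, 0.75),
                                                 names = FALSE),
                     numeric(3)))
    tier <- integer(length(d))
    for (yr in rownames(cuts)) {
      sel <- ccd$year == as.integer(yr)
      tier[sel] <- tier_of(d[sel], cuts[yr, ])
    }
  }
  tiers <- data.frame(unit = ccd$unit, year = ccd$year, D = d, tier = tier,
                      stringsAsFactors = FALSE)
  structure(list(tiers = tiers, cuts = cuts, scheme = scheme),
            class = "tier_partition")
}

tier_labels <- c("I", "II", "III", "IV")

# year-over-year (t, t+1) transitions from a tier table
transition_pairs <- function(tiers) {
  df <- if (inherits(tiers, "tier_partition")) tiers$tiers else tiers
  df <- df[order(df$unit, df$year), , drop = FALSE]
  by_unit <- split(df, df$unit)
  out <- lapply(by_unit, function(u) {
    if (nrow(u) < 2L) return(NULL)
    ok <- diff(u$year) == 1L
    data.frame(unit = u$unit[-nrow(u)][ok], year = u$year[-nrow(u)][ok],
               from = u$tier[-nrow(u)][ok], to = u$tier[-1][ok],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Traditional Markov transition matrix of CCD tiers
#'
#' Maximum-likelihood estimate: counts of year-over-year tier transitions,
#' row-normalized by the number of visits to each starting tier.
#'
#' @param tiers A `tier_partition` or a data frame `unit`, `year`, `tier`.
#' @return A list of class `transition_matrix`: `counts` (4x4), `prob`
#'   (4x4, rows with visits sum to 1), `n` (row totals).
#' @export
transition_matrix <- function(tiers) {
  pairs <- transition_pairs(tiers)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop_ccd("no consecutive-year transitions available", class = "estimation_error")
  }
  counts <- table(factor(pairs$from, levels = 1:4),
                  factor(pairs$to, levels = 1:4))
  counts <- matrix(as.numeric(counts), 4, 4,
                   dimnames = list(tier_labels, tier_labels))
  n <- rowSums(counts)
  prob <- counts / ifelse(n > 0, n, 1)
  prob[n == 0, ] <- NA_real_
  structure(list(counts = counts, prob = prob, n = n),
            class = "transition_matrix")
}

#' Spatial lag of a panel variable
#'
#' Lag_i = sum_j W_ij Y_j computed year by year. With a row-standardized W
#' the lag is the weighted average of neighbours' values, so a constant
#' vector is its own lag.
#'
#' @param ccd CCD table with `unit`, `year` and the value column `D`.
#' @param w A `spatial_weights` object covering all units.
#' @param value Name of the value column.
#' @return Data frame `unit`, `year`, `lag`.
#' @export
spatial_lag <- function(ccd, w, value = "D") {
  stopifnot(inherits(w, "spatial_weights"))
  units <- w$units
  if (!all(ccd$unit %in% units)) {
    stop_ccd("CCD table has units missing from the weight matrix",
             class = "shape_error")
  }
  out <- lapply(split(ccd, ccd$year), function(yr) {
    if (!all(units %in% yr$unit)) {
      stop_ccd("weight matrix has units missing from year ", yr$year[1],
               class = "shape_error")
    }
    y <- yr[[value]][match(units, yr$unit)]
    data.frame(unit = units, year = yr$year[1], lag = drop(w$W %*% y),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$unit, res$year), , drop = FALSE]
}

#' Spatially conditioned Markov transition matrices
#'
#' Transitions are binned by the tier of each unit's spatial lag at the
#' start year t, producing one 4x4 matrix per neighbourhood tier. The
#' cell-wise sum of the four conditioned count matrices equals the
#' unconditional count matrix, since the lag tiers partition the
#' transitions.
#'
#' @param tiers A `tier_partition` of the CCD values.
#' @param lag_tiers A `tier_partition` of the spatial-lag values (same
#'   unit-years).
#' @return A list of class `spatial_transition_set`: `conditional` (list of
#'   four `transition_matrix` objects named I-IV), `unconditional`.
#' @export
spatial_transition_matrices <- function(tiers, lag_tiers) {
  tdf <- if (inherits(tiers, "tier_partition")) tiers$tiers else tiers
  ldf <- if (inherits(lag_tiers, "tier_partition")) lag_tiers$tiers else lag_tiers
  pairs <- transition_pairs(tdf)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop_ccd("no consecutive-year transitions available", class = "estimation_error")
  }
  key <- paste(ldf$unit, ldf$year, sep = "\r")
  lt <- ldf$tier[match(paste(pairs$unit, pairs$year, sep = "\r"), key)]
  if (anyNA(lt)) {
    stop_ccd("missing neighbourhood tier at transition start", class = "conditioning_error")
  }
  conditional <- lapply(1:4, function(g) {
    sub <- pairs[lt == g, , drop = FALSE]
    counts <- table(factor(sub$from, levels = 1:4), factor(sub$to, levels = 1:4))
    counts <- matrix(as.numeric(counts), 4, 4,
                     dimnames = list(tier_labels, tier_labels))
    n <- rowSums(counts)
    prob <- counts / ifelse(n > 0, n, 1)
    prob[n == 0, ] <- NA_real_
    structure(list(counts = counts, prob = prob, n = n),
              class = "transition_matrix")
  })
  names(conditional) <- tier_labels
  structure(list(conditional = conditional,
                 unconditional = transition_matrix(tdf)),
            class = "spatial_transition_set")
}

#' Flatten transition matrices into a long table
#'
#' One row per (chain type, neighbourhood lag type, from-tier) with the four
#' to-tier probabilities and the row total, mirroring the usual published
#' layout of traditional vs spatial Markov results.
#'
#' @param sts A `spatial_transition_set`.
#' @return A data frame.
#' @export
transition_table <- function(sts) {
  stopifnot(inherits(sts, "spatial_transition_set"))
  row_block <- function(tm, type, lag_type) {
    data.frame(type = type, lag_type = lag_type, from = tier_labels,
               I = tm$prob[, 1], II = tm$prob[, 2],
               III = tm$prob[, 3], IV = tm$prob[, 4],
               N = tm$n, row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- row_block(sts$unconditional, "traditional", "none")
  for (g in tier_labels) {
    out <- rbind(out, row_block(sts$conditional[[g]], "spatial", g))
  }
  out
}
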