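#' Global Moran's I with randomization or permutation inference
#'
#' I = n / S0 * sum_ij w_ij z_i z_j / sum_i z_i^2 with z the deviations from
#' the mean. Under randomization the expectation is E(I) = -1/(n-1) and the
#' variance follows the standard randomization-moments formula (which
#' involves the sample kurtosis); a permutation pseudo p-value based on
#' seeded shuffles of y is available as a cross-check.
#'
#' @param y Numeric vector, one value per unit; must be non-constant.
#' @param w A `spatial_weights` object.
#' @param inference `"randomization"` (analytic moments z-test) or
#'   `"permutation"`.
#' @param n_permutations Number of shuffles for permutation inference.
#' @param seed Seed for the permutation shuffles.
#' @param alternative `"two.sided"`, `"greater"` or `"less"` for the
#'   analytic test; the permutation p is one-sided towards the observed
#'   deviation from E(I).
#' @return A list of class `moran_result`: `I`, `expectation`, `sd`, `z`,
#'   `p`, `inference`, `n`.
#' @export
global_moran <- function(y, w, inference = c("randomization", "permutation"),
                         n_permutations = 999L, seed = NULL,
                         alternative = c("two.sided", "greater", "less")) {
  inference <- match.arg(inference)
  alternative <- match.arg(alternative)
  stopifnot(inherits(w, "spatial_weights"))
  W <- w$W
  n <- length(y)
  if (n != nrow(W)) stop_ccd("length(y) must match the weight matrix",
                             class = "shape_error")
  if (stats::sd(y) == 0) stop_ccd("Moran's I undefined for constant y",
                                  class = "undefined_statistic")

  moran_stat <- function(z) {
    # z centered; S0 fixed by W
    n * sum(W * outer(z, z)) / (sum(W) * sum(z^2))
  }
  z <- y - mean(y)
  I <- moran_stat(z)
  EI <- -1 / (n - 1)

  S0 <- sum(W)
  S1 <- sum((W + t(W))^2) / 2
  S2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  num <- n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
    b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)
  den <- (n - 1) * (n - 2) * (n - 3) * S0^2
  VI <- num / den - EI^2
  SDI <- sqrt(VI)
  zstat <- (I - EI) / SDI

  if (inference == "randomization") {
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(zstat)),
                greater = stats::pnorm(zstat, lower.tail = FALSE),
                less = stats::pnorm(zstat))
  } else {
    n_permutations <- check_count(n_permutations, "n_permutations")
    if (!is.null(seed)) set.seed(seed)
    sims <- vapply(seq_len(n_permutations),
                   function(i) moran_stat(sample(z)), numeric(1))
    extreme <- if (I >= EI) sum(sims >= I) else sum(sims <= I)
    p <- (extreme + 1) / (n_permutations + 1)
  }
  structure(list(I = I, expectation = EI, sd = SDI, z = zstat, p = p,
                 inference = inference, n = n),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f  E(I) = %.4f  SD(I) = %.4f  z = %.3f  p = %.4g (%s)\n",
              x$I, x$expectation, x$sd, x$z, x$p, x$inference))
  invisible(x)
}

#' Local Moran's I (LISA) with conditional permutation inference
#'
#' I_i = z_i / m2 * sum_j w_ij z_j with m2 = sum(z^2) / n, so that with a
#' row-standardized W the local statistics sum to n times the global I.
#' Pseudo p-values come from conditional permutations: unit i's value is
#' held fixed while the remaining values are shuffled among the other
#' units. Cluster classes follow the usual quadrant rule on the centered
#' value and centered lag (HH, LL, HL, LH), with `not-significant` when the
#' pseudo p exceeds `alpha`.
#'
#' @inheritParams global_moran
#' @param alpha Significance level for the class assignment.
#' @param adjust Optional multiple-testing adjustment for the pseudo
#'   p-values (a method of [stats::p.adjust()]), off by default.
#' @return A list of class `lisa_result`: data frame `stats` (`unit`,
#'   `Ii`, `p`, `class`), plus `alpha`, `n_permutations`.
#' @export
local_moran <- function(y, w, alpha = 0.05, n_permutations = 999L,
                        seed = NULL, adjust = "none") {
  stopifnot(inherits(w, "spatial_weights"))
  W <- w$W
  n <- length(y)
  if (n != nrow(W)) stop_ccd("length(y) must match the weight matrix",
                             class = "shape_error")
  if (stats::sd(y) == 0) stop_ccd("local Moran undefined for constant y",
                                  class = "undefined_statistic")
  n_permutations <- check_count(n_permutations, "n_permutations")
  z <- y - mean(y)
  m2 <- sum(z^2) / n
  lag <- drop(W %*% z)
  Ii <- z * lag / m2

  if (!is.null(seed)) set.seed(seed)
  p <- numeric(n)
  for (i in seq_len(n)) {
    wi <- W[i, -i]
    zi <- z[-i]
    sims <- vapply(seq_len(n_permutations),
                   function(r) z[i] * sum(wi * sample(zi)) / m2,
                   numeric(1))
    extreme <- if (Ii[i] >= 0) sum(sims >= Ii[i]) else sum(sims <= Ii[i])
    p[i] <- (extreme + 1) / (n_permutations + 1)
  }
  p <- stats::p.adjust(p, method = adjust)
  cls <- ifelse(z >= 0 & lag >= 0, "HH",
         ifelse(z < 0 & lag < 0, "LL",
         ifelse(z >= 0 & lag < 0, "HL", "LH")))
  cls[p > alpha] <- "not-significant"
  structure(list(stats = data.frame(unit = w$units, Ii = Ii, p = p,
                                    class = cls, stringsAsFactors = FALSE),
                 alpha = alpha, n_permutations = n_permutations),
            class = "lisa_result")
}
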