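#' Silverman's rule-of-thumb bandwidth
#'
#' 0.9 min(sd, IQR/1.34) n^(-1/5), the standard plug-in bandwidth for a
#' Gaussian kernel.
#'
#' @param x Numeric sample.
#' @return A positive bandwidth.
#' @export
silverman_bandwidth <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  iqr <- stats::IQR(x)
  spread <- if (iqr > 0) min(s, iqr / 1.34) else s
  if (!is.finite(spread) || spread <= 0) {
    stop_ccd("sample has no spread; bandwidth undefined", class = "bandwidth_error")
  }
  0.9 * spread * n^(-1 / 5)
}

#' Gaussian kernel density estimate on a grid
#'
#' f(x) = (1 / (N h)) sum_i K((X_i - x) / h) with the standard normal kernel
#' K, evaluated on an equally spaced grid spanning the data range extended by
#' four bandwidths on each side (so the density mass is captured and the
#' trapezoid integral is ~1).
#'
#' @param values Numeric observations (N >= 2 unless `allow_single`).
#' @param h Bandwidth; `NULL` for Silverman's rule.
#' @param grid_size Number of grid points.
#' @param allow_single Permit a single observation (the kernel itself).
#' @return A list of class `kde_result` with `grid`, `density`, `h`, `n`.
#' @export
gaussian_kde <- function(values, h = NULL, grid_size = 512L,
                         allow_single = FALSE) {
  values <- as.numeric(values)
  if (anyNA(values)) stop_ccd("values contain NA", class = "invalid_config")
  n <- length(values)
  if (n < 2L && !allow_single) {
    stop_ccd("need at least 2 observations", class = "invalid_config")
  }
  if (is.null(h)) h <- silverman_bandwidth(values)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop_ccd("bandwidth must be a positive number", class = "bandwidth_error")
  }
  grid_size <- check_count(grid_size, "grid_size", lower = 2L)
  grid <- seq(min(values) - 4 * h, max(values) + 4 * h, length.out = grid_size)
  # outer() is fine at panel sizes (a few hundred observations)
  dens <- colMeans(stats::dnorm(outer(values, grid, "-") / h)) / h
  structure(list(grid = grid, density = dens, h = h, n = n),
            class = "kde_result")
}

#' @export
print.kde_result <- function(x, ...) {
  cat(sprintf("kde_result: n = %d, h = %.4g, grid %d points on [%.4g, %.4g]\n",
              x$n, x$h, length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}
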