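#' @keywords internal
"_PACKAGE"

# shared input checks -------------------------------------------------------

stop_ccd <- function(..., class) {
  stop(structure(
    class = c(class, "healthccd_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_ccd(name, " must be a single finite number", class = "invalid_config")
  }
  if (x < lower || x > upper) {
    stop_ccd(name, " must be in [", lower, ", ", upper, "], got ", x,
             class = "invalid_config")
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < lower) {
    stop_ccd(name, " must be an integer >= ", lower, class = "invalid_config")
  }
  invisible(as.integer(x))
}

#' Derive a reproducible child seed from a parent seed and a stage label
#'
#' A single run-level seed is fanned out to per-stage seeds by a stable
#' string hash, so that enabling or disabling one pipeline stage never
#' perturbs the random draws of another.
#'
#' @param seed Integer parent seed.
#' @param label Character stage label.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, label) {
  check_count(seed, "seed", lower = 0L)
  codes <- utf8ToInt(label)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 1000003
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483629)
}

# within-unit demeaning of a column, used by the panel estimators
demean_by <- function(x, id) {
  x - ave(x, id, FUN = mean)
}
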