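#' Build a spatial weight matrix
#'
#' Constructs an n x n nonnegative spatial weight matrix from either an
#' adjacency list (binary contiguity) or centroid coordinates (inverse
#' distance or k-nearest neighbours). Isolated units ("islands") are repaired
#' by linking them to their single nearest neighbour, which requires
#' centroids; the repair is recorded and signalled as a warning.
#'
#' @param adjacency Optional data frame with columns `unit_a`, `unit_b`
#'   listing contiguous pairs (undirected; both orders accepted).
#' @param centroids Optional data frame with columns `unit`, `x`, `y`.
#' @param units Character vector of all unit ids. Defaults to the ids seen in
#'   the geometry inputs.
#' @param kind One of `"contiguity"`, `"inverse_distance"`, `"knn"`.
#' @param k Number of neighbours for `kind = "knn"`.
#' @param row_standardize Logical; divide each row by its sum.
#' @return An object of class `spatial_weights`: a list with the matrix `W`,
#'   `kind`, `row_standardized`, `S0` (sum of all weights) and `units`.
#' @export
build_weights <- function(adjacency = NULL, centroids = NULL, units = NULL,
                          kind = c("contiguity", "inverse_distance", "knn"),
                          k = 4L, row_standardize = TRUE) {
  kind <- match.arg(kind)
  if (is.null(units)) {
    units <- if (!is.null(centroids)) as.character(centroids$unit)
             else unique(c(as.character(adjacency$unit_a),
                           as.character(adjacency$unit_b)))
    units <- sort(unique(units))
  }
  units <- as.character(units)
  if (anyDuplicated(units)) {
    stop_ccd("duplicate unit ids in geometry", class = "geometry_error")
  }
  n <- length(units)
  W <- matrix(0, n, n, dimnames = list(units, units))

  if (kind == "contiguity") {
    if (is.null(adjacency)) stop_ccd("contiguity weights need an adjacency list",
                                     class = "geometry_error")
    a <- match(as.character(adjacency$unit_a), units)
    b <- match(as.character(adjacency$unit_b), units)
    if (anyNA(a) || anyNA(b)) {
      stop_ccd("adjacency references unknown units", class = "geometry_error")
    }
    W[cbind(a, b)] <- 1
    W[cbind(b, a)] <- 1
  } else {
    if (is.null(centroids)) stop_ccd(kind, " weights need centroids",
                                     class = "geometry_error")
    idx <- match(units, as.character(centroids$unit))
    if (anyNA(idx)) stop_ccd("centroids missing for some units",
                             class = "geometry_error")
    xy <- cbind(centroids$x[idx], centroids$y[idx])
    D <- as.matrix(stats::dist(xy))
    off <- D[upper.tri(D)]
    if (any(off == 0)) {
      stop_ccd("zero distance between distinct centroids", class = "geometry_error")
    }
    if (kind == "inverse_distance") {
      W <- 1 / D
      diag(W) <- 0
    } else {
      k <- check_count(k, "k")
      for (i in seq_len(n)) {
        nb <- order(D[i, ])[2:(k + 1L)]
        W[i, nb] <- 1
      }
      # symmetrize so knn graphs are usable for contiguity-style analyses
      W <- pmax(W, t(W))
    }
    dimnames(W) <- list(units, units)
  }
  diag(W) <- 0

  isolated <- which(rowSums(W) == 0)
  if (length(isolated)) {
    if (is.null(centroids)) {
      stop_ccd("isolated units (", paste(units[isolated], collapse = ", "),
               ") and no centroids available for nearest-neighbour repair",
               class = "geometry_error")
    }
    idx <- match(units, as.character(centroids$unit))
    xy <- cbind(centroids$x[idx], centroids$y[idx])
    D <- as.matrix(stats::dist(xy))
    for (i in isolated) {
      nb <- order(D[i, ])[2L]
      W[i, nb] <- 1
      W[nb, i] <- 1
    }
    warning(sprintf("linked %d isolated unit(s) to nearest neighbour",
                    length(isolated)), call. = FALSE)
  }

  S0_raw <- sum(W)
  if (row_standardize) W <- W / rowSums(W)
  structure(
    list(W = W, kind = kind, row_standardized = row_standardize,
         S0 = sum(W), S0_raw = S0_raw, units = units,
         repaired = units[isolated]),
    class = "spatial_weights"
  )
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d units, kind = %s, row-standardized = %s, S0 = %.4g\n",
              length(x$units), x$kind, x$row_standardized, x$S0))
  invisible(x)
}

#' Restrict a spatial weight matrix to a subset of units
#'
#' Drops the excluded units and rebuilds the weights on the remaining block,
#' re-applying row standardization if the parent matrix was standardized.
#' Units left isolated by the subsetting trigger an error.
#'
#' @param w A `spatial_weights` object.
#' @param keep Character vector of unit ids to retain.
#' @return A `spatial_weights` object on the subset.
#' @export
subset_weights <- function(w, keep) {
  stopifnot(inherits(w, "spatial_weights"))
  keep <- as.character(keep)
  if (!all(keep %in% w$units)) stop_ccd("unknown units in subset",
                                        class = "geometry_error")
  W <- w$W[keep, keep, drop = FALSE]
  rs <- rowSums(W)
  if (any(rs == 0)) stop_ccd("subsetting isolated a unit", class = "geometry_error")
  if (w$row_standardized) W <- W / rs
  structure(
    list(W = W, kind = w$kind, row_standardized = w$row_standardized,
         S0 = sum(W), S0_raw = NA_real_, units = keep, repaired = character()),
    class = "spatial_weights"
  )
}
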