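#' Takens delay embedding of a time series
#'
#' Reconstructs a shadow manifold from lagged coordinates of a single
#' series: point at time t is (x_t, x_{t-tau}, ..., x_{t-(E-1)tau}).
#' Vectors that would span an invalid (masked) sample are dropped.
#'
#' @param series a `ccm_series` or numeric vector (`NA` = invalid).
#' @param dimension embedding dimension E (>= 1).
#' @param delay lag tau between coordinates, in samples (>= 1).
#' @return An object of class `shadow_manifold`: list with `points`
#'   (matrix, one row per manifold point, columns ordered most recent
#'   first), `point_times` (1-based sample index of each point's most
#'   recent coordinate), `source_length`, `dimension`, `delay`.
#' @examples
#' m <- delay_embed(c(1, 2, 3, 4, 5), dimension = 2, delay = 1)
#' m$points
#' @export
delay_embed <- function(series, dimension, delay = 1) {
  series <- as_ccm_series(series)
  dimension <- as.integer(dimension)
  delay <- as.integer(delay)
  if (dimension < 1L) stop("dimension must be >= 1")
  if (delay < 1L) stop("delay must be >= 1")
  v <- series$values
  n <- length(v)
  span <- (dimension - 1L) * delay
  if (n < span + 1L)
    stop(sprintf(
      "series too short for embedding: need at least %d samples, got %d",
      span + 1L, n))
  times <- seq.int(span + 1L, n)
  # columns most recent first: x_t, x_{t-tau}, ...
  pts <- vapply(seq_len(dimension) - 1L,
                function(j) v[times - j * delay], numeric(length(times)))
  pts <- matrix(pts, nrow = length(times), ncol = dimension)
  ok <- stats::complete.cases(pts)
  if (!any(ok))
    stop(sprintf(
      "no complete embedding vectors: need %d valid consecutive samples",
      span + 1L))
  structure(list(points = pts[ok, , drop = FALSE],
                 point_times = times[ok],
                 source_length = n,
                 dimension = dimension,
                 delay = delay),
            class = "shadow_manifold")
}

#' @export
print.shadow_manifold <- function(x, ...) {
  cat(sprintf("<shadow_manifold> E = %d, tau = %d, %d points from %d samples\n",
              x$dimension, x$delay, nrow(x$points), x$source_length))
  invisible(x)
}

# Target values of `target` series aligned to manifold point times shifted
# by `lag` (prediction of target(t + lag) from the manifold point at t).
# Returns NA where the shifted time falls outside the series or on an
# invalid sample.
align_target <- function(target, manifold, lag) {
  tv <- as_ccm_series(target)$values
  tt <- manifold$point_times + lag
  out <- rep(NA_real_, length(tt))
  ok <- tt >= 1L & tt <= length(tv)
  out[ok] <- tv[tt[ok]]
  out
}

#' Simplex cross-map prediction
#'
#' Predicts a target series from a shadow manifold of another variable:
#' for each predictable time t the estimate is the weighted mean of the
#' target values at the times of the E+1 nearest library neighbours of
#' the manifold point at t (the query point itself is never its own
#' neighbour). Weights are the simplex exponentials
#' w_i = u_i / sum(u_j), u_i = exp(-d_i / d_1) with d_1 the distance to
#' the nearest neighbour; exact zero-distance ties share equal weight.
#'
#' @param target series to be cross-mapped (`ccm_series` or numeric).
#' @param manifold `shadow_manifold` of the other variable.
#' @param lag cross-map alignment in samples: the manifold point at time
#'   t predicts `target` at time t + lag. Negative lag means the target
#'   (putative cause) precedes the manifold variable (putative effect).
#' @param library_indices indices (into manifold points) of the library;
#'   default all points with a valid aligned target.
#' @param prediction_indices indices of the query points; default all
#'   points with a valid aligned target (queries may overlap the
#'   library — the query point itself is always excluded from its own
#'   neighbourhood).
#' @param num_neighbors number of neighbours; default E + 1 (simplex
#'   convention).
#' @return list with `predicted`, `observed` (aligned equal-length
#'   vectors) and `times` (prediction times on the target's clock).
#' @export
simplex_cross_map <- function(target, manifold, lag = 0,
                              library_indices = NULL,
                              prediction_indices = NULL,
                              num_neighbors = NULL) {
  stopifnot(inherits(manifold, "shadow_manifold"))
  k <- if (is.null(num_neighbors)) manifold$dimension + 1L
       else as.integer(num_neighbors)
  y <- align_target(target, manifold, lag)
  valid <- which(!is.na(y))
  if (length(valid) == 0L)
    stop("alignment error: no overlap between target and manifold after lag shift")
  lib <- if (is.null(library_indices)) valid
         else intersect(as.integer(library_indices), valid)
  pred <- if (is.null(prediction_indices)) valid
          else intersect(as.integer(prediction_indices), valid)
  if (length(pred) == 0L)
    stop("alignment error: no predictable points after lag shift")
  if (length(lib) < k + 1L)
    stop(sprintf(
      "insufficient library: %d points, need at least %d (k = %d plus self-exclusion)",
      length(lib), k + 1L, k))
  est <- simplex_predict_cpp(manifold$points, y, lib, pred, k)
  keep <- !is.na(est)
  list(predicted = est[keep], observed = y[pred][keep],
       times = manifold$point_times[pred][keep] + lag)
}

#' Cross-map skill
#'
#' Pearson correlation between predicted and observed values; defined as
#' 0 when either side has zero variance.
#'
#' @param predicted,observed equal-length aligned numeric vectors (or a
#'   list with components `predicted` and `observed` as returned by
#'   [simplex_cross_map()], in which case `observed` is ignored).
#' @return correlation rho in \[-1, 1\].
#' @export
cross_map_skill <- function(predicted, observed = NULL) {
  if (is.list(predicted) && is.null(observed)) {
    observed <- predicted$observed
    predicted <- predicted$predicted
  }
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  ok <- !is.na(predicted) & !is.na(observed)
  predicted <- predicted[ok]; observed <- observed[ok]
  if (length(predicted) < 3L)
    stop("need at least 3 aligned pairs to compute cross-map skill")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) return(0)
  as.numeric(stats::cor(predicted, observed))
}
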