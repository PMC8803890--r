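# Convergent cross-mapping: convergence-in-library-size curves, the
# extended (lagged) scan, and the positive-lag rejection rule.

# Optimal-lag selection. Exact ties resolve to the smallest |lag|, with
# -k beating +k (causal over anti-causal). The tolerance guards only the
# sign: a positive optimal lag triggers outright rejection downstream,
# so when the skill of a strongly synchronised pair is flat in the lag
# (differences of order 1e-3 are interpolation jitter) a positive argmax
# must beat the best non-positive lag by more than `tol` to stand;
# otherwise the best non-positive lag is selected.
pick_optimal_lag <- function(lags, skills, tol) {
  best <- max(skills, na.rm = TRUE)
  cand <- which(!is.na(skills) & skills == best)
  cand <- cand[order(abs(lags[cand]), lags[cand])]
  pick <- cand[1L]
  if (lags[pick] > 0L) {
    np <- which(!is.na(skills) & lags <= 0L & skills >= best - tol)
    if (length(np) > 0L) {
      np <- np[order(-skills[np], abs(lags[np]))]
      pick <- np[1L]
    }
  }
  list(lag = lags[pick], skill = skills[pick], index = pick)
}

# Default library-size grid: log-spaced sizes from 10*E up to the pool
# maximum.
lib_size_grid <- function(dimension, max_size, n_sizes = 8L) {
  lo <- 10L * as.integer(dimension)
  if (lo >= max_size) return(NULL)
  unique(round(exp(seq(log(lo), log(max_size), length.out = n_sizes))))
}

#' Cross-map skill as a function of library size
#'
#' Tests the direction cause -> effect by cross-mapping the cause from
#' the effect's shadow manifold with libraries of increasing size. Under
#' a true causal influence the skill converges upward as the library
#' grows. Libraries are drawn repeatedly (contiguous blocks or random
#' subsets) and the mean skill per size is reported; both series are
#' z-scored before embedding.
#'
#' @param cause,effect `ccm_series` or numeric vectors on the same
#'   regular time grid.
#' @param dimension embedding dimension E.
#' @param delay embedding delay tau in samples.
#' @param lag cross-map alignment t_p in samples (negative = cause
#'   precedes effect).
#' @param library_sizes increasing integer sizes; default 8 log-spaced
#'   sizes from 10 E to the library-pool maximum.
#' @param n_samples libraries drawn per size.
#' @param sampling `"contiguous"` (random contiguous blocks) or
#'   `"random"` (random subsets).
#' @param train_fraction if non-`NULL`, the first `train_fraction` of
#'   the series provides the library pool and skill is evaluated on
#'   predictions over the remainder (cross-validation through time);
#'   `NULL` uses all points for both.
#' @param seed integer seed for library drawing.
#' @param strict if `TRUE`, a size grid exceeding the pool is an error
#'   instead of being clipped with a warning.
#' @return object of class `ccm_curve`: `library_sizes`, `skills` (mean
#'   per size), `skill_samples` (size x draw matrix), and the
#'   configuration.
#' @examples
#' s <- coupled_logistic_map(n_samples = 400, beta_yx = 0.3, seed = 1)
#' cc <- ccm_curve(s$x, s$y, dimension = 2, seed = 1)
#' cc$skills
#' @export
ccm_curve <- function(cause, effect, dimension = 2, delay = 1, lag = 0,
                      library_sizes = NULL, n_samples = 20,
                      sampling = c("contiguous", "random"),
                      train_fraction = NULL, seed = 1, strict = FALSE) {
  sampling <- match.arg(sampling)
  cause <- as_ccm_series(cause); effect <- as_ccm_series(effect)
  if (length(cause) != length(effect))
    stop("cause and effect must share the same time grid")
  cz <- ccm_series(zscore(cause$values), cause$step)
  ez <- ccm_series(zscore(effect$values), effect$step)
  man <- delay_embed(ez, dimension, delay)
  y <- align_target(cz, man, lag)
  valid <- which(!is.na(y))
  if (length(valid) == 0L)
    stop("alignment error: no overlap after lag shift")
  if (!is.null(train_fraction)) {
    cut <- floor(length(cause) * train_fraction)
    pool <- valid[man$point_times[valid] <= cut]
    pred <- valid[man$point_times[valid] > cut]
  } else {
    pool <- valid
    pred <- valid
  }
  k <- dimension + 1L
  if (length(pool) < k + 1L)
    stop(sprintf("insufficient library: pool of %d points, need >= %d",
                 length(pool), k + 1L))
  if (length(pred) < 3L)
    stop("fewer than 3 predictable points")
  if (is.null(library_sizes)) {
    library_sizes <- lib_size_grid(dimension, length(pool))
    if (is.null(library_sizes)) library_sizes <- length(pool)
  }
  library_sizes <- sort(unique(as.integer(library_sizes)))
  if (any(library_sizes > length(pool))) {
    if (strict)
      stop(sprintf("library sizes exceed available pool (%d points)",
                   length(pool)))
    warning(sprintf("library sizes clipped to pool maximum %d",
                    length(pool)))
    library_sizes <- unique(pmin(library_sizes, length(pool)))
  }
  library_sizes <- library_sizes[library_sizes >= k + 1L]
  if (length(library_sizes) == 0L)
    stop(sprintf("no feasible library size >= %d", k + 1L))
  sk <- ccm_skills_cpp(man$points, y, pool, pred, library_sizes,
                       as.integer(n_samples), sampling == "contiguous",
                       k, as.integer(seed))
  structure(list(library_sizes = library_sizes,
                 skills = rowMeans(sk),
                 skill_samples = sk,
                 dimension = dimension, delay = delay, lag = lag,
                 n_samples = n_samples, sampling = sampling, seed = seed,
                 n_pool = length(pool), n_pred = length(pred)),
            class = "ccm_curve")
}

#' @export
print.ccm_curve <- function(x, ...) {
  cat(sprintf("<ccm_curve> E = %d, lag = %d: rho %.3f -> %.3f over L = %d..%d\n",
              x$dimension, x$lag, x$skills[1L],
              x$skills[length(x$skills)],
              x$library_sizes[1L], x$library_sizes[length(x$library_sizes)]))
  invisible(x)
}

#' @export
as.data.frame.ccm_curve <- function(x, ...) {
  data.frame(library_size = x$library_sizes, skill = x$skills)
}

#' Terminal (maximal-library) skill of a ccm_curve
#' @param curve a `ccm_curve`.
#' @return rho at the largest library size.
#' @export
terminal_skill <- function(curve) {
  curve$skills[length(curve$skills)]
}

#' Extended CCM: scan cross-map alignments and select the optimal lag
#'
#' Evaluates full-library cross-map skill for each candidate alignment
#' lag and selects the lag with maximal skill (t_p). Exact ties resolve
#' to the smallest |lag|, and between -k and +k to -k (favouring the
#' causal over the anti-causal alignment). Because a positive optimal
#' lag triggers outright rejection downstream, the sign is additionally
#' guarded by `lag_tol`: when skill is nearly flat in the lag (strongly
#' synchronised pairs), a positive argmax must beat the best
#' non-positive lag by more than `lag_tol` to stand.
#'
#' @inheritParams ccm_curve
#' @param lags integer candidate lags; default -15:15 (31 lags).
#' @param min_pairs minimum aligned pairs for a lag to be feasible.
#' @param lag_tol skill margin a positive optimal lag must have over
#'   every non-positive lag.
#' @return object of class `lag_scan`: `lags`, `skill_at_lag`
#'   (`NA` where infeasible), `optimal_lag`, `optimal_skill`.
#' @export
lag_scan <- function(cause, effect, dimension = 2, delay = 1,
                     lags = -15:15, min_pairs = 50,
                     train_fraction = NULL, lag_tol = 0.01) {
  cause <- as_ccm_series(cause); effect <- as_ccm_series(effect)
  if (length(cause) != length(effect))
    stop("cause and effect must share the same time grid")
  cz <- ccm_series(zscore(cause$values), cause$step)
  ez <- ccm_series(zscore(effect$values), effect$step)
  man <- delay_embed(ez, dimension, delay)
  k <- dimension + 1L
  lags <- as.integer(lags)
  skills <- rep(NA_real_, length(lags))
  for (i in seq_along(lags)) {
    y <- align_target(cz, man, lags[i])
    valid <- which(!is.na(y))
    if (!is.null(train_fraction)) {
      cut <- floor(length(cause) * train_fraction)
      pool <- valid[man$point_times[valid] <= cut]
      pred <- valid[man$point_times[valid] > cut]
    } else {
      pool <- valid; pred <- valid
    }
    if (length(pred) < max(min_pairs, 3L) || length(pool) < k + 1L) next
    est <- simplex_predict_cpp(man$points, y, pool, pred, k)
    ok <- !is.na(est)
    if (sum(ok) < max(min_pairs, 3L)) next
    skills[i] <- cross_map_skill(est[ok], y[pred][ok])
  }
  if (all(is.na(skills)))
    stop("alignment error: every candidate lag is infeasible")
  opt <- pick_optimal_lag(lags, skills, lag_tol)
  structure(list(lags = lags, skill_at_lag = skills,
                 optimal_lag = opt$lag,
                 optimal_skill = opt$skill,
                 lag_tol = lag_tol,
                 dimension = dimension, delay = delay),
            class = "lag_scan")
}

#' @export
print.lag_scan <- function(x, ...) {
  cat(sprintf("<lag_scan> %d lags in [%d, %d]; optimal t_p = %d (rho = %.3f)\n",
              length(x$lags), min(x$lags), max(x$lags),
              x$optimal_lag, x$optimal_skill))
  invisible(x)
}

#' Positive-lag rejection rule of extended CCM
#'
#' A causal direction is rejected when the optimal cross-map lag is
#' positive (the putative effect would precede its cause); accepted when
#' negative; accepted-but-flagged-instantaneous when zero (such links
#' require the information-geometric mask, see [mask_rccm()]).
#'
#' @param scan a `lag_scan` object, or a single integer optimal lag.
#' @return list with `accepted` (logical), `status` one of
#'   `"accepted"`, `"accepted_instantaneous"`, `"rejected"`, and
#'   `optimal_lag`.
#' @export
accept_by_lag <- function(scan) {
  lag <- if (inherits(scan, "lag_scan")) scan$optimal_lag
         else as.integer(scan)
  status <- if (lag > 0L) "rejected"
            else if (lag == 0L) "accepted_instantaneous"
            else "accepted"
  list(accepted = lag <= 0L, status = status, optimal_lag = lag)
}
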