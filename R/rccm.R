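# Robust CCM: bootstrap-through-time windows, median-aggregated
# skill-difference curves, automatic embedding-dimension selection, and
# the robust cross-map skill rho-tilde.

#' Plan bootstrap windows through time
#'
#' Builds `n_runs` whole-year windows of equal length with evenly spaced
#' start offsets (overlapping as needed). The window length is the
#' smallest whole-year span containing `min_valid_run` samples, so an
#' 11-year series at 46 samples/year with the default 400-sample minimum
#' yields 9-year windows whose starts span the remaining 2 years.
#'
#' @param series_length total samples available.
#' @param year_length samples per year (e.g. 46 for 8-day sampling).
#' @param n_runs number of bootstrap windows (default 10).
#' @param min_valid_run minimum samples a run needs (default 400).
#' @param train_fraction fraction of each window used as the library
#'   (training) segment; the remainder is predicted (default 1/3).
#' @return object of class `window_plan`: data frame `windows` with
#'   1-based `start`/`end`, plus the plan parameters.
#' @export
plan_windows <- function(series_length, year_length, n_runs = 10,
                         min_valid_run = 400, train_fraction = 1 / 3) {
  series_length <- as.integer(series_length)
  year_length <- as.integer(year_length)
  n_runs <- as.integer(n_runs)
  if (year_length < 1L) stop("year_length must be >= 1")
  if (n_runs < 1L) stop("n_runs must be >= 1")
  window_years <- max(1L, as.integer(ceiling(min_valid_run / year_length)))
  wlen <- window_years * year_length
  if (wlen > series_length)
    stop(sprintf(
      "cannot fit %d window(s) of %d samples (%d whole years): series has only %d samples, %d short",
      n_runs, wlen, window_years, series_length, wlen - series_length))
  slack <- series_length - wlen
  starts <- 1L + as.integer(round(seq(0, slack, length.out = n_runs)))
  windows <- data.frame(start = starts, end = starts + wlen - 1L)
  structure(list(windows = windows, n_runs = n_runs,
                 year_length = year_length, window_years = window_years,
                 window_length = wlen, min_valid_run = min_valid_run,
                 train_fraction = train_fraction),
            class = "window_plan")
}

#' @export
print.window_plan <- function(x, ...) {
  cat(sprintf(
    "<window_plan> %d windows of %d samples (%d whole years), starts %d..%d\n",
    x$n_runs, x$window_length, x$window_years,
    min(x$windows$start), max(x$windows$start)))
  invisible(x)
}

#' Split a window into training and testing segments
#'
#' The first `train_fraction` (default one third) of the window is the
#' library (training) segment; the remainder is tested.
#'
#' @param window a single window length, a `c(start, end)` pair, or a
#'   one-row slice of a `window_plan`'s `windows`.
#' @param train_fraction fraction used for training.
#' @return list with `train` and `test`, each `c(start, end)` in the
#'   series' own sample coordinates.
#' @export
split_train_test <- function(window, train_fraction = 1 / 3) {
  if (is.data.frame(window)) window <- c(window$start[1L], window$end[1L])
  if (length(window) == 1L) window <- c(1L, as.integer(window))
  start <- as.integer(window[1L]); end <- as.integer(window[2L])
  len <- end - start + 1L
  if (len < 3L) stop("window must span at least 3 samples")
  ntrain <- max(1L, as.integer(floor(len * train_fraction)))
  list(train = c(start, start + ntrain - 1L),
       test = c(start + ntrain, end))
}

# Library-pool size for one window: embedding points whose time falls in
# the training segment and whose lag-shifted target is valid.
window_pool_size <- function(cvals, evals, dimension, delay, lag,
                             start, end, train_fraction) {
  n <- end - start + 1L
  span <- (dimension - 1L) * delay
  if (n < span + 1L) return(0L)
  w_e <- evals[start:end]; w_c <- cvals[start:end]
  times <- seq.int(span + 1L, n)
  ok <- rep(TRUE, length(times))
  for (j in seq_len(dimension) - 1L)
    ok <- ok & !is.na(w_e[times - j * delay])
  tt <- times + lag
  ok <- ok & tt >= 1L & tt <= n
  ok[ok] <- !is.na(w_c[tt[ok]])
  cut <- floor(n * train_fraction)
  sum(ok & times <= cut)
}

# Cross-map curve for one window of the pair, library drawn from the
# window's training third, skill evaluated on its test remainder.
window_curve <- function(cause, effect, start, end, dimension, delay, lag,
                         library_sizes, n_samples, sampling,
                         train_fraction, seed) {
  cw <- ccm_series(cause$values[start:end], cause$step)
  ew <- ccm_series(effect$values[start:end], effect$step)
  ccm_curve(cw, ew, dimension = dimension, delay = delay, lag = lag,
            library_sizes = library_sizes, n_samples = n_samples,
            sampling = sampling, train_fraction = train_fraction,
            seed = seed)
}

#' Automatic embedding-dimension selection
#'
#' For each candidate dimension, runs the windowed cross-map curve in
#' every bootstrap window and takes the median terminal skill across
#' windows; the dimension maximising this median is selected. The
#' smallest dimension whose median skill comes within `dim_tol` of the
#' maximum wins (parsimony: skill estimates carry sampling jitter, and
#' exact ties — e.g. on structureless noise — resolve to the smallest
#' dimension).
#'
#' @inheritParams ccm_curve
#' @param plan a `window_plan` (see [plan_windows()]).
#' @param dim_range candidate dimensions (default 1:10).
#' @param dim_tol skill margin within which a smaller dimension is
#'   preferred.
#' @return list with `selected`, `median_skills` (named by dimension,
#'   `NA` where infeasible), and `per_dimension` terminal-skill
#'   matrices (window x library size).
#' @export
select_dimension <- function(cause, effect, plan, dim_range = 1:10,
                             delay = 1, lag = 0, n_samples = 20,
                             sampling = "contiguous", dim_tol = 0.01,
                             seed = 1) {
  cause <- as_ccm_series(cause); effect <- as_ccm_series(effect)
  if (length(dim_range) == 0L) stop("dim_range must be non-empty")
  dim_range <- sort(unique(as.integer(dim_range)))
  w <- plan$windows
  med <- stats::setNames(rep(NA_real_, length(dim_range)),
                         as.character(dim_range))
  details <- vector("list", length(dim_range))
  for (di in seq_along(dim_range)) {
    p <- dim_range[di]
    pools <- vapply(seq_len(nrow(w)), function(i)
      window_pool_size(cause$values, effect$values, p, delay, lag,
                       w$start[i], w$end[i], plan$train_fraction),
      integer(1L))
    grid <- lib_size_grid(p, min(pools))
    if (is.null(grid) || min(pools) < p + 2L) next
    term <- rep(NA_real_, nrow(w))
    for (i in seq_len(nrow(w))) {
      cv <- try(window_curve(cause, effect, w$start[i], w$end[i], p, delay,
                             lag, grid, n_samples, sampling,
                             plan$train_fraction, derive_seed(seed, i)),
                silent = TRUE)
      if (!inherits(cv, "try-error")) term[i] <- terminal_skill(cv)
    }
    if (all(is.na(term))) next
    med[di] <- stats::median(term, na.rm = TRUE)
    details[[di]] <- term
  }
  if (all(is.na(med))) stop("no feasible embedding dimension in dim_range")
  best <- max(med, na.rm = TRUE)
  selected <- dim_range[which(!is.na(med) & med >= best - dim_tol)[1L]]
  list(selected = selected, median_skills = med, per_dimension = details)
}

#' Median one-step skill-difference curve
#'
#' Per run, takes consecutive differences of the skill curve over the
#' library-size grid, then the element-wise median across runs: a
#' robust estimate of the change in cross-map skill as the library
#' grows.
#'
#' @param per_run_skills matrix (run x library size) of cross-map
#'   skills.
#' @return numeric vector of length `ncol - 1`; length 0 (with
#'   attribute `flagged = TRUE`) when only one library size is present.
#' @export
median_delta_curve <- function(per_run_skills) {
  m <- as.matrix(per_run_skills)
  if (nrow(m) < 1L) stop("need at least one run")
  if (ncol(m) < 2L) {
    out <- numeric(0)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  deltas <- m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  apply(deltas, 2L, stats::median, na.rm = TRUE)
}

#' Robust convergent cross-mapping of one causal direction
#'
#' Fits the full robust CCM decision for the direction cause -> effect:
#' whole-year bootstrap windows with different start points, first-third
#' training / remainder testing per window, automatic embedding
#' dimension selection by median terminal skill, median one-step
#' skill-difference (convergence) curve, extended lag scan with the
#' positive-lag rejection rule, and the robust skill rho-tilde (median
#' across runs of terminal skill at the selected dimension and optimal
#' lag).
#'
#' @inheritParams ccm_curve
#' @param year_length samples per year (windows are whole years).
#' @param dimension fixed embedding dimension; `NULL` (default) selects
#'   it automatically over `dim_range`.
#' @param dim_range candidate dimensions for automatic selection.
#' @param lags candidate cross-map lags t_p (default -15:15); a single
#'   value fixes the alignment without scanning.
#' @param n_runs bootstrap windows (default 10).
#' @param min_valid_run minimum valid samples per run (default 400); a
#'   window below the minimum is dropped, and the decision requires at
#'   least half the runs to survive.
#' @param skill_threshold minimal rho-tilde for the convergence verdict
#'   (default 0; map products typically use 0.8).
#' @param min_pairs minimum aligned pairs for a lag to be feasible.
#' @param lag_tol skill tolerance within which lags count as tied in the
#'   lag scan (see [lag_scan()]).
#' @param labels optional `c(cause = , effect = )` names recorded in the
#'   decision.
#' @return object of class `rccm`; see Details.
#' @details The returned object carries `robust_skill` (rho-tilde),
#'   `selected_dimension`, `optimal_lag` (t_p), `convergent` (positive
#'   early slope of the median delta curve and rho-tilde at or above the
#'   threshold), `accept` (the positive-lag rule verdict),
#'   `per_run_skills` (run x library size), `median_delta_curve`,
#'   per-lag median skills, and the window plan. Links with t_p = 0 are
#'   flagged instantaneous and should be passed through [mask_rccm()]
#'   together with an [igci()] score.
#' @examples
#' s <- coupled_logistic_map(n_samples = 600, beta_yx = 0.3, seed = 7)
#' fit <- rccm(s$x, s$y, year_length = 50, min_valid_run = 450,
#'             dimension = 2, lags = -3:3, seed = 7)
#' fit
#' @export
rccm <- function(cause, effect, year_length, dimension = NULL,
                 dim_range = 1:10, delay = 1, lags = -15:15,
                 n_runs = 10, min_valid_run = 400,
                 train_fraction = 1 / 3, n_samples = 20,
                 sampling = "contiguous", skill_threshold = 0,
                 min_pairs = 50, lag_tol = 0.01, seed = 1,
                 labels = NULL) {
  cause <- as_ccm_series(cause); effect <- as_ccm_series(effect)
  if (length(cause) != length(effect))
    stop("cause and effect must share the same time grid")
  plan <- plan_windows(length(cause), year_length, n_runs, min_valid_run,
                       train_fraction)
  # run-failure policy: a window without enough jointly valid samples is
  # dropped; at least half the runs must survive
  both_ok <- cause$mask & effect$mask
  valid_in_window <- vapply(seq_len(nrow(plan$windows)), function(i)
    sum(both_ok[plan$windows$start[i]:plan$windows$end[i]]), integer(1L))
  keep <- valid_in_window >= min_valid_run
  if (sum(keep) < ceiling(n_runs / 2))
    stop(sprintf(
      "only %d of %d runs have >= %d valid samples; decision requires at least %d",
      sum(keep), n_runs, as.integer(min_valid_run), ceiling(n_runs / 2)))
  plan$windows <- plan$windows[keep, , drop = FALSE]
  w <- plan$windows
  lags <- as.integer(lags)
  lag0 <- if (length(lags) == 1L) lags else 0L

  dim_sel <- NULL
  if (is.null(dimension)) {
    dim_sel <- select_dimension(cause, effect, plan, dim_range = dim_range,
                                delay = delay, lag = lag0,
                                n_samples = n_samples, sampling = sampling,
                                seed = seed)
    dimension <- dim_sel$selected
  }
  dimension <- as.integer(dimension)

  pools <- vapply(seq_len(nrow(w)), function(i)
    window_pool_size(cause$values, effect$values, dimension, delay, lag0,
                     w$start[i], w$end[i], plan$train_fraction), integer(1L))
  grid <- lib_size_grid(dimension, min(pools))
  if (is.null(grid)) grid <- min(pools)
  per_run <- matrix(NA_real_, nrow(w), length(grid))
  for (i in seq_len(nrow(w))) {
    cv <- try(window_curve(cause, effect, w$start[i], w$end[i], dimension,
                           delay, lag0, grid, n_samples, sampling,
                           plan$train_fraction, derive_seed(seed, i)),
              silent = TRUE)
    if (!inherits(cv, "try-error")) per_run[i, ] <- cv$skills
  }
  run_ok <- rowSums(is.na(per_run)) == 0L
  if (sum(run_ok) < ceiling(n_runs / 2))
    stop(sprintf("only %d of %d runs completed; decision requires at least %d",
                 sum(run_ok), n_runs, ceiling(n_runs / 2)))
  per_run <- per_run[run_ok, , drop = FALSE]
  w <- w[run_ok, , drop = FALSE]
  delta <- median_delta_curve(per_run)

  # lag scan at the selected dimension, full training library per window,
  # median skill per lag across windows
  per_run_lag <- matrix(NA_real_, nrow(w), length(lags))
  for (i in seq_len(nrow(w))) {
    cw <- ccm_series(cause$values[w$start[i]:w$end[i]], cause$step)
    ew <- ccm_series(effect$values[w$start[i]:w$end[i]], effect$step)
    ls <- try(lag_scan(cw, ew, dimension = dimension, delay = delay,
                       lags = lags, min_pairs = min_pairs,
                       train_fraction = plan$train_fraction),
              silent = TRUE)
    if (!inherits(ls, "try-error")) per_run_lag[i, ] <- ls$skill_at_lag
  }
  lag_med <- apply(per_run_lag, 2L, function(z)
    if (all(is.na(z))) NA_real_ else stats::median(z, na.rm = TRUE))
  if (all(is.na(lag_med)))
    stop("alignment error: every candidate lag infeasible in every window")
  opt <- pick_optimal_lag(lags, lag_med, lag_tol)
  optimal_lag <- opt$lag
  robust_skill <- stats::median(per_run_lag[, opt$index], na.rm = TRUE)

  accept <- accept_by_lag(optimal_lag)
  slope_ok <- length(delta) > 0 &&
    mean(delta[seq_len(ceiling(length(delta) / 2))]) > 0
  convergent <- isTRUE(slope_ok) && robust_skill >= skill_threshold

  structure(list(direction = labels,
                 robust_skill = robust_skill,
                 selected_dimension = dimension,
                 optimal_lag = optimal_lag,
                 accept = accept,
                 convergent = convergent,
                 median_delta_curve = delta,
                 per_run_skills = per_run,
                 library_sizes = grid,
                 lags = lags,
                 lag_skills = lag_med,
                 per_run_lag_skills = per_run_lag,
                 dimension_selection = dim_sel,
                 n_surviving_runs = nrow(w),
                 plan = plan,
                 skill_threshold = skill_threshold,
                 delay = delay,
                 seed = seed,
                 call = match.call()),
            class = "rccm")
}

#' @export
print.rccm <- function(x, ...) {
  dir <- if (!is.null(x$direction))
    paste(x$direction[1L], "->", x$direction[2L]) else "cause -> effect"
  cat(sprintf("Robust CCM decision (%s)\n", dir))
  cat(sprintf("  robust skill rho~ : %.3f\n", x$robust_skill))
  cat(sprintf("  embedding p       : %d\n", x$selected_dimension))
  cat(sprintf("  optimal lag t_p   : %d (%s)\n", x$optimal_lag,
              x$accept$status))
  cat(sprintf("  convergent        : %s (threshold %.2f, %d/%d runs)\n",
              x$convergent, x$skill_threshold, x$n_surviving_runs,
              x$plan$n_runs))
  invisible(x)
}

#' @export
summary.rccm <- function(object, ...) {
  structure(list(fit = object), class = "summary.rccm")
}

#' @export
print.summary.rccm <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  cat("\nPer-run terminal skills:\n")
  print(round(f$per_run_skills[, ncol(f$per_run_skills)], 3))
  cat("\nMedian one-step skill-difference curve:\n")
  print(round(f$median_delta_curve, 4))
  if (length(f$lags) > 1L) {
    cat("\nMedian skill by lag:\n")
    print(stats::setNames(round(f$lag_skills, 3), f$lags))
  }
  invisible(x)
}

#' Plot a robust CCM fit
#'
#' Left panel: per-run cross-map skill against library size with the
#' median overlaid. Right panel: median skill against candidate lag
#' (when more than one lag was scanned).
#'
#' @param x an `rccm` object.
#' @param ... passed to `matplot`.
#' @export
plot.rccm <- function(x, ...) {
  two <- length(x$lags) > 1L
  if (two) {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  graphics::matplot(x$library_sizes, t(x$per_run_skills), type = "l",
                    lty = 1, col = "grey70", xlab = "library size",
                    ylab = "cross-map skill", ...)
  graphics::lines(x$library_sizes, apply(x$per_run_skills, 2, stats::median),
                  lwd = 2)
  if (two) {
    graphics::plot(x$lags, x$lag_skills, type = "b", xlab = "lag t_p",
                   ylab = "median skill")
    graphics::abline(v = x$optimal_lag, lty = 2)
  }
  invisible(x)
}

#' Single-run (plain) CCM decision
#'
#' The non-robust baseline: one convergence curve on the full series
#' (first-third library, remainder tested); the direction is accepted
#' when the terminal skill reaches the threshold and the curve has risen
#' from its first to its last library size.
#'
#' @inheritParams ccm_curve
#' @param skill_threshold acceptance threshold on the terminal skill.
#' @return list with `accepted`, `terminal_skill`, and the `ccm_curve`.
#' @export
ccm_decide <- function(cause, effect, dimension = 2, delay = 1, lag = 0,
                       library_sizes = NULL, n_samples = 20,
                       sampling = "contiguous", train_fraction = 1 / 3,
                       skill_threshold = 0.8, seed = 1) {
  cv <- ccm_curve(cause, effect, dimension = dimension, delay = delay,
                  lag = lag, library_sizes = library_sizes,
                  n_samples = n_samples, sampling = sampling,
                  train_fraction = train_fraction, seed = seed)
  term <- terminal_skill(cv)
  rise <- term - cv$skills[1L]
  list(accepted = term >= skill_threshold && rise > 0,
       terminal_skill = term, curve = cv)
}

#' Serialize an RCCM (or masked) decision to JSON
#'
#' @param x an `rccm` or `masked_decision` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_decision_json <- function(x, path) {
  rec <- if (inherits(x, "masked_decision")) {
    r <- x$rccm
    list(direction = r$direction, robust_skill = r$robust_skill,
         dimension = r$selected_dimension, optimal_lag = r$optimal_lag,
         convergent = r$convergent, n_surviving_runs = r$n_surviving_runs,
         igci_score = x$igci$score, final = x$final, reason = x$reason)
  } else {
    list(direction = x$direction, robust_skill = x$robust_skill,
         dimension = x$selected_dimension, optimal_lag = x$optimal_lag,
         convergent = x$convergent, n_surviving_runs = x$n_surviving_runs)
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Per-run skill curves as a data frame (for CSV export)
#'
#' @param x an `rccm` object.
#' @param ... unused.
#' @return data frame with `run`, `library_size`, `skill`.
#' @export
as.data.frame.rccm <- function(x, ...) {
  data.frame(
    run = rep(seq_len(nrow(x$per_run_skills)), ncol(x$per_run_skills)),
    library_size = rep(x$library_sizes, each = nrow(x$per_run_skills)),
    skill = as.vector(x$per_run_skills))
}
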