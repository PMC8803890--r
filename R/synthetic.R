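# Generators for benchmark inputs: the coupled logistic map, planted-lag
# systems, and small planted-regime synthetic datacubes.

#' Coupled logistic map benchmark system
#'
#' Iterates the two-species coupled logistic map
#' \deqn{x_{t+1} = x_t (r_x (1 - x_t) - \beta_{xy} y_t)}
#' \deqn{y_{t+1} = y_t (r_y (1 - y_t) - \beta_{yx} x_t)}
#' where `beta_yx` is the forcing of X on Y (X -> Y when positive).
#' After a burn-in the emitted copies receive independent Gaussian
#' observation noise; the latent dynamics stay noise-free, so a
#' noise-free cause with a noisy effect leaves the attractor intact.
#'
#' With the benchmark defaults r_x = 3.8 (chaotic) and r_y = 3.5, Y sits
#' on a period-4 attractor when uncoupled and becomes increasingly
#' chaotic as `beta_yx` grows.
#'
#' @param n_samples emitted series length (default 1000).
#' @param r_x,r_y growth rates, in (0, 4].
#' @param beta_xy forcing of Y on X (default 0: unidirectional X -> Y).
#' @param beta_yx forcing of X on Y.
#' @param sigma_x,sigma_y observation-noise standard deviations.
#' @param burn_in discarded initial iterations (default 300).
#' @param x0,y0 initial states in (0, 1); default drawn uniformly from
#'   (0.2, 0.8) under `seed`.
#' @param seed integer seed (initial conditions and observation noise).
#' @return list with `x`, `y` (`ccm_series`), the latent `x_latent`,
#'   `y_latent`, and `params`.
#' @examples
#' s <- coupled_logistic_map(n_samples = 500, beta_yx = 0.1, seed = 1)
#' plot(s$x$values[1:100], type = "l")
#' @export
coupled_logistic_map <- function(n_samples = 1000, r_x = 3.8, r_y = 3.5,
                                 beta_xy = 0, beta_yx = 0.1,
                                 sigma_x = 0, sigma_y = 0,
                                 burn_in = 300, x0 = NULL, y0 = NULL,
                                 seed = 1) {
  stopifnot(r_x > 0, r_x <= 4, r_y > 0, r_y <= 4,
            beta_xy >= 0, beta_yx >= 0, sigma_x >= 0, sigma_y >= 0,
            burn_in >= 0, n_samples >= 1)
  with_seed(seed, {
    if (is.null(x0)) x0 <- stats::runif(1, 0.2, 0.8)
    if (is.null(y0)) y0 <- stats::runif(1, 0.2, 0.8)
    if (x0 < 0 || x0 > 1 || y0 < 0 || y0 > 1)
      stop("initial conditions must lie in [0, 1]")
    ntot <- n_samples + burn_in
    x <- numeric(ntot + 1L); y <- numeric(ntot + 1L)
    x[1L] <- x0; y[1L] <- y0
    for (t in seq_len(ntot)) {
      x[t + 1L] <- x[t] * (r_x * (1 - x[t]) - beta_xy * y[t])
      y[t + 1L] <- y[t] * (r_y * (1 - y[t]) - beta_yx * x[t])
      if (x[t + 1L] < 0 || x[t + 1L] > 1 || y[t + 1L] < 0 || y[t + 1L] > 1)
        stop(sprintf(
          "trajectory escaped [0, 1] at step %d; reduce couplings or growth rates",
          t))
    }
    xe <- x[(burn_in + 1L):(burn_in + n_samples)]
    ye <- y[(burn_in + 1L):(burn_in + n_samples)]
    xo <- xe + if (sigma_x > 0) stats::rnorm(n_samples, 0, sigma_x) else 0
    yo <- ye + if (sigma_y > 0) stats::rnorm(n_samples, 0, sigma_y) else 0
    list(x = ccm_series(xo), y = ccm_series(yo),
         x_latent = xe, y_latent = ye,
         params = list(r_x = r_x, r_y = r_y, beta_xy = beta_xy,
                       beta_yx = beta_yx, sigma_x = sigma_x,
                       sigma_y = sigma_y, n_samples = n_samples,
                       burn_in = burn_in, x0 = x0, y0 = y0, seed = seed))
  })
}

#' Planted-lag driver-response system
#'
#' Generates a chaotic logistic driver X and a response
#' Y(t) = g(X(t - d)) + noise with a fixed smooth monotone map g
#' (default the square on \[0, 1\]). The ground-truth optimal cross-map
#' lag for X -> Y is -d under the convention that negative lags mean
#' the cause precedes the effect.
#'
#' @param n emitted length of both series.
#' @param d planted delay in samples (>= 0).
#' @param sigma observation-noise sd added to Y.
#' @param g monotone response map.
#' @param r driver growth rate.
#' @param burn_in discarded initial iterations.
#' @param seed integer seed.
#' @return list with `x`, `y` (`ccm_series`), `d` and `g`.
#' @export
planted_lag_system <- function(n = 500, d = 3, sigma = 0,
                               g = function(v) v^2, r = 3.8,
                               burn_in = 300, seed = 1) {
  d <- as.integer(d)
  stopifnot(d >= 0, sigma >= 0)
  if (d >= n) stop("planted delay d must be smaller than n")
  with_seed(seed, {
    x0 <- stats::runif(1, 0.2, 0.8)
    ntot <- n + d + burn_in
    x <- numeric(ntot)
    x[1L] <- x0
    for (t in seq_len(ntot - 1L))
      x[t + 1L] <- r * x[t] * (1 - x[t])
    xs <- x[(burn_in + 1L):ntot]          # length n + d
    xe <- xs[(d + 1L):(d + n)]            # emitted driver
    ye <- g(xs[1:n])                      # y(t) = g(x(t - d))
    if (sigma > 0) ye <- ye + stats::rnorm(n, 0, sigma)
    list(x = ccm_series(xe), y = ccm_series(ye), d = d, g = g,
         params = list(n = n, d = d, sigma = sigma, r = r, seed = seed))
  })
}

# Planted causal regimes for the synthetic datacube.
cube_regimes <- c("independent", "a_drives_b", "b_drives_a", "bidirectional")

#' Planted-regime synthetic datacube
#'
#' Builds a small gridded dataset (two variables A and B on a
#' lat x lon x time grid, regular step) in which each pixel's pair is
#' simulated from one of four planted causal regimes: `independent`,
#' `a_drives_b`, `b_drives_a`, `bidirectional`. The coupled logistic map
#' provides the dynamics and a pixel-phase seasonal sinusoid (period =
#' `samples_per_year`) is added to both variables to mimic flux
#' periodicity; the ground truth is recorded in `regime_map`.
#'
#' @param n_lat,n_lon grid shape (kept small, <= 32 x 32).
#' @param n_years,samples_per_year temporal extent; the default 11 x 46
#'   mirrors an 8-day, 11-year record (506 steps).
#' @param layout either the string `"quadrants"` (the four regimes in
#'   the four grid quadrants) or a character matrix of regime labels.
#' @param coupling logistic coupling strength for unidirectional
#'   regimes.
#' @param coupling_bidir coupling used in each direction of the
#'   bidirectional regime.
#' @param seasonal_amplitude amplitude of the added seasonal sinusoid
#'   (series units; the chaotic signal has sd of roughly 0.2).
#' @param sigma observation-noise sd added to both variables.
#' @param missing_frac fraction of time steps blanked out (as a
#'   contiguous stripe) in every pixel, to exercise gap handling.
#' @param seed master seed; per-pixel seeds are derived from it and the
#'   pixel coordinates, so any pixel can be regenerated alone.
#' @return object of class `rccm_cube`: `variables` (named list of
#'   lat x lon x time arrays), `regime_map` (character matrix),
#'   `samples_per_year`, `step_days`, `n_time`.
#' @export
synthetic_datacube <- function(n_lat = 8, n_lon = 8, n_years = 11,
                               samples_per_year = 46,
                               layout = "quadrants",
                               coupling = 0.15, coupling_bidir = 0.2,
                               seasonal_amplitude = 0.05, sigma = 0,
                               missing_frac = 0, seed = 1) {
  if (n_lat > 32 || n_lon > 32)
    stop("synthetic cubes are desk-scale: grid must be at most 32 x 32")
  n_time <- n_years * samples_per_year
  if (is.character(layout) && length(layout) == 1L &&
      layout == "quadrants") {
    regime_map <- matrix("", n_lat, n_lon)
    hi <- ceiling(n_lat / 2); hj <- ceiling(n_lon / 2)
    regime_map[seq_len(hi), seq_len(hj)] <- "a_drives_b"
    regime_map[seq_len(hi), (hj + 1):n_lon] <- "b_drives_a"
    regime_map[(hi + 1):n_lat, seq_len(hj)] <- "bidirectional"
    regime_map[(hi + 1):n_lat, (hj + 1):n_lon] <- "independent"
  } else {
    regime_map <- matrix(as.character(layout), n_lat, n_lon)
  }
  bad <- setdiff(unique(as.vector(regime_map)), cube_regimes)
  if (length(bad) > 0L)
    stop(sprintf("unknown regime label(s): %s (known: %s)",
                 paste(bad, collapse = ", "),
                 paste(cube_regimes, collapse = ", ")))
  A <- array(NA_real_, c(n_lat, n_lon, n_time))
  B <- array(NA_real_, c(n_lat, n_lon, n_time))
  tt <- seq_len(n_time)
  for (i in seq_len(n_lat)) {
    for (j in seq_len(n_lon)) {
      px_seed <- derive_seed(seed, (i - 1L) * n_lon + j)
      reg <- regime_map[i, j]
      # Unidirectional pixels pair a chaotic driver (r = 3.8) with a
      # damped responder (r = 3.2) whose dynamics are dominated by the
      # forcing; a near-periodic driver would have no signature to
      # cross-map, so for b_drives_a the two roles are swapped.
      # Bidirectional pixels couple two identical chaotic maps
      # symmetrically, so the pair synchronises with matching marginal
      # distributions (no spurious entropy asymmetry).
      s <- switch(reg,
        a_drives_b = ,
        b_drives_a = coupled_logistic_map(n_samples = n_time,
                                          r_y = 3.2,
                                          beta_yx = coupling,
                                          sigma_x = sigma, sigma_y = sigma,
                                          seed = px_seed),
        bidirectional = coupled_logistic_map(n_samples = n_time,
                                             r_y = 3.8,
                                             beta_yx = coupling_bidir,
                                             beta_xy = coupling_bidir,
                                             sigma_x = sigma,
                                             sigma_y = sigma,
                                             seed = px_seed),
        independent = coupled_logistic_map(n_samples = n_time,
                                           beta_yx = 0,
                                           sigma_x = sigma, sigma_y = sigma,
                                           seed = px_seed))
      if (reg == "b_drives_a") {
        tmp <- s$x; s$x <- s$y; s$y <- tmp
      }
      phase <- with_seed(derive_seed(px_seed, 1L),
                         stats::runif(1, 0, 2 * pi))
      season <- seasonal_amplitude *
        sin(2 * pi * tt / samples_per_year + phase)
      a <- s$x$values + season
      b <- s$y$values + season
      if (missing_frac > 0) {
        nmiss <- floor(missing_frac * n_time)
        if (nmiss > 0) {
          at <- with_seed(derive_seed(px_seed, 2L),
                          sample.int(n_time - nmiss, 1L))
          a[at:(at + nmiss - 1L)] <- NA
          b[at:(at + nmiss - 1L)] <- NA
        }
      }
      A[i, j, ] <- a
      B[i, j, ] <- b
    }
  }
  structure(list(variables = list(A = A, B = B),
                 regime_map = regime_map,
                 samples_per_year = samples_per_year,
                 step_days = 8, n_time = n_time,
                 params = list(coupling = coupling,
                               coupling_bidir = coupling_bidir,
                               seasonal_amplitude = seasonal_amplitude,
                               sigma = sigma, missing_frac = missing_frac,
                               seed = seed)),
            class = "rccm_cube")
}

#' @export
print.rccm_cube <- function(x, ...) {
  d <- dim(x$variables[[1L]])
  cat(sprintf("<rccm_cube> %s: %d x %d pixels, %d time steps (%d/yr)\n",
              paste(names(x$variables), collapse = ", "),
              d[1L], d[2L], d[3L], x$samples_per_year))
  invisible(x)
}

#' Write a datacube as plain text (long CSV + JSON header)
#'
#' Serializes the cube's variable x lat x lon x time layout to a
#' long-format CSV (`<base>.csv`, columns variable, lat, lon, time,
#' value; missing values as empty fields) plus a JSON metadata header
#' (`<base>.json`: dimensions, sampling, regime vocabulary and map).
#'
#' @param cube an `rccm_cube`.
#' @param base output path without extension.
#' @return `base`, invisibly.
#' @export
write_cube <- function(cube, base) {
  d <- dim(cube$variables[[1L]])
  rows <- do.call(rbind, lapply(names(cube$variables), function(v) {
    a <- cube$variables[[v]]
    data.frame(variable = v,
               lat = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
               lon = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
               time = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
               value = as.vector(a))
  }))
  utils::write.csv(rows, paste0(base, ".csv"), row.names = FALSE, na = "")
  meta <- list(variables = names(cube$variables),
               n_lat = d[1L], n_lon = d[2L], n_time = d[3L],
               samples_per_year = cube$samples_per_year,
               step_days = cube$step_days,
               regime_levels = cube_regimes,
               regime_map = if (!is.null(cube$regime_map))
                 as.vector(cube$regime_map)  # column-major
               else NULL)
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(base)
}

#' Read a datacube written by [write_cube()]
#'
#' @param base path without extension.
#' @return an `rccm_cube`.
#' @export
read_cube <- function(base) {
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  rows <- utils::read.csv(paste0(base, ".csv"),
                          na.strings = c("", "NA", "NaN"))
  vars <- lapply(meta$variables, function(v) {
    a <- array(NA_real_, c(meta$n_lat, meta$n_lon, meta$n_time))
    r <- rows[rows$variable == v, ]
    a[cbind(r$lat, r$lon, r$time)] <- r$value
    a
  })
  names(vars) <- meta$variables
  regime_map <- NULL
  if (!is.null(meta$regime_map))
    regime_map <- matrix(unlist(meta$regime_map), meta$n_lat, meta$n_lon)
  structure(list(variables = vars, regime_map = regime_map,
                 samples_per_year = meta$samples_per_year,
                 step_days = meta$step_days, n_time = meta$n_time),
            class = "rccm_cube")
}
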