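test_that("logistic recursions match hand iteration", {
  s <- coupled_logistic_map(n_samples = 3, r_x = 3.8, r_y = 3.5,
                            beta_xy = 0, beta_yx = 0, burn_in = 0,
                            x0 = 0.4, y0 = 0.4, seed = 1)
  # x1 = 0.4 * (3.8 * 0.6) = 0.912; x2 = 0.912 * (3.8 * 0.088)
  expect_equal(s$x$values, c(0.4, 0.912, 0.912 * 3.8 * 0.088))
  expect_equal(s$x$values[3], 0.3049728, tolerance = 1e-7)

  s2 <- coupled_logistic_map(n_samples = 2, r_x = 3.8, r_y = 3.5,
                             beta_xy = 0, beta_yx = 0.1, burn_in = 0,
                             x0 = 0.4, y0 = 0.4, seed = 1)
  # y1 = 0.4 * (3.5 * 0.6 - 0.1 * 0.4) = 0.824
  expect_equal(s2$y$values[2], 0.824)
})

test_that("generator is reproducible, bounded, and flags divergence", {
  a <- coupled_logistic_map(n_samples = 400, beta_yx = 0.1,
                            sigma_y = 0.02, seed = 99)
  b <- coupled_logistic_map(n_samples = 400, beta_yx = 0.1,
                            sigma_y = 0.02, seed = 99)
  expect_identical(a$x$values, b$x$values)
  expect_identical(a$y$values, b$y$values)

  # zero everything: the origin is a fixed point
  z <- coupled_logistic_map(n_samples = 50, beta_yx = 0, burn_in = 0,
                            x0 = 0, y0 = 0.5, seed = 1)
  expect_true(all(z$x$values == 0))

  # benchmark defaults stay on the attractor for a long horizon
  long <- coupled_logistic_map(n_samples = 1e5, beta_yx = 0.15, seed = 7)
  expect_true(all(long$x_latent >= 0 & long$x_latent <= 1))
  expect_true(all(long$y_latent >= 0 & long$y_latent <= 1))

  # escaping trajectories raise a divergence error naming the step
  expect_error(coupled_logistic_map(n_samples = 100, r_y = 3.5,
                                    beta_yx = 2.5, burn_in = 0,
                                    x0 = 0.9, y0 = 0.9, seed = 1),
               "escaped .* at step")

  expect_error(coupled_logistic_map(n_samples = 10, r_x = 4.5),
               "r_x")
})

test_that("planted-lag system plants exactly the advertised delay", {
  p0 <- planted_lag_system(n = 100, d = 0, sigma = 0, g = identity,
                           seed = 2)
  expect_identical(p0$x$values, p0$y$values)

  p <- planted_lag_system(n = 200, d = 4, sigma = 0, seed = 3)
  expect_equal(p$y$values[5:200], p$x$values[1:196]^2)
  expect_error(planted_lag_system(n = 10, d = 10), "smaller than n")
})

test_that("synthetic datacube plants regimes on the advertised grid", {
  cube <- synthetic_datacube(n_lat = 4, n_lon = 4, n_years = 3,
                             samples_per_year = 20, seed = 5)
  expect_equal(dim(cube$variables$A), c(4L, 4L, 60L))
  expect_equal(sort(unique(as.vector(cube$regime_map))),
               sort(c("a_drives_b", "b_drives_a", "bidirectional",
                      "independent")))
  # 11 x 46 default matches the 8-day 11-year record length
  expect_equal(synthetic_datacube(n_lat = 2, n_lon = 2,
                                  seed = 1)$n_time, 506L)

  expect_error(synthetic_datacube(n_lat = 2, n_lon = 2, n_years = 1,
                                  samples_per_year = 10,
                                  layout = matrix("nonsense", 2, 2)),
               "unknown regime")

  # reproducibility: same seed, same cube
  c2 <- synthetic_datacube(n_lat = 4, n_lon = 4, n_years = 3,
                           samples_per_year = 20, seed = 5)
  expect_identical(cube$variables, c2$variables)

  # missing stripes blank out the stated fraction
  cm <- synthetic_datacube(n_lat = 2, n_lon = 2, n_years = 3,
                           samples_per_year = 20, missing_frac = 0.1,
                           seed = 5)
  expect_equal(sum(is.na(cm$variables$A[1, 1, ])), 6L)
})

test_that("cube text serialization round-trips", {
  cube <- synthetic_datacube(n_lat = 3, n_lon = 2, n_years = 2,
                             samples_per_year = 12,
                             missing_frac = 0.1, seed = 8)
  base <- tempfile()
  write_cube(cube, base)
  back <- read_cube(base)
  expect_equal(back$variables, cube$variables)
  expect_equal(back$regime_map, cube$regime_map)
  expect_equal(back$samples_per_year, cube$samples_per_year)
})
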