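test_that("delay embedding produces all complete lagged vectors", {
  m <- delay_embed(c(1, 2, 3, 4, 5), dimension = 2, delay = 1)
  expect_equal(nrow(m$points), 4L)  # L - (E-1) tau
  expect_equal(m$points,
               matrix(c(2, 1, 3, 2, 4, 3, 5, 4), 4, 2, byrow = TRUE))
  expect_equal(m$point_times, 2:5)

  # E = 1 is the series itself
  m1 <- delay_embed(c(3, 1, 4, 1, 5), dimension = 1)
  expect_equal(as.vector(m1$points), c(3, 1, 4, 1, 5))

  # E = 3, tau = 2, enumerated by hand
  m2 <- delay_embed(1:6, dimension = 3, delay = 2)
  expect_equal(m2$points, matrix(c(5, 3, 1, 6, 4, 2), 2, 3, byrow = TRUE))

  # matches the enumeration oracle on random configurations
  set.seed(42)
  for (rep in 1:10) {
    v <- rnorm(sample(20:60, 1))
    E <- sample(1:4, 1); tau <- sample(1:3, 1)
    m <- delay_embed(v, E, tau)
    expect_equal(m$points, embed_oracle(v, E, tau), ignore_attr = TRUE)
    expect_equal(nrow(m$points), length(v) - (E - 1) * tau)
  }
})

test_that("embedding drops vectors spanning masked samples and errors on short input", {
  v <- c(1, 2, NA, 4, 5, 6)
  m <- delay_embed(v, dimension = 2, delay = 1)
  # vectors at t = 3 and t = 4 span the NA
  expect_equal(m$point_times, c(2L, 5L, 6L))
  expect_error(delay_embed(1:3, dimension = 4, delay = 2),
               "need at least 7 samples")
  expect_error(delay_embed(c(1, NA, 3), dimension = 3, delay = 1),
               "valid consecutive")
})

test_that("simplex prediction matches the exhaustive brute-force oracle", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(50:400, 1)
    E <- sample(1:5, 1)
    s <- coupled_logistic_map(n_samples = n + 20, beta_yx = 0.1,
                              seed = rep)
    man <- delay_embed(s$y, dimension = E)
    npts <- nrow(man$points)
    lib <- sort(sample(npts, sample((E + 2):npts, 1)))
    res <- simplex_cross_map(s$x, man, lag = 0, library_indices = lib)
    y <- rep(NA_real_, npts)
    y[man$point_times <= length(s$x$values)] <-
      s$x$values[man$point_times]
    oracle <- simplex_oracle(man$points, y, lib, seq_len(npts), E + 1)
    expect_equal(res$predicted, oracle, tolerance = 1e-10)
  }
})

test_that("simplex self-map reproduces the target and white noise does not", {
  s <- coupled_logistic_map(n_samples = 500, beta_yx = 0, seed = 3)
  man <- delay_embed(s$x, dimension = 2)
  res <- simplex_cross_map(s$x, man, lag = 0)
  expect_gt(cross_map_skill(res), 0.99)

  set.seed(4)
  noise <- ccm_series(rnorm(500))
  res2 <- simplex_cross_map(noise, man, lag = 0)
  expect_lt(abs(cross_map_skill(res2)), 0.2)
})

test_that("simplex errors on insufficient library and empty overlap", {
  man <- delay_embed(1:30, dimension = 2)
  expect_error(simplex_cross_map(ccm_series(1:30), man,
                                 library_indices = 1:3),
               "insufficient library")
  expect_error(simplex_cross_map(ccm_series(1:30), man, lag = 1000),
               "alignment error")
})

test_that("cross-map skill is a guarded Pearson correlation", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(cross_map_skill(x, x), 1)
  expect_equal(cross_map_skill(x, -x), -1)
  expect_equal(cross_map_skill(rep(1, 5), x), 0)   # degenerate variance
  expect_error(cross_map_skill(1:2, 2:3), "at least 3")

  # symmetry and affine invariance (up to slope sign)
  set.seed(1)
  a <- rnorm(50); b <- rnorm(50) + 0.5 * a
  expect_equal(cross_map_skill(a, b), cross_map_skill(b, a))
  expect_equal(cross_map_skill(2.5 * a - 1, b), cross_map_skill(a, b))
  expect_equal(cross_map_skill(-a, b), -cross_map_skill(a, b))
})

test_that("series container validates and round-trips through CSV", {
  s <- ccm_series(c(1.5, NA, 3), step = 8)
  expect_equal(s$mask, c(TRUE, FALSE, TRUE))
  expect_error(ccm_series(numeric(0)), "at least one")
  expect_error(ccm_series(1:3, step = -1), "positive")
  path <- tempfile(fileext = ".csv")
  write_series_csv(s, path)
  s2 <- read_series_csv(path)
  expect_equal(s2$values, s$values)
  expect_equal(s2$step, 8)
})
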