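test_that("window planning follows the whole-year bootstrap rule", {
  # 11 years at 46 samples/year, 400-sample minimum: 9-year windows of
  # 414 samples whose starts span the remaining 2 years
  plan <- plan_windows(506, 46, n_runs = 10, min_valid_run = 400)
  expect_equal(plan$n_runs, 10L)
  expect_equal(plan$window_length, 414L)
  expect_equal(plan$window_years, 9L)
  expect_equal(nrow(plan$windows), 10L)
  expect_true(all(plan$windows$end - plan$windows$start + 1L == 414L))
  expect_equal(min(plan$windows$start), 1L)
  expect_equal(max(plan$windows$start), 93L)  # offsets span 2 years
  expect_true(all(diff(plan$windows$start) > 0))

  # degenerate plan: series exactly the minimum, one run
  p1 <- plan_windows(400, 100, n_runs = 1, min_valid_run = 400)
  expect_equal(p1$windows, data.frame(start = 1L, end = 400L))

  # cannot fit: explicit error naming the deficit
  expect_error(plan_windows(300, 100, n_runs = 2, min_valid_run = 400),
               "100 short")
})

test_that("train/test split takes the first third for the library", {
  s <- split_train_test(414)
  expect_equal(s$train, c(1L, 138L))
  expect_equal(s$test, c(139L, 414L))
  expect_equal(split_train_test(300)$train, c(1L, 100L))
  expect_equal(split_train_test(300)$test, c(101L, 300L))
  s3 <- split_train_test(3)
  expect_equal(s3$train, c(1L, 1L))
  expect_equal(s3$test, c(2L, 3L))
  expect_error(split_train_test(2), "at least 3")
  # windows offset into the series keep absolute coordinates
  sw <- split_train_test(c(101, 514))
  expect_equal(sw$train, c(101L, 238L))
})

test_that("median delta curve is the element-wise median of one-step differences", {
  expect_equal(median_delta_curve(matrix(c(0.2, 0.5, 0.6), 1)),
               c(0.3, 0.1))
  m <- rbind(c(0, 0.3, 0.4), c(0, 0.1, 0.1), c(0, 0.2, 0.4))
  expect_equal(median_delta_curve(m), c(0.2, 0.1))
  expect_equal(median_delta_curve(matrix(0.7, 3, 4)), rep(0, 3))
  flagged <- median_delta_curve(matrix(c(0.1, 0.2), 2, 1))
  expect_length(flagged, 0L)
  expect_true(attr(flagged, "flagged"))
})

test_that("dimension selection returns the forced choice and breaks ties low", {
  s <- coupled_logistic_map(n_samples = 506, beta_yx = 0.15, seed = 3)
  plan <- plan_windows(506, 46, 10, 400)
  one <- select_dimension(s$x, s$y, plan, dim_range = 4, seed = 1)
  expect_equal(one$selected, 4L)

  # white-noise pair: flat, near-zero skills; the parsimony rule keeps
  # the selection at the low end (chance skill does not grow with p)
  set.seed(8)
  wn <- select_dimension(rnorm(506), rnorm(506), plan, dim_range = 1:4,
                         n_samples = 5, seed = 1)
  expect_lte(wn$selected, 2L)
  expect_lt(max(abs(wn$median_skills), na.rm = TRUE), 0.25)

  # exact ties resolve to the smallest dimension: identical series give
  # identical (perfect) skill at every dimension
  s2 <- coupled_logistic_map(n_samples = 506, beta_yx = 0, seed = 9)
  tie <- select_dimension(s2$x, s2$x, plan, dim_range = 2:4,
                          n_samples = 5, seed = 1)
  expect_equal(tie$selected, 2L)
})

test_that("dimension selection finds a low dimension for the 2-D logistic system", {
  hits <- vapply(1:10, function(sd) {
    s <- coupled_logistic_map(n_samples = 700, beta_yx = 0.15, seed = sd)
    plan <- plan_windows(700, 70, 10, 560)
    sel <- select_dimension(s$x, s$y, plan, dim_range = 1:6,
                            n_samples = 10, seed = sd)
    sel$selected
  }, integer(1L))
  expect_gte(mean(hits %in% 2:3), 0.9)
})

test_that("rccm decisions are deterministic and median-bounded", {
  s <- coupled_logistic_map(n_samples = 600, beta_yx = 0.15,
                            sigma_y = 0.01, seed = 21)
  f1 <- rccm(s$x, s$y, year_length = 60, min_valid_run = 480,
             dimension = 2, lags = -3:3, seed = 5)
  f2 <- rccm(s$x, s$y, year_length = 60, min_valid_run = 480,
             dimension = 2, lags = -3:3, seed = 5)
  expect_identical(f1[setdiff(names(f1), "call")],
                   f2[setdiff(names(f2), "call")])

  # rho-tilde lies between the per-run extremes at the optimal lag
  col <- which(f1$lags == f1$optimal_lag)
  runs <- f1$per_run_lag_skills[, col]
  expect_gte(f1$robust_skill, min(runs, na.rm = TRUE))
  expect_lte(f1$robust_skill, max(runs, na.rm = TRUE))
})

test_that("rccm detects the true direction of the noise-free logistic pair", {
  s <- coupled_logistic_map(n_samples = 1000, beta_yx = 0.1, seed = 2)
  fit <- rccm(s$x, s$y, year_length = 100, min_valid_run = 800,
              dimension = 2, lags = -5:5, skill_threshold = 0.8,
              seed = 1)
  expect_true(fit$convergent)
  expect_gt(fit$robust_skill, 0.8)
  expect_lte(fit$optimal_lag, 0L)
  rev <- rccm(s$y, s$x, year_length = 100, min_valid_run = 800,
              dimension = 2, lags = -5:5, skill_threshold = 0.8,
              seed = 1)
  expect_lt(rev$robust_skill, fit$robust_skill)
  expect_false(rev$convergent)
})

test_that("identical copies give near-perfect instantaneous links in both directions", {
  s <- coupled_logistic_map(n_samples = 600, beta_yx = 0, seed = 13)
  # at E = 1 the copy is reconstructed exactly at lag 0
  fit <- rccm(s$x, s$x, year_length = 60, min_valid_run = 480,
              dimension = 1, lags = -3:3, skill_threshold = 0.8, seed = 2)
  expect_true(fit$convergent)
  expect_gt(fit$robust_skill, 0.99)
  expect_equal(fit$optimal_lag, 0L)
  expect_equal(fit$accept$status, "accepted_instantaneous")
  # at E = 2 an extra exact coordinate can pull the alignment one step
  # back (deterministic-copy caveat); the link is still accepted
  fit2 <- rccm(s$x, s$x, year_length = 60, min_valid_run = 480,
               dimension = 2, lags = -3:3, skill_threshold = 0.8, seed = 2)
  expect_true(fit2$convergent)
  expect_gt(fit2$robust_skill, 0.99)
  expect_true(fit2$optimal_lag %in% c(-1L, 0L))
  expect_true(fit2$accept$accepted)
})

test_that("runs with too many gaps are dropped and the decision fails below quorum", {
  s <- coupled_logistic_map(n_samples = 600, beta_yx = 0.15, seed = 4)
  v <- s$x$values
  v[50:500] <- NA  # almost everything invalid
  expect_error(rccm(v, s$y$values, year_length = 60, min_valid_run = 480,
                    dimension = 2, lags = 0L, seed = 1),
               "requires at least")
})

test_that("windowed robust skill is steadier under sparse observation noise than one run", {
  # perturb 10% of samples with sigma = 0.05 observation noise and
  # compare the decision-score shift of RCCM against plain CCM
  d_rccm <- c(); d_ccm <- c()
  for (sd in 1:50) {
    s <- coupled_logistic_map(n_samples = 700, beta_yx = 0.15, seed = sd)
    set.seed(sd + 500)
    idx <- sample(700, 70)
    xn <- s$x$values; xn[idx] <- xn[idx] + rnorm(70, 0, 0.05)
    yn <- s$y$values; yn[idx] <- yn[idx] + rnorm(70, 0, 0.05)
    base_r <- rccm(s$x, s$y, year_length = 70, min_valid_run = 560,
                   dimension = 2, lags = 0L, n_samples = 10, seed = sd)
    pert_r <- rccm(xn, yn, year_length = 70, min_valid_run = 560,
                   dimension = 2, lags = 0L, n_samples = 10, seed = sd)
    base_c <- ccm_decide(s$x, s$y, dimension = 2, n_samples = 10,
                         seed = sd)
    pert_c <- ccm_decide(xn, yn, dimension = 2, n_samples = 10, seed = sd)
    d_rccm <- c(d_rccm, abs(base_r$robust_skill - pert_r$robust_skill))
    d_ccm <- c(d_ccm, abs(base_c$terminal_skill - pert_c$terminal_skill))
  }
  expect_lte(median(d_rccm), median(d_ccm))
})
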