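test_that("dominance classification follows the high/low thresholds", {
  s1 <- matrix(c(0.95, 0.95, 0.50, NA), 2, 2)
  s2 <- matrix(c(0.30, 0.95, 0.50, 0.2), 2, 2)
  d <- dominance_map(s1, s2, high = 0.9, low = 0.4)
  expect_equal(d[1, 1], "driver1")
  expect_equal(d[2, 1], "joint")
  expect_equal(d[1, 2], "none")
  expect_equal(d[2, 2], "masked")
  expect_error(dominance_map(s1, s2, high = 0.4, low = 0.9),
               "high > low")
  expect_error(dominance_map(s1, matrix(0, 3, 3)), "aligned")
})

test_that("skill-difference map is exactly antisymmetric and propagates NA", {
  a <- matrix(c(0.9, 0.2, NA, 0.5), 2, 2)
  b <- matrix(c(0.1, 0.2, 0.3, 0.9), 2, 2)
  expect_equal(skill_difference_map(a, a), matrix(c(0, 0, NA, 0), 2, 2))
  expect_equal(skill_difference_map(a, b), -skill_difference_map(b, a))
  expect_true(is.na(skill_difference_map(a, b)[1, 2]))
})

test_that("stratified summaries reduce to the global summary for one stratum", {
  set.seed(2)
  m <- matrix(runif(36), 6, 6)
  one <- stratified_summary(m, matrix(1L, 6, 6))
  expect_equal(one$summary$n, 36L)
  expect_equal(one$summary$median, median(m))
  expect_equal(one$summary$q25, unname(quantile(m, 0.25)))

  # constant stratum: median and quartiles coincide
  strata <- matrix(rep(1:2, each = 18), 6, 6)
  m[strata == 2] <- 0.7
  two <- stratified_summary(m, strata)
  r2 <- two$summary[two$summary$stratum == "2", ]
  expect_equal(r2$median, 0.7)
  expect_equal(r2$q25, 0.7)
  expect_equal(r2$q75, 0.7)

  # empty stratum reported with n = 0
  m2 <- matrix(NA_real_, 2, 2)
  e <- stratified_summary(m2, matrix(1L, 2, 2))
  expect_equal(e$summary$n, 0L)
})

test_that("a full pixel mask skips every pixel with the mask reason", {
  cube <- synthetic_datacube(n_lat = 2, n_lon = 2, n_years = 2,
                             samples_per_year = 10, seed = 1)
  g <- run_pair(cube, mask = matrix(FALSE, 2, 2), min_valid = 10,
                seed = 1)
  expect_true(all(g$skipped == "masked"))
  expect_true(all(g$label == "skipped"))
})

test_that("pixels below the data minimum are skipped, never errored", {
  cube <- synthetic_datacube(n_lat = 2, n_lon = 2, n_years = 2,
                             samples_per_year = 10, seed = 1)
  g <- run_pair(cube, min_valid = 400, seed = 1)  # only 20 samples
  expect_true(all(g$skipped == "insufficient data"))
  # every input pixel is accounted for
  expect_equal(sum(g$label != "skipped") + sum(!is.na(g$skipped)), 4L)
  expect_error(run_pair(cube, var_a = "Z"), "not present")
})

test_that("pixel results are independent of which other pixels run", {
  cube <- synthetic_datacube(n_lat = 2, n_lon = 2, n_years = 6,
                             samples_per_year = 20, seed = 4)
  cfg <- list(min_valid = 100, dimension = 2, lags = -2:2, n_samples = 5)
  full <- run_pair(cube, min_valid = 100, dimension = 2, lags = -2:2,
                   n_samples = 5, seed = 9)
  only <- matrix(FALSE, 2, 2); only[2, 1] <- TRUE
  alone <- run_pair(cube, mask = only, min_valid = 100, dimension = 2,
                    lags = -2:2, n_samples = 5, seed = 9)
  expect_equal(alone$skill_ab[2, 1], full$skill_ab[2, 1])
  expect_equal(alone$skill_ba[2, 1], full$skill_ba[2, 1])
  expect_equal(alone$lag_ab[2, 1], full$lag_ab[2, 1])
  expect_equal(alone$label[2, 1], full$label[2, 1])
})

test_that("decision records serialize to JSON with the advertised fields", {
  s <- coupled_logistic_map(n_samples = 400, beta_yx = 0.15, seed = 6)
  fit <- rccm(s$x, s$y, year_length = 40, min_valid_run = 320,
              dimension = 2, lags = -2:2, seed = 1,
              labels = c("X", "Y"))
  path <- tempfile(fileext = ".json")
  write_decision_json(fit, path)
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rec$direction, c("X", "Y"))
  expect_equal(rec$optimal_lag, fit$optimal_lag)
  expect_equal(rec$robust_skill, fit$robust_skill)

  m <- mask_rccm(fit, igci(s$x, s$y, labels = c("X", "Y")))
  write_decision_json(m, path)
  rec2 <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_true(rec2$final %in% c("kept", "masked", "rejected_by_lag"))

  # per-run curves export as tidy rows
  df <- as.data.frame(fit)
  expect_equal(nrow(df),
               nrow(fit$per_run_skills) * ncol(fit$per_run_skills))
})
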