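test_that("fit controls validate and carry the documented defaults", {
  fc <- fit_controls()
  expect_equal(fc$max_outer_iter, 1000)
  expect_equal(fc$max_inner_iter, 200)
  expect_equal(fc$step_tol, 1e-1)
  expect_equal(fc$convergence_tol, 1e-6)
  expect_equal(fc$optimizer, "nlm")
  expect_error(fit_controls(max_outer_iter = 0))
})

test_that("zero-random-effect cohorts recover the shared parameters", {
  sets <- simulate_weibull_cohort(pop_A = 0, pop_B = 0, re_sd_A = 0,
                                  re_sd_B = 0, n_samples = 12,
                                  n_distances = 5000, seed = 13)
  fit <- suppressWarnings(sequential_filter_fit(sets))
  expect_true(fit$converged)
  expect_lt(abs(fit$population$shape - 5) / 5, 0.02)
  expect_lt(abs(fit$population$scale - 250) / 250, 0.02)
  expect_lt(fit$re_sd[["A"]], 0.1)
  expect_lt(fit$re_sd[["B"]], 0.1)
})

test_that("population fixed effects are recovered within 2 SEs", {
  sets <- simulate_weibull_cohort(pop_A = 0, pop_B = 0, re_sd_A = 0.3,
                                  re_sd_B = 0.2, n_samples = 24,
                                  n_distances = 2000, seed = 42)
  fit <- suppressWarnings(sequential_filter_fit(sets))
  expect_true(fit$converged)
  expect_lt(abs(fit$population$A - 0), 2 * fit$population$se_A)
  expect_lt(abs(fit$population$B - 0), 2 * fit$population$se_B)
  # RE SDs in the right ballpark, per-sample parameters inside the box
  expect_lt(abs(fit$re_sd[["A"]] - 0.3) / 0.3, 0.5)
  expect_lt(abs(fit$re_sd[["B"]] - 0.2) / 0.2, 0.5)
  expect_true(all(fit$per_sample$shape > 0 & fit$per_sample$shape < 10))
  expect_true(all(fit$per_sample$scale > 0 & fit$per_sample$scale < 500))
  # per-sample predictions track the generating parameters
  truth <- attr(sets, "truth")
  idx <- match(fit$per_sample$sample_id, truth$sample_id)
  expect_gt(cor(fit$per_sample$shape, truth$shape[idx]), 0.9)
  expect_gt(cor(fit$per_sample$scale, truth$scale[idx]), 0.9)
})

test_that("the filter ladder drops low-count pathological samples and converges", {
  set.seed(99)
  sets <- lapply(1:21, function(i) {
    nn_distance_set(sprintf("C%02d", i), "cd8_t", "cancer",
                    rweibull(400, 2, 30), 400, 400)
  })
  names(sets) <- sprintf("C%02d", 1:21)
  for (i in 1:3) {
    sid <- paste0("P", i)
    sets[[sid]] <- nn_distance_set(sid, "cd8_t", "cancer", rep(450, 10), 10, 10)
  }
  fit <- suppressWarnings(sequential_filter_fit(sets))
  expect_true(fit$converged)
  expect_equal(fit$filter_level, "20")
  expect_setequal(names(fit$samples_filtered), c("P1", "P2", "P3"))
  expect_setequal(fit$samples_used, sprintf("C%02d", 1:21))
})

test_that("clean cohorts keep every sample at filter level none", {
  sets <- simulate_weibull_cohort(n_samples = 8, n_distances = 500, seed = 3)
  fit <- suppressWarnings(sequential_filter_fit(sets))
  expect_true(fit$converged)
  expect_equal(fit$filter_level, "none")
  expect_length(fit$samples_used, 8L)
  expect_length(fit$samples_filtered, 0L)
})

test_that("unfittable cohorts are rejected with no parameters reported", {
  sets <- lapply(1:5, function(i) {
    nn_distance_set(paste0("D", i), "cd8_t", "cancer", rep(425 + 5 * i, 10), 10, 10)
  })
  names(sets) <- paste0("D", 1:5)
  fit <- suppressWarnings(sequential_filter_fit(sets))
  expect_false(fit$converged)
  expect_equal(fit$filter_level, "rejected")
  expect_null(fit$population)
  expect_null(fit$per_sample)
})

test_that("fewer than 3 samples is an insufficient-data error", {
  cv <- smooth_nn_pdf(rweibull(100, 2, 20))
  expect_error(fit_weibull_nlme(list(S1 = cv)), "at least 3 samples")
})

test_that("refitting identical inputs is bit-reproducible", {
  sets <- simulate_weibull_cohort(n_samples = 6, n_distances = 400, seed = 77)
  f1 <- suppressWarnings(sequential_filter_fit(sets))
  f2 <- suppressWarnings(sequential_filter_fit(sets))
  expect_identical(f1$population, f2$population)
  expect_identical(f1$per_sample, f2$per_sample)
  expect_identical(f1$re_sd, f2$re_sd)
})

test_that("fit reports serialize to JSON and read back", {
  sets <- simulate_weibull_cohort(n_samples = 6, n_distances = 400, seed = 78)
  fit <- suppressWarnings(sequential_filter_fit(sets))
  p <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, p)
  rep <- jsonlite::read_json(p)
  expect_equal(rep$sr_key, fit$sr_key)
  expect_equal(rep$filter_level, "none")
  expect_equal(rep$population$shape, fit$population$shape, tolerance = 1e-12)
})
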