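test_that("Poisson patterns have the right mean count and CSR 1-NN mean", {
  expect_equal(nrow(simulate_poisson_pattern(0, c(1000, 1000), seed = 1)), 0L)
  counts <- vapply(1:200, function(s) {
    nrow(simulate_poisson_pattern(0.005, c(1000, 1000), seed = s))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 5000) / 5000, 0.02)
  # mean cross 1-NN distance from independent references: 1/(2 sqrt(lambda))
  set.seed(2)
  tgt <- simulate_poisson_pattern(0.005, c(1000, 1000), seed = 3)
  ref <- cbind(runif(3000, 0, 1000), runif(3000, 0, 1000))
  d <- brute_nn(ref, tgt)
  expect_lt(abs(mean(d) - 1 / (2 * sqrt(0.005))) / (1 / (2 * sqrt(0.005))), 0.02)
})

test_that("seeding is reproducible and leaves the caller's RNG alone", {
  a <- simulate_poisson_pattern(0.001, c(500, 500), seed = 9)
  b <- simulate_poisson_pattern(0.001, c(500, 500), seed = 9)
  d <- simulate_poisson_pattern(0.001, c(500, 500), seed = 10)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(dim(a), dim(d))) &&
                 isTRUE(all.equal(a, d)))
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_poisson_pattern(0.001, c(500, 500), seed = 4))
  expect_identical(runif(1), before)
})

test_that("Weibull cohorts carry the configured random-effect structure", {
  sets0 <- simulate_weibull_cohort(re_sd_A = 0, re_sd_B = 0, n_samples = 5,
                                   n_distances = 100, seed = 1)
  truth0 <- attr(sets0, "truth")
  expect_equal(var(truth0$shape), 0)
  expect_equal(truth0$shape[1], 5)
  expect_equal(truth0$scale[1], 250)

  sets <- simulate_weibull_cohort(pop_A = -1, pop_B = 0.5, re_sd_A = 0.3,
                                  re_sd_B = 0.2, n_samples = 3,
                                  n_distances = 20000, seed = 6)
  truth <- attr(sets, "truth")
  for (i in 1:3) {
    want <- truth$scale[i] * gamma(1 + 1 / truth$shape[i])
    expect_lt(abs(mean(sets[[i]]$distances) - want) / want, 0.03)
  }
  expect_identical(
    simulate_weibull_cohort(n_samples = 3, n_distances = 50, seed = 8)[[1]]$distances,
    simulate_weibull_cohort(n_samples = 3, n_distances = 50, seed = 8)[[1]]$distances)
})

test_that("TME cohorts encode the response-dependent immune proximity", {
  cfg <- sim_config(n_responders = 3, n_non_responders = 3, seed = 5)
  cohort <- simulate_tme_cohort(cfg)
  expect_s3_class(cohort$cells, "cell_table")
  expect_equal(nrow(cohort$labels), 6L)
  expect_setequal(unique(cohort$cells$cell_type),
                  c("cancer", "negative", "cd8_t", "t_helper", "macrophage",
                    "b_cell", "foxp3_t"))
  med <- vapply(cohort$labels$sample_id, function(sid) {
    d <- cross_nn_distances(cohort$cells[cohort$cells$sample_id == sid, ],
                            "cd8_t", "cancer")
    median(d$distances)
  }, numeric(1))
  resp <- cohort$labels$response == "responder"
  expect_lt(max(med[resp]), min(med[!resp]))
})

test_that("infeasible nest configurations are rejected", {
  expect_error(sim_config(n_nests = 10, nest_radius = 200,
                          window = c(1000, 1000), seed = 1),
               "infeasible")
})

test_that("under CSR the fitted scale tracks only the target intensity", {
  lam_t <- 0.004
  base <- function(lam_ref, lam_target, seed) {
    with_seed(seed, {
      pooled <- unlist(lapply(1:4, function(i) {
        tgt <- simulate_poisson_pattern(lam_target, c(800, 800))
        ref <- simulate_poisson_pattern(lam_ref, c(800, 800))
        cross_nn_distances(cell_table(
          "S", c(ref[, 1], tgt[, 1]), c(ref[, 2], tgt[, 2]),
          rep(c("cd8_t", "cancer"), c(nrow(ref), nrow(tgt)))),
          "cd8_t", "cancer")$distances
      }))
      suppressMessages(fit_weibull_mle(pooled))
    })
  }
  p_full <- base(4e-4, lam_t, 11)
  p_half_ref <- base(2e-4, lam_t, 12)
  p_half_tgt <- base(4e-4, lam_t / 2, 13)
  b_expect <- (pi * lam_t)^(-1 / 2)
  # scale matches the closed form and ignores the reference intensity
  expect_lt(abs(p_full$scale - b_expect) / b_expect, 0.08)
  expect_lt(abs(p_half_ref$scale - p_full$scale) / p_full$scale, 0.08)
  # halving the target intensity rescales b by sqrt(2)
  expect_lt(abs(p_half_tgt$scale / p_full$scale - sqrt(2)) / sqrt(2), 0.08)
  expect_lt(abs(p_full$shape - 2), 0.15)
})
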