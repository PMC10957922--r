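make_labels <- function(n_resp, n_non) {
  cohort_labels(sprintf("S%02d", seq_len(n_resp + n_non)),
                rep(c("responder", "non_responder"), c(n_resp, n_non)))
}

make_matrix <- function(cols, n) {
  m <- data.frame(sample_id = sprintf("S%02d", seq_len(n)), cols)
  class(m) <- c("metrics_matrix", "data.frame")
  m
}

test_that("differential tests run on the declared analysis scale with BH by family", {
  set.seed(5)
  n <- 20
  labels <- make_labels(10, 10)
  grp <- rep(c(1, 0), each = 10)
  m <- make_matrix(data.frame(
    shape_a.b = rnorm(n, 2 + 0.8 * grp, 0.3),
    shape_c.d = rnorm(n, 3, 0.3),
    shape_e.f = rnorm(n, 1, 0.2),
    scale_a.b = exp(rnorm(n, 2 + grp, 0.3)),
    density_cd8_t_tumor = exp(rnorm(n, 5, 1))
  ), n)
  out <- differential_test(m, labels)
  expect_equal(out$scale[out$metric == "shape_a.b"], "linear")
  expect_equal(out$scale[out$metric == "scale_a.b"], "log")
  # fold change of a log-scale metric is the difference of log-means
  v <- log(m$scale_a.b)
  expect_equal(out$fold_change[out$metric == "scale_a.b"],
               mean(v[grp == 1]) - mean(v[grp == 0]))
  # BH within each family matches the hand-written step-up
  for (fam in unique(out$family)) {
    sel <- out$family == fam & !out$skipped
    expect_equal(out$fdr[sel], bh_stepup(out$p_value[sel]))
  }
})

test_that("identical groups give p = 1 and sparse metrics are skipped", {
  labels <- make_labels(2, 2)
  m <- make_matrix(data.frame(shape_x.y = c(1, 2, 1, 2),
                              scale_x.y = c(5, NA, NA, 6)), 4)
  out <- differential_test(m, labels)
  expect_equal(out$p_value[out$metric == "shape_x.y"], 1)
  expect_true(out$skipped[out$metric == "scale_x.y"])
})

test_that("the BH step-up of p.adjust matches the definition on random vectors", {
  # the documented q-values for [0.01, 0.02, 0.04] in a family of 3
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  set.seed(17)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(p.adjust(p, "BH"), bh_stepup(p))
  }
})

test_that("median distance test reproduces the exact Mann-Whitney p", {
  fit <- structure(list(
    converged = TRUE,
    per_sample = data.frame(
      sample_id = sprintf("S%02d", 1:6), A = 0, B = 0,
      shape = rep(1, 6), scale = c(1, 2, 3, 4, 5, 6) / log(2),
      median_1nn = c(1, 2, 3, 4, 5, 6))),
    class = "weibull_fit")
  labels <- make_labels(3, 3)
  out <- median_distance_test(fit, labels)
  expect_equal(out$p_value, 0.1) # enumeration over C(6,3) = 20 arrangements
  expect_equal(out$median_responder, 2)
  expect_equal(out$median_non_responder, 5)
  # medians satisfy the analytic formula
  ps <- fit$per_sample
  expect_equal(ps$median_1nn, ps$scale * log(2)^(1 / ps$shape))
})

test_that("rank-statistic AUC equals trapezoidal ROC integration", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    scores <- sample(c(rnorm(n), round(rnorm(n), 1))) # with and without ties
    scores <- scores[1:n]
    is_case <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(is_case) || all(is_case)) next
    expect_equal(weibullSR:::auc_rank(scores, is_case),
                 trapezoid_auc(scores, is_case), tolerance = 1e-12)
  }
})

test_that("logistic ROC: perfect separation, null features, and pROC agreement", {
  labels <- make_labels(7, 7)
  perfect <- c(rnorm(7, 10), rnorm(7, -10))
  roc_p <- logistic_roc(perfect, labels, seed = 1)
  expect_equal(roc_p$auc, 1)
  expect_equal(unname(roc_p$ci), c(1, 1))
  expect_true(roc_p$separation_flag)

  set.seed(31)
  big_labels <- cohort_labels(sprintf("N%03d", 1:200),
                              rep(c("responder", "non_responder"), 100))
  noise <- rnorm(200)
  roc_n <- logistic_roc(noise, big_labels, seed = 2)
  expect_gt(roc_n$auc, 0.4)
  expect_lt(roc_n$auc, 0.6)

  # independent cross-check of the AUC statistic
  feats <- rnorm(14, ifelse(labels$response == "responder", 0.8, 0), 1)
  roc_f <- logistic_roc(feats, labels, seed = 3)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels$response == "responder",
    predictor = roc_f$scores, quiet = TRUE, direction = "<")))
  expect_equal(roc_f$auc, ref, tolerance = 1e-12)
})

test_that("paired bootstrap ROC comparison is directional and seed-stable", {
  set.seed(41)
  labels <- cohort_labels(sprintf("N%03d", 1:100),
                          rep(c("responder", "non_responder"), 50))
  strong <- ifelse(labels$response == "responder", 1, 0) + rnorm(100, 0, 1e-6)
  noise <- rnorm(100)
  roc_a <- logistic_roc(strong, labels, seed = 5)
  roc_b <- logistic_roc(noise, labels, seed = 5)
  self <- bootstrap_roc_compare(roc_a, roc_a, seed = 6)
  expect_gt(self$p_value, 0.4)
  cmp <- bootstrap_roc_compare(roc_a, roc_b, seed = 6)
  expect_lt(cmp$p_value, 0.01)
  rev <- bootstrap_roc_compare(roc_b, roc_a, seed = 6)
  expect_gt(rev$p_value, 0.5)
  expect_identical(bootstrap_roc_compare(roc_a, roc_b, seed = 6)$boot_diff,
                   cmp$boot_diff)
  bad <- logistic_roc(rnorm(14), make_labels(7, 7), seed = 1)
  expect_error(bootstrap_roc_compare(roc_a, bad), "same samples")
})

test_that("LOO deviance: closed-form null deviance and set comparisons", {
  labels <- make_labels(14, 10)
  n <- 24
  intercept_only <- data.frame(rep(1, n))
  # full-data null binomial deviance for a 14/10 split
  y <- labels$response == "responder"
  expected_null <- -2 * (14 * log(14 / 24) + 10 * log(10 / 24))
  null_fit <- glm(y ~ 1, family = binomial())
  expect_equal(null_fit$null.deviance, expected_null, tolerance = 1e-10)
  expect_equal(expected_null, 32.60, tolerance = 1e-2)

  set.seed(51)
  perfect <- data.frame(f = ifelse(y, 5, -5))
  weak <- data.frame(f = rnorm(n))
  out <- loo_deviance_compare(list(perfect = perfect, weak = weak,
                                   weak2 = weak), labels)
  expect_true(all(out$deviance[, "perfect"] < 1e-4))
  expect_lt(out$p_matrix["perfect", "weak"], 0.01)
  expect_equal(out$p_matrix["weak", "weak2"], 1)
})
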