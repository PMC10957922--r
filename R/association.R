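# Downstream statistics: differential tests with BH correction, median
# 1-NN distance group comparisons, logistic-regression ROC machinery with
# bootstrap confidence intervals and comparisons, and leave-one-out deviance
# comparisons between feature sets.

#' Differential metric testing between response groups
#'
#' Per metric: a two-sided Welch t-test between responders and non-responders
#' on the metric's analysis scale (natural log for densities, exclusion
#' ratios and the Weibull scale; linear for the shape), followed by
#' Benjamini-Hochberg adjustment within each declared family. Fold change is
#' the difference of group means on the analysis scale (a log-ratio for
#' log-scale metrics). Non-positive values are dropped before a log
#' transform; metrics with fewer than 2 usable values in either group are
#' skipped with a reason.
#'
#' @param m a [build_metrics_matrix()] data.frame.
#' @param labels a [cohort_labels()] data.frame.
#' @param scale_map optional named character vector metric -> `"log"` or
#'   `"linear"`; defaults by metric prefix (`shape_` linear, all else log).
#' @param family_map optional named character vector metric -> family label
#'   for the FDR adjustment; defaults by metric prefix.
#' @param var_equal use the pooled-variance Student t-test instead of Welch.
#' @return data.frame with one row per metric: `metric`, `family`, `scale`,
#'   `mean_responder`, `mean_non_responder`, `fold_change`, `p_value`, `fdr`,
#'   `skipped`, `skip_reason`.
#' @export
differential_test <- function(m, labels, scale_map = NULL, family_map = NULL,
                              var_equal = FALSE) {
  metrics <- setdiff(names(m), "sample_id")
  grp <- labels$response[match(m$sample_id, labels$sample_id)]
  default_scale <- function(metric) {
    if (startsWith(metric, "shape_")) "linear" else "log"
  }
  default_family <- function(metric) sub("_.*$", "", metric)
  rows <- lapply(metrics, function(metric) {
    scale <- scale_map[[metric]] %||% default_scale(metric)
    family <- family_map[[metric]] %||% default_family(metric)
    v <- m[[metric]]
    ok <- !is.na(v) & !is.na(grp)
    if (scale == "log") ok <- ok & v > 0
    x <- if (scale == "log") log(v[ok & grp == "responder"]) else v[ok & grp == "responder"]
    y <- if (scale == "log") log(v[ok & grp == "non_responder"]) else v[ok & grp == "non_responder"]
    base <- data.frame(metric = metric, family = family, scale = scale,
                       mean_responder = NA_real_, mean_non_responder = NA_real_,
                       fold_change = NA_real_, p_value = NA_real_, fdr = NA_real_,
                       skipped = FALSE, skip_reason = NA_character_,
                       stringsAsFactors = FALSE)
    if (length(x) < 2L || length(y) < 2L) {
      base$skipped <- TRUE
      base$skip_reason <- "fewer than 2 usable values in a group"
      return(base)
    }
    tt <- if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
      list(p.value = 1) # identical constant groups: no evidence by definition
    } else {
      stats::t.test(x, y, var.equal = var_equal)
    }
    base$mean_responder <- mean(x)
    base$mean_non_responder <- mean(y)
    base$fold_change <- mean(x) - mean(y)
    base$p_value <- tt$p.value
    base
  })
  out <- do.call(rbind, rows)
  for (fam in unique(out$family)) {
    sel <- out$family == fam & !out$skipped
    out$fdr[sel] <- stats::p.adjust(out$p_value[sel], method = "BH")
  }
  out
}

#' Median 1-NN distance comparison between response groups
#'
#' Per-sample median distances (scale * (ln 2)^(1/shape), from the
#' mixed-model per-sample parameters) compared between responders and
#' non-responders with a two-sided Mann-Whitney test (exact when group sizes
#' allow, normal approximation above 20 per group).
#'
#' @param fit a converged `weibull_fit`.
#' @param labels a [cohort_labels()] data.frame.
#' @return List with `median_responder`, `median_non_responder`, `p_value`,
#'   `per_sample` (data.frame of sample, group, median).
#' @export
median_distance_test <- function(fit, labels) {
  if (!isTRUE(fit$converged)) stop("fit did not converge; no per-sample parameters")
  ps <- fit$per_sample
  grp <- labels$response[match(ps$sample_id, labels$sample_id)]
  keep <- !is.na(grp)
  med <- ps$median_1nn[keep]
  grp <- grp[keep]
  x <- med[grp == "responder"]
  y <- med[grp == "non_responder"]
  exact <- length(x) <= 20 && length(y) <= 20
  wt <- stats::wilcox.test(x, y, exact = exact)
  list(median_responder = stats::median(x),
       median_non_responder = stats::median(y),
       p_value = wt$p.value,
       per_sample = data.frame(sample_id = ps$sample_id[keep],
                               response = grp, median_1nn = med,
                               stringsAsFactors = FALSE))
}

# Rank-statistic ROC AUC: P(score_case > score_control) + 0.5 P(tie).
auc_rank <- function(scores, is_case) {
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Logistic-regression ROC with bootstrap confidence interval
#'
#' Fits an unpenalized logistic regression of response on the supplied
#' features, builds the ROC from the in-sample fitted probabilities, and
#' summarizes it by the rank-statistic AUC. Significance against AUC = 0.5
#' is a two-sided rank test comparing fitted scores between classes; the 95%
#' CI is a percentile bootstrap (class-stratified resampling of samples,
#' default 500 replicates). In-sample ROCs are optimistic; the AUC measures
#' discrimination of the fitted model on its own training data.
#'
#' @param features data.frame (or vector) of predictors, rows aligned with
#'   `labels` (must include `sample_id` alignment via row order).
#' @param labels a [cohort_labels()] data.frame (same order as `features`).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return Object of class `roc_result`: `auc`, `ci` (length 2),
#'   `p_vs_chance`, `boot_aucs`, `scores`, `is_case`, `separation_flag`.
#' @export
logistic_roc <- function(features, labels, n_boot = 500, seed = 1) {
  if (is.vector(features) || is.null(dim(features))) {
    features <- data.frame(f1 = features)
  }
  features <- as.data.frame(features)
  features$sample_id <- NULL
  y <- as.integer(labels$response == "responder")
  if (sum(y) < 3L || sum(1 - y) < 3L) stop("need at least 3 samples per class")
  stopifnot(all(is.finite(as.matrix(features))))
  dat <- cbind(data.frame(.y = y), features)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  separated <- separated || !fit$converged
  scores <- stats::fitted(fit)
  is_case <- y == 1L
  auc <- auc_rank(scores, is_case)
  wt <- tryCatch(
    suppressWarnings(stats::wilcox.test(scores[is_case], scores[!is_case])),
    error = function(e) list(p.value = NA_real_)
  )
  boot_aucs <- with_seed(seed, {
    cases <- which(is_case)
    controls <- which(!is_case)
    vapply(seq_len(n_boot), function(i) {
      idx <- c(sample(cases, replace = TRUE), sample(controls, replace = TRUE))
      auc_rank(scores[idx], is_case[idx])
    }, numeric(1))
  })
  structure(list(
    auc = auc,
    ci = unname(stats::quantile(boot_aucs, c(0.025, 0.975), na.rm = TRUE)),
    p_vs_chance = wt$p.value,
    boot_aucs = boot_aucs,
    scores = scores,
    is_case = is_case,
    separation_flag = separated,
    n_boot = n_boot,
    seed = seed
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC AUC = %.3f (95%% CI %.3f-%.3f, bootstrap n=%d), p vs 0.5 = %.3g%s\n",
              x$auc, x$ci[1L], x$ci[2L], x$n_boot, x$p_vs_chance,
              if (x$separation_flag) " [perfect separation flagged]" else ""))
  invisible(x)
}

#' One-sided bootstrap comparison of two ROC curves
#'
#' Paired bootstrap over the same samples: each replicate resamples sample
#' indices (class-stratified) once and recomputes both AUCs on that
#' replicate; a one-sided t-test on the replicate AUC differences tests
#' H1: AUC_a > AUC_b. If every replicate difference is exactly zero
#' (identical score vectors), p = 0.5 by convention.
#'
#' @param roc_a,roc_b `roc_result` objects built on the same samples.
#' @param n_boot replicates.
#' @param seed integer seed.
#' @return List with `p_value`, `mean_diff`, `boot_diff`.
#' @export
bootstrap_roc_compare <- function(roc_a, roc_b, n_boot = 500, seed = 1) {
  if (length(roc_a$scores) != length(roc_b$scores) ||
      !identical(roc_a$is_case, roc_b$is_case)) {
    stop("the two ROCs must be built on the same samples")
  }
  is_case <- roc_a$is_case
  boot_diff <- with_seed(seed, {
    cases <- which(is_case)
    controls <- which(!is_case)
    vapply(seq_len(n_boot), function(i) {
      idx <- c(sample(cases, replace = TRUE), sample(controls, replace = TRUE))
      auc_rank(roc_a$scores[idx], is_case[idx]) -
        auc_rank(roc_b$scores[idx], is_case[idx])
    }, numeric(1))
  })
  if (stats::sd(boot_diff) == 0) {
    p <- if (mean(boot_diff) > 0) 0 else if (mean(boot_diff) < 0) 1 else 0.5
  } else {
    p <- stats::t.test(boot_diff, alternative = "greater")$p.value
  }
  list(p_value = p, mean_diff = mean(boot_diff), boot_diff = boot_diff)
}

#' Leave-one-out deviance comparison between feature sets
#'
#' For each leave-one-out fold, fits a logistic regression of response on
#' each feature set using the retained samples and records its residual
#' deviance (lower = better fit); per-fold deviance vectors are compared
#' between feature sets by a two-sided t-test. Folds with separation are
#' flagged and keep the capped-fit deviance.
#'
#' @param feature_sets named list of data.frames (rows aligned with
#'   `labels`).
#' @param labels a [cohort_labels()] data.frame.
#' @return List with `deviance` (folds x sets matrix), `p_matrix` (pairwise
#'   two-sided t-test p-values), `separation_flags`.
#' @export
loo_deviance_compare <- function(feature_sets, labels) {
  y <- as.integer(labels$response == "responder")
  n <- length(y)
  if (n < 4L) stop("need at least 4 samples for leave-one-out deviance")
  sets <- names(feature_sets)
  dev <- matrix(NA_real_, n, length(sets), dimnames = list(NULL, sets))
  sep <- matrix(FALSE, n, length(sets), dimnames = list(NULL, sets))
  for (s in sets) {
    feats <- as.data.frame(feature_sets[[s]])
    feats$sample_id <- NULL
    for (i in seq_len(n)) {
      dat <- cbind(data.frame(.y = y), feats)[-i, , drop = FALSE]
      fit <- suppressWarnings(stats::glm(.y ~ ., data = dat,
                                         family = stats::binomial()))
      dev[i, s] <- fit$deviance
      sep[i, s] <- !fit$converged || any(abs(stats::coef(fit)[-1L]) > 1e3)
    }
  }
  p_matrix <- matrix(NA_real_, length(sets), length(sets),
                     dimnames = list(sets, sets))
  for (a in sets) for (b in sets) {
    if (a == b) next
    da <- dev[, a]
    db <- dev[, b]
    p_matrix[a, b] <- if (isTRUE(all.equal(da, db))) 1 else {
      stats::t.test(da, db)$p.value
    }
  }
  list(deviance = dev, p_matrix = p_matrix, separation_flags = sep)
}
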