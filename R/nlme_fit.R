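# Cohort-level Weibull fit of the smoothed 1-NN distance densities:
# a nonlinear mixed-effects model with the unconstrained (A, B) logistic
# coordinates as fixed effects and diagonal-covariance Gaussian random
# effects per sample, estimated by REML.

#' Mixed-model fitting controls
#'
#' Control constants for the nonlinear mixed-effects optimization.
#'
#' @param max_outer_iter maximum iterations of the outer optimization.
#' @param max_inner_iter maximum iterations of the inner optimization step.
#' @param step_tol tolerance of the penalized nonlinear least-squares step.
#' @param convergence_tol relative-change convergence criterion.
#' @param optimizer `"nlm"` or `"nlminb"`.
#' @param max_fit_seconds wall-clock bound per optimization attempt; an
#'   attempt exceeding it counts as non-convergence, which hands control to
#'   the filter ladder.
#' @param seed optional integer seed recorded with the fit (the fit itself is
#'   deterministic; the seed tags simulated inputs).
#' @return Object of class `fit_controls`.
#' @export
fit_controls <- function(max_outer_iter = 1000, max_inner_iter = 200,
                         step_tol = 1e-1, convergence_tol = 1e-6,
                         optimizer = "nlm", max_fit_seconds = 30,
                         seed = NULL) {
  stopifnot(max_outer_iter > 0, max_inner_iter > 0, step_tol > 0,
            convergence_tol > 0, max_fit_seconds > 0)
  structure(list(max_outer_iter = max_outer_iter,
                 max_inner_iter = max_inner_iter,
                 step_tol = step_tol,
                 convergence_tol = convergence_tol,
                 optimizer = match.arg(optimizer, c("nlm", "nlminb")),
                 max_fit_seconds = max_fit_seconds,
                 seed = seed),
            class = "fit_controls")
}

# Moment-based Weibull guess from a density curve (fallback initialization
# when the raw-distance MLE is unavailable for a sample).
curve_moment_init <- function(grid, dens) {
  m <- trapz(grid, grid * dens)
  v <- max(trapz(grid, (grid - m)^2 * dens), 1e-8)
  cv <- sqrt(v) / max(m, 1e-8)
  shape <- min(max(cv^(-1.086), 0.05), SHAPE_SUP - 0.05)
  scale <- min(max(m / gamma(1 + 1 / shape), 0.05), SCALE_SUP - 0.05)
  weibull_params(shape, scale)
}

#' Fit the Weibull nonlinear mixed-effects model to smoothed 1-NN curves
#'
#' Fits density(t) ~ Weibull pdf(t; a_i, b_i) + Gaussian residual across a
#' cohort of per-sample smoothed 1-NN densities, where the per-sample
#' unconstrained parameters (A_i, B_i) are the population fixed effects plus
#' sample-level Gaussian random effects with diagonal covariance
#' (`nlme::pdDiag`), estimated by REML. Per-sample reported parameters are
#' fixed effect + predicted random effect, mapped through the logistic links.
#'
#' @param curves named list of [smooth_nn_pdf()] objects, one per sample
#'   (>= 3 samples).
#' @param init optional named list of `weibull_params` initial estimates per
#'   sample (e.g. from [fit_weibull_mle()]); missing entries fall back to a
#'   curve-moment guess. Population start = mean of per-sample (A_i, B_i).
#' @param controls a [fit_controls()] object.
#' @param t_max optional truncation of the fitting grid (micrometers),
#'   typically the 99th percentile of the pooled distances.
#' @param sr_key optional character label `"from->to"` recorded on the fit.
#' @return Object of class `weibull_fit`; see [sequential_filter_fit()] for
#'   the fields.
#' @export
fit_weibull_nlme <- function(curves, init = NULL, controls = fit_controls(),
                             t_max = NULL, sr_key = NA_character_) {
  if (length(curves) < 3L) {
    stop("insufficient data: the mixed model needs at least 3 samples")
  }
  ids <- names(curves) %||% as.character(seq_along(curves))
  names(curves) <- ids

  rows <- lapply(ids, function(sid) {
    cv <- curves[[sid]]
    # t = 0 is excluded: the Weibull density is unbounded there for shape < 1
    # (and the half-open smoothing window makes the 0-bin boundary-biased)
    keep <- cv$grid > 0 & (if (is.null(t_max)) TRUE else cv$grid <= t_max)
    data.frame(sample = sid, t = cv$grid[keep], dens = cv$density[keep],
               stringsAsFactors = FALSE)
  })
  dat <- do.call(rbind, rows)
  dat$sample <- factor(dat$sample, levels = ids)

  start_ab <- t(vapply(ids, function(sid) {
    p <- init[[sid]]
    if (is.null(p)) {
      cv <- curves[[sid]]
      p <- curve_moment_init(cv$grid, cv$density)
    }
    c(p$A, p$B)
  }, numeric(2)))
  start <- c(A = mean(start_ab[, 1L]), B = mean(start_ab[, 2L]))

  # model expression inlined (dweibull is on the search path) so nlme's
  # internal evaluation environment can always resolve it
  model <- dens ~ dweibull(t, shape = 10 / (1 + exp(-A)),
                           scale = 500 / (1 + exp(-B)))
  environment(model) <- environment()

  # primary optimizer first; one fallback attempt with the other optimizer
  # before the failure is handed to the filter ladder
  opts <- unique(c(controls$optimizer, "nlminb", "nlm"))[1:2]
  fit <- NULL
  for (op in opts) {
    ctrl <- nlme::nlmeControl(maxIter = controls$max_outer_iter,
                              msMaxIter = controls$max_inner_iter,
                              pnlsTol = controls$step_tol,
                              tolerance = controls$convergence_tol,
                              opt = op)
    fit <- tryCatch({
      setTimeLimit(elapsed = controls$max_fit_seconds %||% 30,
                   transient = TRUE)
      on.exit(setTimeLimit(elapsed = Inf), add = TRUE)
      nlme::nlme(model, data = dat,
                 fixed = A + B ~ 1,
                 random = nlme::pdDiag(A + B ~ 1),
                 groups = ~sample,
                 start = start,
                 method = "REML",
                 control = ctrl)
    }, error = function(e) e)
    setTimeLimit(elapsed = Inf)
    if (!inherits(fit, "error")) break
  }

  if (inherits(fit, "error")) {
    return(structure(list(sr_key = sr_key, converged = FALSE,
                          failure = conditionMessage(fit),
                          population = NULL, per_sample = NULL,
                          samples_used = ids, filter_level = NA_character_,
                          controls = controls),
                     class = "weibull_fit"))
  }

  fe <- nlme::fixef(fit)
  pop_nat <- link_transform(fe[["A"]], fe[["B"]])
  co <- stats::coef(fit) # fixed + predicted random effect per sample
  per_sample <- data.frame(
    sample_id = rownames(co),
    A = co$A, B = co$B,
    shape = SHAPE_SUP / (1 + exp(-co$A)),
    scale = SCALE_SUP / (1 + exp(-co$B)),
    stringsAsFactors = FALSE
  )
  per_sample$median_1nn <- median_1nn(shape = per_sample$shape,
                                      scale = per_sample$scale)
  vc <- nlme::VarCorr(fit)
  re_sd <- suppressWarnings(as.numeric(vc[c("A", "B"), "StdDev"]))
  se <- sqrt(diag(fit$varFix))
  ap_pd <- is.numeric(fit$apVar) # non-PD approximate covariance => character

  structure(list(
    sr_key = sr_key,
    converged = TRUE,
    hessian_pd = ap_pd,
    population = list(A = unname(fe[["A"]]), B = unname(fe[["B"]]),
                      shape = unname(pop_nat[["shape"]]),
                      scale = unname(pop_nat[["scale"]]),
                      se_A = unname(se[1L]), se_B = unname(se[2L])),
    per_sample = per_sample,
    re_sd = c(A = re_sd[1L], B = re_sd[2L]),
    sigma = fit$sigma,
    logLik = as.numeric(stats::logLik(fit)),
    n_iter = fit$numIter %||% NA_integer_,
    samples_used = ids,
    filter_level = NA_character_,
    controls = controls
  ), class = "weibull_fit")
}

#' Sequential cell-count filter ladder around the mixed-effects fit
#'
#' Attempts the cohort fit on all samples of one spatial relationship; on
#' non-convergence, samples with fewer than 20 reference or target cells
#' (nFROM < 20 or nTO < 20) are dropped and the fit retried, then at the 50,
#' 70 and 100-cell levels. If the fit still fails after the 100-cell level
#' the relationship is marked rejected. The fitting grid is restricted to
#' \[0, 99th percentile of the pooled distances\].
#'
#' @param sets named list of `nn_distance_set` objects, one per sample, all
#'   for the same (from, to) relationship.
#' @param controls a [fit_controls()].
#' @param window,step smoothing parameters passed to [smooth_nn_pdf()].
#' @return A `weibull_fit` with `filter_level` in
#'   `"none"`, `"20"`, `"50"`, `"70"`, `"100"` or `"rejected"`, plus
#'   `samples_filtered` (named reasons for every dropped sample).
#' @export
sequential_filter_fit <- function(sets, controls = fit_controls(),
                                  window = 5, step = 1) {
  if (length(sets) < 1L) stop("no samples supplied")
  ids <- names(sets) %||% vapply(sets, function(s) s$sample_id, character(1))
  names(sets) <- ids
  sr_key <- if (length(sets)) {
    paste0(sets[[1L]]$from_type, "->", sets[[1L]]$to_type)
  } else NA_character_

  prep <- lapply(sets, function(s) {
    curve <- tryCatch(smooth_nn_pdf(s, window = window, step = step),
                      error = function(e) NULL)
    mle <- tryCatch(suppressMessages(fit_weibull_mle(s)),
                    error = function(e) NULL)
    list(set = s, curve = curve, mle = mle)
  })

  filtered <- character(0)
  levels <- c(none = 0, `20` = 20, `50` = 50, `70` = 70, `100` = 100)
  last_failure <- NULL
  prev_keep <- NULL
  for (lv in names(levels)) {
    thr <- levels[[lv]]
    keep <- vapply(prep, function(p) {
      !is.null(p$curve) && p$set$n_from >= thr && p$set$n_to >= thr
    }, logical(1))
    if (identical(keep, prev_keep)) next # same samples: the fit cannot differ
    prev_keep <- keep
    dropped <- ids[!keep]
    reasons <- vapply(prep[!keep], function(p) {
      if (is.null(p$curve)) "degenerate_curve"
      else sprintf("n_from=%d or n_to=%d below %d", p$set$n_from, p$set$n_to, thr)
    }, character(1))
    names(reasons) <- dropped
    if (sum(keep) < 3L) {
      last_failure <- sprintf("fewer than 3 samples remain at filter level %s", lv)
      next
    }
    pooled <- unlist(lapply(prep[keep], function(p) p$set$distances))
    t_max <- max(stats::quantile(pooled, 0.99), 10)
    fit <- fit_weibull_nlme(
      curves = lapply(prep[keep], `[[`, "curve"),
      init = lapply(prep[keep], `[[`, "mle"),
      controls = controls, t_max = t_max, sr_key = sr_key
    )
    if (isTRUE(fit$converged)) {
      fit$filter_level <- lv
      fit$samples_filtered <- reasons
      return(fit)
    }
    last_failure <- fit$failure %||% "non-convergence"
  }
  structure(list(sr_key = sr_key, converged = FALSE,
                 failure = last_failure %||% "non-convergence at all filter levels",
                 population = NULL, per_sample = NULL,
                 samples_used = character(0),
                 samples_filtered = stats::setNames(
                   rep("rejected with relationship", length(ids)), ids),
                 filter_level = "rejected", controls = controls),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf("Weibull SR fit [%s]: shape = %.3f, scale = %.3f um (filter level %s, %d samples)\n",
                x$sr_key %||% "?", x$population$shape, x$population$scale,
                x$filter_level, length(x$samples_used)))
    cat(sprintf("  random-effect SDs: A %.3f, B %.3f; residual sigma %.4g\n",
                x$re_sd[["A"]], x$re_sd[["B"]], x$sigma))
  } else {
    cat(sprintf("Weibull SR fit [%s]: NOT converged (%s)\n",
                x$sr_key %||% "?", x$failure %||% "unknown"))
  }
  invisible(x)
}

#' Write a fit report as JSON
#'
#' @param fit a `weibull_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  rep <- list(
    sr_key = fit$sr_key,
    converged = fit$converged,
    filter_level = fit$filter_level,
    population = fit$population,
    random_effect_sd = as.list(fit$re_sd),
    residual_sd = fit$sigma,
    per_sample = fit$per_sample,
    samples_used = fit$samples_used,
    samples_filtered = as.list(fit$samples_filtered %||% character(0)),
    failure = fit$failure %||% NULL
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
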