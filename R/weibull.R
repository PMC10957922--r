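# Weibull parameterization of a spatial relationship, with the logistic
# re-parameterization used inside the mixed model: the unconstrained (A, B)
# map to shape a = 10 / (1 + exp(-A)) in (0, 10) and
# scale b = 500 / (1 + exp(-B)) um in (0, 500).

SHAPE_SUP <- 10
SCALE_SUP <- 500

#' Weibull shape/scale parameters
#'
#' @param shape Weibull shape a (dimensionless, in (0, 10)).
#' @param scale Weibull scale b in micrometers (in (0, 500)).
#' @return Object of class `weibull_params` with fields `shape`, `scale`,
#'   `A`, `B` (the unconstrained logistic coordinates).
#' @export
weibull_params <- function(shape, scale) {
  ab <- inverse_link_transform(shape, scale)
  structure(list(shape = shape, scale = scale, A = ab[["A"]], B = ab[["B"]]),
            class = "weibull_params")
}

#' Logistic link between unconstrained and natural Weibull parameters
#'
#' `link_transform(A, B)` returns the natural parameters
#' a = 10 / (1 + exp(-A)), b = 500 / (1 + exp(-B));
#' `inverse_link_transform(shape, scale)` inverts it and errors at or outside
#' the open bounds.
#'
#' @param A,B unconstrained real parameters.
#' @return Named vector `c(shape=, scale=)` (or `c(A=, B=)` for the inverse).
#' @export
link_transform <- function(A, B) {
  c(shape = SHAPE_SUP / (1 + exp(-A)), scale = SCALE_SUP / (1 + exp(-B)))
}

#' @rdname link_transform
#' @param shape,scale natural parameters, shape in (0, 10), scale in (0, 500).
#' @export
inverse_link_transform <- function(shape, scale) {
  if (shape <= 0 || shape >= SHAPE_SUP) {
    stop("shape must lie strictly inside (0, ", SHAPE_SUP, ")")
  }
  if (scale <= 0 || scale >= SCALE_SUP) {
    stop("scale must lie strictly inside (0, ", SCALE_SUP, ")")
  }
  c(A = -log(SHAPE_SUP / shape - 1), B = -log(SCALE_SUP / scale - 1))
}

#' Weibull probability density
#'
#' f(x; a, b) = (a/b) (x/b)^(a-1) exp(-(x/b)^a) for x >= 0.
#'
#' @param x distances in micrometers (>= 0).
#' @param p a `weibull_params` object (or use `shape`/`scale` directly).
#' @param shape,scale alternative to `p`.
#' @return Density values (per micrometer).
#' @export
weibull_pdf <- function(x, p = NULL, shape = p$shape, scale = p$scale) {
  if (any(x < 0)) stop("weibull_pdf is defined for x >= 0")
  stats::dweibull(x, shape = shape, scale = scale)
}

#' Analytic cumulative 1-NN distance distribution
#'
#' CDF(r) = 1 - exp(-(r/b)^a): the Weibull-derived (threshold-free analogue
#' of the) G-function.
#'
#' @param r distances in micrometers (>= 0).
#' @inheritParams weibull_pdf
#' @return Probabilities in \[0, 1\].
#' @export
analytic_cdf <- function(r, p = NULL, shape = p$shape, scale = p$scale) {
  if (any(r < 0)) stop("analytic_cdf is defined for r >= 0")
  stats::pweibull(r, shape = shape, scale = scale)
}

#' AUC of the analytic CDF up to a threshold (Weibull-G-AUC-T)
#'
#' Numerical integral of [analytic_cdf()] over \[0, T\] by adaptive
#' quadrature (absolute tolerance 1e-8).
#'
#' @param T threshold in micrometers (> 0).
#' @inheritParams weibull_pdf
#' @return The Weibull-G-AUC-T in micrometers.
#' @export
weibull_g_auc <- function(p = NULL, T, shape = p$shape, scale = p$scale) {
  stopifnot(T > 0)
  stats::integrate(function(r) stats::pweibull(r, shape, scale),
                   0, T, abs.tol = 1e-8, rel.tol = 1e-10)$value
}

#' Median 1-NN distance of a fitted spatial relationship
#'
#' The exact Weibull median, scale * (ln 2)^(1/shape).
#'
#' @inheritParams weibull_pdf
#' @return Median distance in micrometers.
#' @export
median_1nn <- function(p = NULL, shape = p$shape, scale = p$scale) {
  scale * log(2)^(1 / shape)
}

#' Per-sample Weibull maximum-likelihood estimate
#'
#' MLE of (shape, scale) on the raw 1-NN distances, used to initialize the
#' cohort mixed-effects fit. Zero distances are floored at 0.01 um (with a
#' message) so the likelihood stays finite.
#'
#' @param d an `nn_distance_set` or numeric distance vector (>= 5 values, not
#'   all identical).
#' @return A `weibull_params` object with attribute `"se"` (estimate
#'   standard errors from the fit).
#' @export
fit_weibull_mle <- function(d) {
  x <- if (inherits(d, "nn_distance_set")) d$distances else as.numeric(d)
  if (length(x) < 5L) stop("need at least 5 distances for a Weibull MLE")
  if (diff(range(x)) == 0) stop("degenerate distance set: all values identical")
  n_zero <- sum(x <= 0)
  if (n_zero > 0L) {
    message(n_zero, " zero distance(s) floored at 0.01 um for the MLE")
    x[x <= 0] <- 0.01
  }
  fit <- fitdistrplus::fitdist(x, "weibull")
  est <- fit$estimate
  shape <- unname(est[["shape"]])
  scale <- unname(est[["scale"]])
  # the estimate only seeds the constrained mixed model, so clamp it just
  # inside the logistic-link bounds if the unconstrained MLE falls outside
  if (shape >= SHAPE_SUP || shape <= 0 || scale >= SCALE_SUP || scale <= 0) {
    message("MLE (", signif(shape, 4), ", ", signif(scale, 4),
            ") clamped inside the (0,10) x (0,500) parameter box")
    shape <- min(max(shape, 1e-3), SHAPE_SUP - 1e-3)
    scale <- min(max(scale, 1e-3), SCALE_SUP - 1e-3)
  }
  p <- weibull_params(shape = shape, scale = scale)
  attr(p, "se") <- fit$sd
  p
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull SR parameters: shape = %.4g, scale = %.4g um (A = %.4g, B = %.4g)\n",
              x$shape, x$scale, x$A, x$B))
  invisible(x)
}
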