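#' Cross-type first-nearest-neighbor distances
#'
#' For every reference cell (`from_type`) in a sample, the Euclidean distance
#' to its closest target cell (`to_type`) over the whole slide. The statistic
#' is asymmetric: (A to B) and (B to A) are distinct. For a self-self
#' relationship a cell is excluded as its own neighbor.
#'
#' @param ct a [cell_table()]; must contain exactly one sample (subset first).
#' @param from_type,to_type phenotype labels from [cell_types()].
#' @return An object of class `nn_distance_set`: list with `sample_id`,
#'   `from_type`, `to_type`, `distances` (one per reference cell, in
#'   micrometers), `n_from`, `n_to`.
#' @export
cross_nn_distances <- function(ct, from_type, to_type) {
  ct <- validate_cell_table(ct)
  sid <- unique(ct$sample_id)
  if (length(sid) != 1L) stop("cross_nn_distances expects a single-sample cell table")
  stopifnot(from_type %in% cell_types(), to_type %in% cell_types())
  from <- ct[ct$cell_type == from_type, c("x", "y")]
  to <- ct[ct$cell_type == to_type, c("x", "y")]
  self <- identical(from_type, to_type)
  n_from <- nrow(from)
  n_to <- nrow(to)
  if (n_from < 1L) stop("no reference cells of type ", from_type)
  if (n_to < 1L || (self && n_to < 2L)) {
    stop(structure(
      class = c("empty_target_error", "error", "condition"),
      list(message = sprintf("no target cells of type %s (n_from=%d, n_to=%d)",
                             to_type, n_from, n_to),
           call = sys.call(),
           n_from = n_from, n_to = n_to)
    ))
  }
  d <- nn_dist_chunked(as.matrix(from), as.matrix(to), self = self)
  nn_distance_set(sid, from_type, to_type, d, n_from, n_to)
}

#' @rdname cross_nn_distances
#' @param sample_id sample identifier.
#' @param distances numeric vector of 1-NN distances (micrometers, >= 0).
#' @param n_from,n_to reference / target cell counts.
#' @export
nn_distance_set <- function(sample_id, from_type, to_type, distances,
                            n_from = length(distances), n_to = NA_integer_) {
  stopifnot(all(is.finite(distances)), all(distances >= 0))
  structure(
    list(sample_id = sample_id, from_type = from_type, to_type = to_type,
         distances = as.numeric(distances),
         n_from = as.integer(n_from), n_to = as.integer(n_to)),
    class = "nn_distance_set"
  )
}

#' @export
print.nn_distance_set <- function(x, ...) {
  cat(sprintf("1-NN distances %s -> %s, sample %s: n=%d (n_from=%d, n_to=%d), median %.2f um\n",
              x$from_type, x$to_type, x$sample_id, length(x$distances),
              x$n_from, x$n_to, stats::median(x$distances)))
  invisible(x)
}

#' Smoothed unit-area 1-NN distance density
#'
#' Slides a `window`-micrometer window across the 1-NN distance histogram: at
#' each integer grid point t the distances falling in
#' \[t - window/2, t + window/2) are counted, and the resulting curve is
#' divided by its trapezoidal area so it integrates to one.
#'
#' @param d an `nn_distance_set` (or bare numeric vector of distances).
#' @param window sliding window width in micrometers.
#' @param step grid step in micrometers.
#' @return Object of class `smoothed_pdf`: list with `grid` (micrometers),
#'   `density` (per micrometer, unit trapezoidal area), `window`.
#' @export
smooth_nn_pdf <- function(d, window = 5, step = 1) {
  x <- if (inherits(d, "nn_distance_set")) d$distances else as.numeric(d)
  if (length(x) == 0L) stop("cannot smooth an empty distance set")
  grid <- seq(0, ceiling(max(x)) + window, by = step)
  half <- window / 2
  counts <- vapply(grid, function(t) sum(x >= t - half & x < t + half), numeric(1))
  area <- trapz(grid, counts)
  if (area <= 0) stop("degenerate distance set: smoothed curve has zero area")
  structure(list(grid = grid, density = counts / area, window = window),
            class = "smoothed_pdf")
}

#' Empirical G-function (cumulative 1-NN distance distribution)
#'
#' G(r) = fraction of 1-NN distances <= r, evaluated on a regular grid. The
#' raw empirical CDF is the primary estimator; a reduced-sample (border
#' corrected) variant can be requested by supplying per-reference-cell border
#' distances.
#'
#' @param d an `nn_distance_set` or numeric vector of distances.
#' @param r_max grid maximum in micrometers (default: max distance).
#' @param step grid step in micrometers.
#' @param border_dist optional numeric vector (same length as the distances)
#'   of each reference cell's distance to the window border; when supplied,
#'   the reduced-sample estimator G(r) = #(d_i <= r, b_i >= r) / #(b_i >= r)
#'   is used.
#' @return Object of class `g_curve`: list with `r`, `G`.
#' @export
empirical_g_curve <- function(d, r_max = NULL, step = 1, border_dist = NULL) {
  x <- if (inherits(d, "nn_distance_set")) d$distances else as.numeric(d)
  if (length(x) == 0L) stop("cannot compute a G-function from an empty distance set")
  r_max <- r_max %||% max(x)
  r <- seq(0, r_max, by = step)
  if (r[length(r)] < r_max) r <- c(r, r_max)
  if (is.null(border_dist)) {
    G <- vapply(r, function(ri) mean(x <= ri), numeric(1))
  } else {
    stopifnot(length(border_dist) == length(x))
    G <- vapply(r, function(ri) {
      at_risk <- border_dist >= ri
      if (!any(at_risk)) return(NA_real_)
      mean(x[at_risk] <= ri)
    }, numeric(1))
    # carry the last defined value forward so the curve stays monotone-usable
    for (i in seq_along(G)[-1L]) if (is.na(G[i])) G[i] <- G[i - 1L]
  }
  structure(list(r = r, G = G), class = "g_curve")
}

#' Area under the G-function up to a threshold
#'
#' Trapezoidal integral of G over \[0, T\] (micrometers); the G-AUC-T summary.
#' If T exceeds the computed grid, the curve is extended at its saturated
#' value G = 1.
#'
#' @param g a `g_curve`.
#' @param T threshold in micrometers (> 0).
#' @return The G-AUC-T in micrometers.
#' @export
g_auc <- function(g, T) {
  stopifnot(T > 0)
  r <- g$r
  G <- g$G
  if (T > max(r)) {
    r <- c(r, T)
    G <- c(G, 1)
  }
  keep <- r <= T
  r2 <- r[keep]
  G2 <- G[keep]
  if (max(r2) < T) {
    # interpolate the curve value exactly at T
    GT <- stats::approx(r, G, xout = T, rule = 2)$y
    r2 <- c(r2, T)
    G2 <- c(G2, GT)
  }
  trapz(r2, G2)
}
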