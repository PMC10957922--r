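#' Split a slide into tissue foci by density-based clustering
#'
#' Labels each cell with a focus id using DBSCAN on all cells of each sample
#' (defaults: epsilon neighborhood 300 um, minimum 50 points). Tissue islands
#' become foci 1, 2, ...; cells not density-reachable from any core point are
#' noise and get focus id -1.
#'
#' @param ct a [cell_table()] (one or more samples).
#' @param eps neighborhood radius in micrometers.
#' @param min_pts minimum number of points (including the point itself) within
#'   `eps` for a core point.
#' @return The cell table with `focus_id` assigned.
#' @export
split_foci <- function(ct, eps = 300, min_pts = 50) {
  ct <- validate_cell_table(ct)
  for (sid in unique(ct$sample_id)) {
    sel <- ct$sample_id == sid
    ct$focus_id[sel] <- dbscan_labels(cbind(ct$x[sel], ct$y[sel]), eps, min_pts)
  }
  ct
}

# Classic DBSCAN on a 2-column coordinate matrix. Neighborhoods are found by
# chunked exact distance computation (point counts here are slide-scale, not
# image-scale). Returns integer labels, -1 for noise.
dbscan_labels <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  if (n == 0L) return(integer(0))
  eps2 <- eps^2
  # neighbor lists, chunked to bound memory
  nbrs <- vector("list", n)
  chunk <- max(1L, floor(4e6 / n))
  start <- 1L
  while (start <= n) {
    end <- min(start + chunk - 1L, n)
    idx <- start:end
    dx <- outer(xy[idx, 1L], xy[, 1L], "-")
    dy <- outer(xy[idx, 2L], xy[, 2L], "-")
    d2 <- dx * dx + dy * dy
    for (k in seq_along(idx)) nbrs[[idx[k]]] <- which(d2[k, ] <= eps2)
    start <- end + 1L
  }
  core <- lengths(nbrs) >= min_pts
  labels <- rep(NA_integer_, n)
  cluster <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cluster <- cluster + 1L
    labels[i] <- cluster
    frontier <- nbrs[[i]]
    while (length(frontier)) {
      unlab <- frontier[is.na(labels[frontier])]
      labels[unlab] <- cluster
      # expand only through core points
      expand <- unlab[core[unlab]]
      frontier <- unique(unlist(nbrs[expand], use.names = FALSE))
      frontier <- frontier[is.na(labels[frontier])]
    }
  }
  labels[is.na(labels)] <- -1L
  labels
}
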