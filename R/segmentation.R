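# Tumor/stroma segmentation: per-focus kernel intensity surfaces of cancer and
# negative cells, compared after max-normalization.

# Build the per-focus cancer ("tumor") and negative surfaces on a shared grid.
# Returns a list keyed by "<sample>|<focus>" with elements tumor, negative
# (intensity_surface or NULL when that type is absent) and the focus row index.
focus_surfaces <- function(ct, pixel_size = 10, bandwidth = "auto",
                           fallback_bandwidth = 30) {
  ct <- validate_cell_table(ct)
  if (all(is.na(ct$focus_id))) {
    stop("focus ids are unassigned; run split_foci() first")
  }
  key <- paste(ct$sample_id, ct$focus_id, sep = "|")
  out <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    sub <- ct[rows, , drop = FALSE]
    surfs <- list(tumor = NULL, negative = NULL)
    pts <- list(tumor = cbind(sub$x, sub$y)[sub$cell_type == "cancer", , drop = FALSE],
                negative = cbind(sub$x, sub$y)[sub$cell_type == "negative", , drop = FALSE])
    # one bandwidth per surface; pad the shared grid by 3x the widest kernel
    bws <- lapply(pts, function(p) {
      if (nrow(p) == 0L) return(NULL)
      if (identical(bandwidth, "auto")) {
        if (nrow(p) < 2L) fallback_bandwidth else {
          win0 <- c(range(sub$x), range(sub$y))
          select_bandwidth_ppl(p, win0)
        }
      } else bandwidth
    })
    pad <- 3 * max(unlist(bws), fallback_bandwidth)
    win <- c(min(sub$x) - pad, max(sub$x) + pad, min(sub$y) - pad, max(sub$y) + pad)
    for (nm in c("tumor", "negative")) {
      if (nrow(pts[[nm]]) > 0L) {
        surfs[[nm]] <- compute_intensity_surface(
          pts[[nm]], win, pixel_size = pixel_size,
          bandwidth = bws[[nm]], normalize = TRUE
        )
      }
    }
    out[[k]] <- list(rows = rows, tumor = surfs$tumor, negative = surfs$negative)
  }
  out
}

#' Assign tumor/stroma compartments
#'
#' For each focus, the kernel intensity surfaces of cancer cells and of
#' negative cells are computed and max-normalized; a cell is labeled
#' `"tumor"` when the normalized cancer surface strictly exceeds the
#' normalized negative surface at its position (bilinear interpolation), and
#' `"stroma"` otherwise. Foci with no cancer cells are entirely stroma; foci
#' with no negative cells are entirely tumor.
#'
#' @param ct a [cell_table()] with focus ids assigned (see [split_foci()]).
#' @param pixel_size pixel side in micrometers for the intensity grids.
#' @param bandwidth `"auto"` (likelihood cross-validation per surface) or a
#'   fixed bandwidth in micrometers.
#' @return The cell table with `compartment` filled in.
#' @export
assign_compartments <- function(ct, pixel_size = 10, bandwidth = "auto") {
  surfs <- focus_surfaces(ct, pixel_size, bandwidth)
  for (k in names(surfs)) {
    s <- surfs[[k]]
    rows <- s$rows
    if (is.null(s$tumor)) {
      ct$compartment[rows] <- "stroma"
    } else if (is.null(s$negative)) {
      ct$compartment[rows] <- "tumor"
    } else {
      kt <- interp_surface(s$tumor, ct$x[rows], ct$y[rows])
      kn <- interp_surface(s$negative, ct$x[rows], ct$y[rows])
      ct$compartment[rows] <- ifelse(kt > kn, "tumor", "stroma")
    }
  }
  ct
}

#' Compute tumor, stroma and total tissue areas
#'
#' Per focus: the tumor area is the aggregated area of pixels whose
#' max-normalized cancer-cell surface is >= `threshold`; the total tissue
#' area uses the sum of the two max-normalized surfaces (renormalized to its
#' own maximum) at the same threshold; stroma = total - tumor (clipped at 0
#' with a warning if numerically negative). Areas are summed across foci per
#' sample.
#'
#' @param ct a [cell_table()] with focus ids assigned.
#' @param pixel_size,bandwidth as in [assign_compartments()].
#' @param threshold normalized-intensity cutoff defining tissue extent.
#' @return data.frame of class `compartment_areas` with one row per
#'   (sample_id, focus_id): `tumor_area`, `stroma_area`, `total_area` in um^2.
#' @export
compute_compartment_areas <- function(ct, pixel_size = 10, bandwidth = "auto",
                                      threshold = 0.1) {
  surfs <- focus_surfaces(ct, pixel_size, bandwidth)
  res <- lapply(names(surfs), function(k) {
    s <- surfs[[k]]
    parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
    px2 <- NA_real_
    zt <- zn <- NULL
    if (!is.null(s$tumor)) { zt <- s$tumor$z; px2 <- s$tumor$pixel_size^2 }
    if (!is.null(s$negative)) { zn <- s$negative$z; px2 <- s$negative$pixel_size^2 }
    tumor_area <- if (is.null(zt)) 0 else px2 * sum(zt >= threshold)
    ztot <- if (is.null(zt)) zn else if (is.null(zn)) zt else zt + zn
    total_area <- if (is.null(ztot)) 0 else {
      m <- max(ztot)
      if (m > 0) px2 * sum(ztot / m >= threshold) else 0
    }
    stroma_area <- total_area - tumor_area
    if (stroma_area < 0) {
      warning("negative stroma area clipped to 0 for focus ", k)
      stroma_area <- 0
    }
    data.frame(sample_id = parts[1L], focus_id = as.integer(parts[2L]),
               tumor_area = tumor_area, stroma_area = stroma_area,
               total_area = total_area, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- unique(c("compartment_areas", class(out)))
  out
}

#' Trim distal stroma
#'
#' Removes stroma-compartment cells whose nearest cancer cell (same sample,
#' whole slide) lies farther than `max_dist` micrometers, aligning tumor
#' purity across cohorts with different sampling. Tumor-compartment cells are
#' never removed. A sample with no cancer cells is returned unchanged with a
#' warning.
#'
#' @param ct a [cell_table()] with compartments assigned.
#' @param max_dist trim distance in micrometers.
#' @return The trimmed cell table.
#' @export
trim_distal_stroma <- function(ct, max_dist = 150) {
  ct <- validate_cell_table(ct)
  if (any(is.na(ct$compartment))) {
    stop("compartments are unassigned; run assign_compartments() first")
  }
  keep <- rep(TRUE, nrow(ct))
  for (sid in unique(ct$sample_id)) {
    sel <- which(ct$sample_id == sid)
    cancer <- sel[ct$cell_type[sel] == "cancer"]
    if (length(cancer) == 0L) {
      warning("sample ", sid, " has no cancer cells; distal-stroma trim skipped")
      next
    }
    stroma <- sel[ct$compartment[sel] == "stroma"]
    if (length(stroma) == 0L) next
    d <- nn_dist_chunked(cbind(ct$x[stroma], ct$y[stroma]),
                         cbind(ct$x[cancer], ct$y[cancer]))
    keep[stroma[d > max_dist]] <- FALSE
  }
  out <- ct[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
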