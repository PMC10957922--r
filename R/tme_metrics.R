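# Compartment immune-cell densities and exclusion ratios, and the per-sample
# metrics matrix that feeds the association battery.

#' Immune-cell density in a tissue compartment
#'
#' Count of cells of a type inside a compartment divided by the compartment
#' area, reported per mm^2 (1 mm^2 = 1e6 um^2). A zero compartment area
#' yields `NA` (undefined, flagged), not an error.
#'
#' @param ct a segmented [cell_table()] for one sample.
#' @param cell_type a label from [cell_types()].
#' @param compartment `"tumor"` or `"stroma"`.
#' @param areas the sample's [compute_compartment_areas()] rows.
#' @return Density in cells/mm^2, or `NA_real_` when the area is zero.
#' @export
compartment_density <- function(ct, cell_type, compartment, areas) {
  stopifnot(compartment %in% c("tumor", "stroma"))
  sid <- unique(ct$sample_id)
  stopifnot(length(sid) == 1L)
  a <- areas[areas$sample_id == sid, , drop = FALSE]
  area_um2 <- sum(a[[paste0(compartment, "_area")]])
  if (!is.finite(area_um2) || area_um2 <= 0) return(NA_real_)
  n <- sum(ct$cell_type == cell_type & ct$compartment == compartment,
           na.rm = TRUE)
  n / area_um2 * 1e6
}

#' Stromal-to-intratumoral exclusion ratio
#'
#' Ratio of stromal to intratumoral density of an immune cell type, used as a
#' proxy for excluded vs. inflamed immune phenotypes. A 0.5-cell continuity
#' correction is added to both counts so the ratio stays finite and
#' log-transformable when a compartment holds no cells:
#' ratio = ((n_stroma + 0.5)/area_stroma) / ((n_tumor + 0.5)/area_tumor).
#'
#' @inheritParams compartment_density
#' @param correction continuity correction in cells (0 disables it).
#' @return The exclusion ratio, or `NA_real_` if either area is zero.
#' @export
exclusion_ratio <- function(ct, cell_type, areas, correction = 0.5) {
  sid <- unique(ct$sample_id)
  stopifnot(length(sid) == 1L)
  a <- areas[areas$sample_id == sid, , drop = FALSE]
  area_s <- sum(a$stroma_area)
  area_t <- sum(a$tumor_area)
  if (area_s <= 0 || area_t <= 0) return(NA_real_)
  n_s <- sum(ct$cell_type == cell_type & ct$compartment == "stroma", na.rm = TRUE)
  n_t <- sum(ct$cell_type == cell_type & ct$compartment == "tumor", na.rm = TRUE)
  ((n_s + correction) / area_s) / ((n_t + correction) / area_t)
}

#' Assemble the per-sample metrics matrix
#'
#' One row per sample; columns are machine-parsable metric names:
#' `density_<type>_<compartment>` (cells/mm^2), `exclusion_<type>`,
#' and per-relationship `shape_<from>.<to>`, `scale_<from>.<to>`,
#' `median_<from>.<to>` (from the mixed-model per-sample parameters) plus
#' `gauc<T>_<from>.<to>` (empirical G-AUC-T).
#'
#' @param ct segmented cohort [cell_table()].
#' @param areas [compute_compartment_areas()] output for the cohort.
#' @param fits optional named list of converged `weibull_fit` objects keyed
#'   `"from->to"`.
#' @param g_aucs optional named list (same keys) of per-sample named numeric
#'   vectors per threshold, as produced by the pipeline.
#' @return data.frame of class `metrics_matrix`, rows = samples.
#' @export
build_metrics_matrix <- function(ct, areas, fits = NULL, g_aucs = NULL) {
  sids <- unique(ct$sample_id)
  out <- data.frame(sample_id = sids, stringsAsFactors = FALSE)
  for (ty in immune_cell_types()) {
    for (comp in c("tumor", "stroma")) {
      col <- paste0("density_", ty, "_", comp)
      out[[col]] <- vapply(sids, function(sid) {
        compartment_density(ct[ct$sample_id == sid, ], ty, comp, areas)
      }, numeric(1))
    }
    out[[paste0("exclusion_", ty)]] <- vapply(sids, function(sid) {
      exclusion_ratio(ct[ct$sample_id == sid, ], ty, areas)
    }, numeric(1))
  }
  for (key in names(fits %||% list())) {
    fit <- fits[[key]]
    if (!isTRUE(fit$converged)) next
    safe <- gsub("->", ".", key, fixed = TRUE)
    ps <- fit$per_sample
    idx <- match(sids, ps$sample_id)
    out[[paste0("shape_", safe)]] <- ps$shape[idx]
    out[[paste0("scale_", safe)]] <- ps$scale[idx]
    out[[paste0("median_", safe)]] <- ps$median_1nn[idx]
  }
  for (key in names(g_aucs %||% list())) {
    safe <- gsub("->", ".", key, fixed = TRUE)
    per_thr <- g_aucs[[key]]
    for (thr in names(per_thr)) {
      v <- per_thr[[thr]]
      out[[paste0("gauc", thr, "_", safe)]] <- unname(v[sids])
    }
  }
  class(out) <- unique(c("metrics_matrix", class(out)))
  out
}

#' Write / read a metrics matrix (TSV)
#'
#' Deterministic column order, one row per sample; values round-trip through
#' [read_metrics()] to within 1e-12.
#'
#' @param m a `metrics_matrix`.
#' @param path file path.
#' @return `path` (write) / the `metrics_matrix` (read).
#' @export
write_metrics <- function(m, path) {
  if (is.null(m) || nrow(m) == 0L) stop("refusing to write an empty metrics matrix")
  df <- as.data.frame(m)
  df <- df[, c("sample_id", sort(setdiff(names(df), "sample_id"))), drop = FALSE]
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  df$sample_id <- as.character(df$sample_id)
  class(df) <- unique(c("metrics_matrix", class(df)))
  df
}
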