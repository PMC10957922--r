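# One-command orchestration: segment -> 1-NN -> mixed-model fits -> metrics
# -> association battery, with per-unit error isolation and a JSON manifest.

#' All 49 ordered cell-type pairs
#'
#' The 7 x 7 ordered pairs (including self-self), keyed `"from->to"`.
#'
#' @return Character vector of 49 SR keys.
#' @export
all_sr_pairs <- function() {
  g <- expand.grid(to = cell_types(), from = cell_types(),
                   stringsAsFactors = FALSE)
  paste0(g$from, "->", g$to)
}

#' Pipeline configuration
#'
#' @param cells a cohort [cell_table()] or path to a cell-table TSV/CSV.
#' @param labels optional [cohort_labels()] or path to a labels CSV.
#' @param pairs `"all"` (the 49 ordered pairs) or a character vector of
#'   `"from->to"` keys.
#' @param eps,min_pts focus-splitting parameters ([split_foci()]).
#' @param pixel_size,bandwidth segmentation grid parameters.
#' @param trim_stroma distal-stroma trim distance in um, or `NULL` to skip.
#' @param g_thresholds G-AUC-T thresholds in um.
#' @param fdr_threshold significance level on the BH-adjusted q-values.
#' @param controls a [fit_controls()].
#' @param window,step smoothing parameters for the 1-NN densities.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in the manifest.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cells, labels = NULL, pairs = "all",
                            eps = 300, min_pts = 50,
                            pixel_size = 10, bandwidth = "auto",
                            trim_stroma = NULL,
                            g_thresholds = c(25, 50, 100),
                            fdr_threshold = 0.10,
                            controls = fit_controls(),
                            window = 5, step = 1,
                            out_dir = tempfile("weibullsr_"), seed = 1) {
  stopifnot(all(g_thresholds > 0), fdr_threshold > 0)
  if (is.character(cells)) {
    if (!file.exists(cells)) stop("cells file not found: ", cells)
  }
  if (is.character(labels) && !file.exists(labels)) {
    stop("labels file not found: ", labels)
  }
  if (identical(pairs, "all")) pairs <- all_sr_pairs()
  structure(list(cells = cells, labels = labels, pairs = pairs,
                 eps = eps, min_pts = min_pts, pixel_size = pixel_size,
                 bandwidth = bandwidth, trim_stroma = trim_stroma,
                 g_thresholds = g_thresholds, fdr_threshold = fdr_threshold,
                 controls = controls, window = window, step = step,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with fields named as in [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  ctrl_args <- y$controls %||% list()
  y$controls <- do.call(fit_controls, ctrl_args)
  do.call(pipeline_config, y)
}

#' Enumerate SR fitting units
#'
#' One unit per (sample, ordered cell-type pair); with 24 samples and all 49
#' pairs this enumerates 1176 units.
#'
#' @param sample_ids character vector of sample ids.
#' @param pairs character vector of `"from->to"` keys (default all 49).
#' @return data.frame with `sample_id`, `sr_key`, `status`
#'   (initially `"pending"`).
#' @export
enumerate_sr_units <- function(sample_ids, pairs = all_sr_pairs()) {
  units <- expand.grid(sr_key = pairs, sample_id = sample_ids,
                       stringsAsFactors = FALSE)[, c("sample_id", "sr_key")]
  units$status <- "pending"
  units$reason <- NA_character_
  rownames(units) <- NULL
  units
}

#' Run the full spatial-relationship analysis pipeline
#'
#' Segments each slide (foci, tumor/stroma compartments, areas, optional
#' distal-stroma trim), computes 1-NN distances for every (sample, ordered
#' pair) unit, fits the Weibull mixed model per pair with the sequential
#' cell-count filter ladder, assembles the per-sample metrics matrix
#' (densities, exclusion ratios, per-SR shape/scale/median, empirical
#' G-AUC-T), and, when labels are supplied, runs the differential battery.
#' Per-unit errors are recorded and never abort the remaining units; every
#' unit terminates in exactly one of `fit`, `filtered_at_<level>`,
#' `rejected` or `errored`, recorded in the JSON manifest along with output
#' checksums.
#'
#' @param cfg a [pipeline_config()].
#' @return List with `units`, `fits`, `metrics`, `areas`, `differential`,
#'   `manifest` (also written under `cfg$out_dir`).
#' @export
run_full_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
  }

  cells <- if (is.character(cfg$cells)) read_cell_table(cfg$cells) else
    validate_cell_table(cfg$cells)
  labels <- if (is.character(cfg$labels)) {
    read_cohort_labels(cfg$labels, sample_ids = unique(cells$sample_id))
  } else cfg$labels

  say("segmenting %d sample(s)", length(unique(cells$sample_id)))
  cells <- split_foci(cells, eps = cfg$eps, min_pts = cfg$min_pts)
  cells <- assign_compartments(cells, pixel_size = cfg$pixel_size,
                               bandwidth = cfg$bandwidth)
  areas <- compute_compartment_areas(cells, pixel_size = cfg$pixel_size,
                                     bandwidth = cfg$bandwidth)
  if (!is.null(cfg$trim_stroma)) {
    cells <- withCallingHandlers(
      trim_distal_stroma(cells, max_dist = cfg$trim_stroma),
      warning = function(w) {
        say("trim: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  }

  sids <- unique(cells$sample_id)
  units <- enumerate_sr_units(sids, cfg$pairs)
  set_status <- function(sr, sid, status, reason = NA_character_) {
    sel <- units$sr_key == sr & units$sample_id %in% sid
    units$status[sel] <<- status
    units$reason[sel] <<- reason
  }

  fits <- list()
  g_aucs <- list()
  for (sr in cfg$pairs) {
    ft <- sub("->.*$", "", sr)
    tt <- sub("^.*->", "", sr)
    sets <- list()
    for (sid in sids) {
      res <- tryCatch(
        cross_nn_distances(cells[cells$sample_id == sid, ], ft, tt),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        set_status(sr, sid, "filtered_at_none", conditionMessage(res))
      } else {
        sets[[sid]] <- res
      }
    }
    if (length(sets) < 3L) {
      set_status(sr, names(sets), "rejected", "fewer than 3 samples with distances")
      say("SR %s rejected: %d sample(s) with distances", sr, length(sets))
      next
    }
    fit <- tryCatch(
      sequential_filter_fit(sets, controls = cfg$controls,
                            window = cfg$window, step = cfg$step),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      set_status(sr, names(sets), "errored", conditionMessage(fit))
      say("SR %s errored: %s", sr, conditionMessage(fit))
      next
    }
    fits[[sr]] <- fit
    if (isTRUE(fit$converged)) {
      set_status(sr, fit$samples_used, "fit")
      dropped <- names(fit$samples_filtered %||% character(0))
      if (length(dropped)) {
        set_status(sr, dropped, paste0("filtered_at_", fit$filter_level),
                   "below cell-count filter level")
      }
      say("SR %s converged at filter level %s (%d samples)",
          sr, fit$filter_level, length(fit$samples_used))
    } else {
      set_status(sr, names(sets), "rejected", fit$failure)
      say("SR %s rejected after filter ladder: %s", sr, fit$failure)
    }
    # empirical G-AUC-T per sample
    per_thr <- lapply(cfg$g_thresholds, function(T) {
      v <- vapply(sets, function(s) {
        g <- empirical_g_curve(s, r_max = max(max(s$distances), T))
        g_auc(g, T)
      }, numeric(1))
      v
    })
    names(per_thr) <- as.character(cfg$g_thresholds)
    g_aucs[[sr]] <- per_thr
  }
  units$status[units$status == "pending"] <- "errored"

  metrics <- build_metrics_matrix(cells, areas, fits = fits, g_aucs = g_aucs)
  differential <- NULL
  if (!is.null(labels)) {
    differential <- differential_test(metrics, labels)
    say("differential battery: %d metric(s), %d significant at q < %.2f",
        nrow(differential), sum(differential$fdr < cfg$fdr_threshold, na.rm = TRUE),
        cfg$fdr_threshold)
  }

  # write artifacts
  paths <- list(
    cells = file.path(cfg$out_dir, "cells_segmented.tsv"),
    areas = file.path(cfg$out_dir, "areas.tsv"),
    metrics = file.path(cfg$out_dir, "metrics.tsv"),
    units = file.path(cfg$out_dir, "sr_units.tsv"),
    fits = file.path(cfg$out_dir, "fits.json")
  )
  write_cell_table(cells, paths$cells)
  utils::write.table(areas, paths$areas, sep = "\t", quote = FALSE, row.names = FALSE)
  write_metrics(metrics, paths$metrics)
  utils::write.table(units, paths$units, sep = "\t", quote = FALSE, row.names = FALSE)
  fit_summaries <- lapply(fits, function(f) list(
    sr_key = f$sr_key, converged = f$converged, filter_level = f$filter_level,
    population = f$population, random_effect_sd = as.list(f$re_sd),
    residual_sd = f$sigma, per_sample = f$per_sample
  ))
  jsonlite::write_json(fit_summaries, paths$fits, auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (!is.null(differential)) {
    paths$differential <- file.path(cfg$out_dir, "differential.tsv")
    utils::write.table(differential, paths$differential, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  status_counts <- table(units$status)
  manifest <- list(
    seed = cfg$seed,
    n_samples = length(sids),
    n_pairs = length(cfg$pairs),
    n_units = nrow(units),
    unit_status_counts = as.list(status_counts),
    files = lapply(paths, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(cfg$out_dir, "pipeline.log"))

  list(units = units, fits = fits, metrics = metrics, areas = areas,
       differential = differential, manifest = manifest, cells = cells,
       g_aucs = g_aucs, out_dir = cfg$out_dir)
}
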