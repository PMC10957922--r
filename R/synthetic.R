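# Seed-reproducible synthetic cohorts: homogeneous Poisson patterns for
# closed-form oracles, Thomas-process tumor nests with immune infiltration
# for end-to-end cohorts, and Weibull distance cohorts with known
# random-effect structure for fit-recovery checks.

#' Simulation configuration for a synthetic cohort
#'
#' Defaults emulate a mIF cohort of 24 tissue slides (14 responders, 10
#' non-responders) on a 1000 x 1000 um window: cancer cells in dense
#' Thomas-process nests, negative cells filling the surrounding stroma, and
#' rarer immune populations whose proximity to cancer cells differs by
#' response group (infiltrating in responders, excluded in non-responders).
#'
#' @param window `c(width, height)` in micrometers.
#' @param n_responders,n_non_responders samples per group.
#' @param n_nests,nest_radius tumor nest count and Gaussian nest radius (um).
#' @param cancer_per_nest mean cancer cells per nest.
#' @param negative_intensity stromal negative-cell intensity (cells/um^2).
#' @param immune_counts named vector of mean immune cells per slide.
#' @param architecture `"tumor_nests"` (response-modulated immune proximity,
#'   the default), `"csr"` (every type completely spatially random),
#'   `"inflamed"` (all samples infiltrated) or `"excluded"` (all samples
#'   excluded).
#' @param infiltration_sd responder immune placement: Gaussian offset SD (um)
#'   around a random cancer cell (small = tight infiltration; default gives
#'   a median immune-to-cancer 1-NN distance of about 4 um).
#' @param exclusion_d0 non-responder immune placement: preferred distance
#'   (um) from the nearest cancer cell; candidates at distance d are kept
#'   with probability exp(-((d - d0)/tau)^2 / 2) (default targets a median
#'   1-NN distance near 18 um).
#' @param exclusion_tau width (um) of the exclusion distance kernel.
#' @param seed mandatory integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(window = c(1000, 1000),
                       n_responders = 14, n_non_responders = 10,
                       architecture = c("tumor_nests", "csr", "inflamed",
                                        "excluded"),
                       n_nests = 5, nest_radius = 60,
                       cancer_per_nest = 150,
                       negative_intensity = 8e-4,
                       immune_counts = c(cd8_t = 80, t_helper = 60,
                                         macrophage = 60, b_cell = 40,
                                         foxp3_t = 30),
                       infiltration_sd = 5,
                       exclusion_d0 = 22,
                       exclusion_tau = 8,
                       seed) {
  stopifnot(all(window > 0), !missing(seed))
  if (2 * n_nests * nest_radius > max(window)) {
    stop("infeasible config: nests larger than the window")
  }
  structure(list(window = window, n_responders = n_responders,
                 n_non_responders = n_non_responders,
                 architecture = match.arg(architecture),
                 n_nests = n_nests,
                 nest_radius = nest_radius, cancer_per_nest = cancer_per_nest,
                 negative_intensity = negative_intensity,
                 immune_counts = immune_counts,
                 infiltration_sd = infiltration_sd,
                 exclusion_d0 = exclusion_d0,
                 exclusion_tau = exclusion_tau,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Homogeneous Poisson (CSR) point pattern
#'
#' Count ~ Poisson(intensity * area), positions uniform on the window.
#'
#' @param intensity points per um^2 (>= 0).
#' @param window `c(width, height)` um.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return n x 2 matrix of coordinates.
#' @export
simulate_poisson_pattern <- function(intensity, window, seed = NULL) {
  stopifnot(intensity >= 0)
  with_seed(seed, {
    n <- stats::rpois(1L, intensity * window[1L] * window[2L])
    cbind(x = stats::runif(n, 0, window[1L]), y = stats::runif(n, 0, window[2L]))
  })
}

# Thomas cluster process: Poisson parents, Gaussian offspring, clipped to the
# window. `parents` may be supplied to share nest centers across cell types.
simulate_thomas <- function(n_parents, mean_offspring, sigma, window,
                            parents = NULL) {
  if (is.null(parents)) {
    parents <- cbind(stats::runif(n_parents, 0, window[1L]),
                     stats::runif(n_parents, 0, window[2L]))
  }
  pts <- do.call(rbind, lapply(seq_len(nrow(parents)), function(i) {
    m <- stats::rpois(1L, mean_offspring)
    if (m == 0L) return(NULL)
    cbind(stats::rnorm(m, parents[i, 1L], sigma),
          stats::rnorm(m, parents[i, 2L], sigma))
  }))
  if (is.null(pts)) pts <- matrix(numeric(0), 0, 2)
  keep <- pts[, 1L] >= 0 & pts[, 1L] <= window[1L] &
    pts[, 2L] >= 0 & pts[, 2L] <= window[2L]
  pts[keep, , drop = FALSE]
}

# Place immune cells relative to cancer cells: attracted (Gaussian offsets
# around random cancer cells) or excluded (uniform candidates thinned by a
# Gaussian kernel on the distance to the nearest cancer cell, centered at a
# preferred distance d0).
place_immune <- function(n, cancer_xy, window, mode, infiltration_sd,
                         exclusion_d0, exclusion_tau) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  if (nrow(cancer_xy) == 0L || mode == "csr") {
    return(cbind(stats::runif(n, 0, window[1L]), stats::runif(n, 0, window[2L])))
  }
  if (mode == "attract") {
    anchors <- cancer_xy[sample.int(nrow(cancer_xy), n, replace = TRUE), , drop = FALSE]
    pts <- anchors + matrix(stats::rnorm(2L * n, 0, infiltration_sd), n, 2L)
    pts[, 1L] <- pmin(pmax(pts[, 1L], 0), window[1L])
    pts[, 2L] <- pmin(pmax(pts[, 2L], 0), window[2L])
    return(pts)
  }
  # excluded: distance-kernel thinning of uniform candidates
  out <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(out) < n && tries < 60L) {
    m <- max(4L * (n - nrow(out)), 50L)
    cand <- cbind(stats::runif(m, 0, window[1L]), stats::runif(m, 0, window[2L]))
    d <- nn_dist_chunked(cand, cancer_xy)
    acc <- stats::runif(m) < exp(-0.5 * ((d - exclusion_d0) / exclusion_tau)^2)
    out <- rbind(out, cand[acc, , drop = FALSE])
    tries <- tries + 1L
  }
  out[seq_len(min(n, nrow(out))), , drop = FALSE]
}

#' Simulate a synthetic tumor-microenvironment cohort
#'
#' Per sample: cancer cells in Thomas-process nests, negative cells as a CSR
#' stromal background, and immune populations placed near cancer cells in
#' responders (Gaussian infiltration) and pushed away from them in
#' non-responders (distance-kernel thinning), so immune-to-cancer proximity
#' separates the groups.
#'
#' @param cfg a [sim_config()].
#' @return List with `cells` (a cohort [cell_table()]) and `labels`
#'   (a [cohort_labels()]).
#' @export
simulate_tme_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    groups <- c(rep("responder", cfg$n_responders),
                rep("non_responder", cfg$n_non_responders))
    tabs <- lapply(seq_along(groups), function(i) {
      sid <- sprintf("S%02d", i)
      win <- cfg$window
      if (cfg$architecture == "csr") {
        area <- win[1L] * win[2L]
        cancer <- simulate_poisson_pattern(
          cfg$n_nests * cfg$cancer_per_nest / area, win)
      } else {
        parents <- cbind(stats::runif(cfg$n_nests, 0.15 * win[1L], 0.85 * win[1L]),
                         stats::runif(cfg$n_nests, 0.15 * win[2L], 0.85 * win[2L]))
        cancer <- simulate_thomas(cfg$n_nests, cfg$cancer_per_nest,
                                  cfg$nest_radius, win, parents = parents)
      }
      negative <- simulate_poisson_pattern(cfg$negative_intensity, win)
      rows <- list(
        data.frame(x = cancer[, 1L], y = cancer[, 2L], cell_type = "cancer"),
        data.frame(x = negative[, 1L], y = negative[, 2L], cell_type = "negative")
      )
      mode <- switch(cfg$architecture,
        csr = "csr",
        inflamed = "attract",
        excluded = "exclude",
        tumor_nests = if (groups[i] == "responder") "attract" else "exclude"
      )
      for (ty in names(cfg$immune_counts)) {
        n_ty <- stats::rpois(1L, cfg$immune_counts[[ty]])
        pts <- place_immune(n_ty, cancer, win, mode,
                            cfg$infiltration_sd, cfg$exclusion_d0,
                            cfg$exclusion_tau)
        if (nrow(pts)) {
          rows[[length(rows) + 1L]] <-
            data.frame(x = pts[, 1L], y = pts[, 2L], cell_type = ty)
        }
      }
      df <- do.call(rbind, rows)
      df$sample_id <- sid
      df
    })
    all <- do.call(rbind, tabs)
    cells <- cell_table(all$sample_id, all$x, all$y, all$cell_type)
    labels <- cohort_labels(sprintf("S%02d", seq_along(groups)), groups)
    list(cells = cells, labels = labels)
  })
}

#' Scenario presets spanning the scale/shape quadrants
#'
#' Two-type point-pattern presets reproducing the four canonical SR regimes:
#' `"packed_target"` (low scale, high shape: dense CSR targets, a target is
#' always near), `"comingled"` (low scale, low shape: both types share dense
#' overlapping clusters), `"dispersed"` (high scale, low shape: few sparse
#' target clusters, CSR references, wide distance spread) and `"repulsion"`
#' (high scale, high shape: reference and target clusters mutually displaced,
#' distances concentrated at a large offset). Reference cells are `cd8_t`,
#' target cells `cancer`.
#'
#' @param preset one of `"packed_target"`, `"comingled"`, `"dispersed"`,
#'   `"repulsion"`.
#' @param n_samples samples to generate.
#' @param window `c(width, height)` um.
#' @param seed integer seed.
#' @return A cohort [cell_table()].
#' @export
simulate_sr_scenario <- function(preset = c("packed_target", "comingled",
                                            "dispersed", "repulsion"),
                                 n_samples = 8, window = c(800, 800),
                                 seed = 1) {
  preset <- match.arg(preset)
  with_seed(seed, {
    tabs <- lapply(seq_len(n_samples), function(i) {
      win <- window
      # between-sample abundance heterogeneity, as in real cohorts
      jit <- stats::rlnorm(1, 0, 0.25)
      if (preset == "packed_target") {
        target <- simulate_poisson_pattern(0.01 * jit, win)
        ref <- simulate_poisson_pattern(1.2e-4, win)
      } else if (preset == "comingled") {
        parents <- cbind(stats::runif(8, 0, win[1L]), stats::runif(8, 0, win[2L]))
        target <- simulate_thomas(8, 60 * jit, 15, win, parents = parents)
        ref <- simulate_thomas(8, 12, 15, win, parents = parents)
      } else if (preset == "dispersed") {
        target <- simulate_thomas(5, 30 * jit, 25, win)
        ref <- simulate_poisson_pattern(1.5e-4, win)
      } else { # repulsion: clusters of each type displaced from the other
        tpar <- cbind(stats::runif(3, 0.20 * win[1L], 0.30 * win[1L]),
                      stats::runif(3, 0.35 * win[2L], 0.65 * win[2L]))
        rpar <- cbind(stats::runif(3, 0.50 * win[1L], 0.60 * win[1L]),
                      stats::runif(3, 0.35 * win[2L], 0.65 * win[2L]))
        target <- simulate_thomas(3, 60 * jit, 35, win, parents = tpar)
        ref <- simulate_thomas(3, 30, 35, win, parents = rpar)
      }
      df <- rbind(
        data.frame(x = target[, 1L], y = target[, 2L], cell_type = "cancer"),
        data.frame(x = ref[, 1L], y = ref[, 2L], cell_type = "cd8_t")
      )
      df$sample_id <- sprintf("S%02d", i)
      df
    })
    all <- do.call(rbind, tabs)
    cell_table(all$sample_id, all$x, all$y, all$cell_type)
  })
}

#' Simulate a Weibull distance cohort with known random-effect structure
#'
#' Per sample, (A_i, B_i) ~ N((pop_A, pop_B), diag(re_sd_A^2, re_sd_B^2)) is
#' drawn on the unconstrained scale, mapped through the logistic links to
#' (shape_i, scale_i), and `n_distances` 1-NN distances are sampled from
#' Weibull(shape_i, scale_i). The oracle for mixed-model parameter recovery.
#'
#' @param pop_A,pop_B population fixed effects (unconstrained scale).
#' @param re_sd_A,re_sd_B random-effect standard deviations (>= 0).
#' @param n_samples number of samples.
#' @param n_distances distances per sample.
#' @param seed integer seed.
#' @return Named list of `nn_distance_set` objects with attribute
#'   `"truth"` (data.frame of the generating per-sample parameters).
#' @export
simulate_weibull_cohort <- function(pop_A = 0, pop_B = 0,
                                    re_sd_A = 0.3, re_sd_B = 0.2,
                                    n_samples = 24, n_distances = 2000,
                                    seed = 1) {
  stopifnot(re_sd_A >= 0, re_sd_B >= 0)
  with_seed(seed, {
    ids <- sprintf("S%02d", seq_len(n_samples))
    A_i <- stats::rnorm(n_samples, pop_A, re_sd_A)
    B_i <- stats::rnorm(n_samples, pop_B, re_sd_B)
    shape_i <- SHAPE_SUP / (1 + exp(-A_i))
    scale_i <- SCALE_SUP / (1 + exp(-B_i))
    sets <- lapply(seq_len(n_samples), function(i) {
      d <- stats::rweibull(n_distances, shape = shape_i[i], scale = scale_i[i])
      nn_distance_set(ids[i], "cd8_t", "cancer", d,
                      n_from = n_distances, n_to = n_distances)
    })
    names(sets) <- ids
    attr(sets, "truth") <- data.frame(sample_id = ids, A = A_i, B = B_i,
                                      shape = shape_i, scale = scale_i,
                                      stringsAsFactors = FALSE)
    sets
  })
}
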