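# Shared fixtures, all generated in code.

# Brute-force all-pairs 1-NN oracle (kept independent of nn_dist_chunked).
brute_nn <- function(from, to, self = FALSE) {
  vapply(seq_len(nrow(from)), function(i) {
    d2 <- (to[, 1L] - from[i, 1L])^2 + (to[, 2L] - from[i, 2L])^2
    if (self) d2[i] <- Inf
    sqrt(min(d2))
  }, numeric(1))
}

# Independent trapezoid rule for test-side integration.
trapz_test <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Hand-written Benjamini-Hochberg step-up (oracle for p.adjust-based code).
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Trapezoidal ROC AUC oracle: integrate TPR over FPR across all thresholds.
trapezoid_auc <- function(scores, is_case) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(s) mean(scores[is_case] >= s), numeric(1)), 1)
  fpr <- c(0, vapply(thr, function(s) mean(scores[!is_case] >= s), numeric(1)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Small two-blob slide: dense cancer blob at the left, negative blob at the
# right, `gap` um apart (centers), for segmentation checks.
make_two_blob_slide <- function(n_per_blob = 250, gap = 500, seed = 1,
                                sample_id = "S01") {
  set.seed(seed)
  cancer <- cbind(rnorm(n_per_blob, 200, 40), rnorm(n_per_blob, 300, 40))
  negative <- cbind(rnorm(n_per_blob, 200 + gap, 40), rnorm(n_per_blob, 300, 40))
  cell_table(
    sample_id = sample_id,
    x = c(cancer[, 1], negative[, 1]),
    y = c(cancer[, 2], negative[, 2]),
    cell_type = rep(c("cancer", "negative"), each = n_per_blob)
  )
}

# Tiny valid cell-table TSV on disk; returns the path.
write_tiny_cell_tsv <- function(path, extra_row = NULL) {
  lines <- c(
    "sample_id\tx\ty\tcell_type",
    "S1\t0\t0\tcancer",
    "S1\t3\t4\tcd8_t",
    "S1\t10\t10\tnegative"
  )
  writeLines(c(lines, extra_row), path)
  path
}
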