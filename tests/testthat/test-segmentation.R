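test_that("focus splitting separates distant blobs and flags sparse noise", {
  set.seed(21)
  blob1 <- cbind(runif(100, 0, 100), runif(100, 0, 100))
  blob2 <- cbind(runif(100, 1100, 1200), runif(100, 0, 100))
  ct <- cell_table("S1", c(blob1[, 1], blob2[, 1]), c(blob1[, 2], blob2[, 2]),
                   rep("cancer", 200))
  ct <- split_foci(ct)
  expect_equal(length(setdiff(unique(ct$focus_id), -1L)), 2L)
  # blobs are 1000 um apart (> eps): no focus spans both
  expect_equal(length(unique(ct$focus_id[1:100])), 1L)
  expect_false(unique(ct$focus_id[1:100]) == unique(ct$focus_id[101:200]))

  tiny <- cell_table("S1", runif(10, 0, 100), runif(10, 0, 100),
                     rep("cancer", 10))
  tiny <- split_foci(tiny)
  expect_true(all(tiny$focus_id == -1L))
})

test_that("a dense blob forms one focus matching brute-force density-reachability", {
  set.seed(22)
  pts <- cbind(runif(500, 0, 400), runif(500, 0, 400))
  ct <- cell_table("S1", pts[, 1], pts[, 2], rep("negative", 500))
  ct <- split_foci(ct)
  expect_equal(unique(ct$focus_id), 1L)
  # oracle: with eps = 300 > blob diameter/2 every point is core and mutually
  # reachable, so a single cluster is forced
  d <- as.matrix(dist(pts))
  expect_true(all(rowSums(d <= 300) >= 50))
})

test_that("intensity surfaces are deterministic, peaked and max-normalized", {
  s1 <- compute_intensity_surface(cbind(50, 50), c(0, 100, 0, 100),
                                  pixel_size = 2, bandwidth = 10,
                                  normalize = TRUE)
  expect_equal(max(s1$z), 1)
  peak <- which(s1$z == 1, arr.ind = TRUE)
  expect_lt(abs(s1$x[peak[1]] - 50), 2)
  expect_lt(abs(s1$y[peak[2]] - 50), 2)

  set.seed(4)
  pts <- cbind(runif(100, 0, 200), runif(100, 0, 200))
  sA <- compute_intensity_surface(pts, c(0, 200, 0, 200), bandwidth = 15)
  sB <- compute_intensity_surface(pts, c(0, 200, 0, 200), bandwidth = 15)
  expect_identical(sA$z, sB$z)
  expect_error(compute_intensity_surface(cbind(1, 1), c(0, 10, 0, 10)),
               "bandwidth")
})

test_that("CSR cover: normalized intensity exceeds 0.1 over the interior", {
  set.seed(31)
  pts <- cbind(runif(2000, 0, 1000), runif(2000, 0, 1000))
  s <- compute_intensity_surface(pts, c(0, 1000, 0, 1000), bandwidth = "auto",
                                 normalize = TRUE)
  margin <- 2 * s$bandwidth
  ix <- s$x > margin & s$x < 1000 - margin
  iy <- s$y > margin & s$y < 1000 - margin
  interior <- s$z[ix, iy]
  expect_gte(mean(interior > 0.1), 0.95)
})

test_that("two-blob slides segment with >=95% compartment accuracy", {
  ct <- make_two_blob_slide(seed = 101)
  ct <- split_foci(ct)
  ct <- assign_compartments(ct)
  cancer_acc <- mean(ct$compartment[ct$cell_type == "cancer"] == "tumor")
  negative_acc <- mean(ct$compartment[ct$cell_type == "negative"] == "stroma")
  expect_gte(cancer_acc, 0.95)
  expect_gte(negative_acc, 0.95)
})

test_that("degenerate foci follow the comparison rule's limits", {
  set.seed(33)
  onlyc <- cell_table("S1", runif(60, 0, 100), runif(60, 0, 100),
                      rep("cancer", 60))
  onlyc <- split_foci(onlyc, min_pts = 10)
  onlyc <- assign_compartments(onlyc)
  expect_true(all(onlyc$compartment == "tumor"))

  onlyn <- cell_table("S1", runif(60, 0, 100), runif(60, 0, 100),
                      rep("negative", 60))
  onlyn <- split_foci(onlyn, min_pts = 10)
  onlyn <- assign_compartments(onlyn)
  expect_true(all(onlyn$compartment == "stroma"))
})

test_that("compartment assignment is invariant under rigid motions", {
  ct <- make_two_blob_slide(n_per_blob = 120, seed = 7)
  ct <- split_foci(ct)
  base <- assign_compartments(ct, bandwidth = 25)
  th <- 0.7
  rot <- ct
  rot$x <- cos(th) * ct$x - sin(th) * ct$y + 400
  rot$y <- sin(th) * ct$x + cos(th) * ct$y - 150
  moved <- assign_compartments(rot, bandwidth = 25)
  expect_equal(moved$compartment, base$compartment)
})

test_that("areas: slab coverage, stroma identity, and threshold monotonicity", {
  set.seed(35)
  slab <- cell_table("S1", runif(4000, 0, 1000), runif(4000, 0, 1000),
                     rep("cancer", 4000))
  slab <- split_foci(slab)
  ar <- compute_compartment_areas(slab)
  expect_lt(abs(ar$tumor_area - 1e6) / 1e6, 0.15)
  expect_equal(ar$stroma_area, ar$total_area - ar$tumor_area)

  mixed <- make_two_blob_slide(seed = 36)
  mixed <- split_foci(mixed)
  a_strict <- compute_compartment_areas(mixed, bandwidth = 30, threshold = 0.1)
  a_loose <- compute_compartment_areas(mixed, bandwidth = 30, threshold = 0.05)
  expect_gte(sum(a_loose$tumor_area), sum(a_strict$tumor_area))
  expect_gte(sum(a_loose$total_area), sum(a_strict$total_area))

  empty <- cell_table(character(0), numeric(0), numeric(0), character(0))
  expect_error(compute_compartment_areas(empty), "unassigned")
})

test_that("distal-stroma trim removes exactly the distal stroma cells", {
  ct <- cell_table(
    "S1",
    x = c(0, 100, 200, 0),
    y = c(0, 0, 0, 50),
    cell_type = c("cancer", "negative", "negative", "negative"),
    compartment = c("tumor", "stroma", "stroma", "stroma")
  )
  ct$focus_id <- 1L
  out <- trim_distal_stroma(ct, max_dist = 150)
  # the stroma cell at x=200 (200 um from the only cancer cell) must go,
  # the ones at 100 and ~50 um stay, the tumor cell is untouched
  expect_equal(nrow(out), 3L)
  expect_false(any(out$x == 200 & out$cell_type == "negative"))

  no_cancer <- cell_table("S1", c(0, 10), c(0, 0), c("negative", "negative"),
                          compartment = c("stroma", "stroma"))
  expect_warning(kept <- trim_distal_stroma(no_cancer), "no cancer cells")
  expect_equal(nrow(kept), 2L)
})
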