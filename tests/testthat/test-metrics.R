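test_that("volume and overlap fractions follow voxel counting", {
  d <- c(10L, 10L, 10L)
  nuc <- array(TRUE, d)
  m <- cuboid_mask(d, 1:4, 1:5, 1:5)   # 100 voxels in a 1000-voxel nucleus
  expect_equal(volume_fraction(m, nuc), 0.10)
  expect_equal(volume_fraction(nuc, nuc), 1.0)
  expect_equal(volume_fraction(array(FALSE, d), nuc), 0.0)
  expect_error(volume_fraction(m, array(FALSE, d)), "empty nucleus")

  big <- cuboid_mask(c(30L, 12L, 12L), 1:20, 1:10, 1:10)
  ref <- cuboid_mask(c(30L, 12L, 12L), 1:10, 1:10, 1:10)
  expect_equal(overlap_fraction(big, ref), 1.0)
  expect_equal(overlap_fraction(ref, big), 0.5)
  expect_equal(overlap_fraction(ref, ref), 1.0)
  disj <- cuboid_mask(c(30L, 12L, 12L), 25:28, 1:4, 1:4)
  expect_equal(overlap_fraction(disj, ref), 0.0)
  expect_error(overlap_fraction(ref, array(FALSE, dim(ref))), "empty reference")
})

test_that("intermixing is the covered fraction of the target", {
  d <- c(12L, 12L, 12L)
  target <- cuboid_mask(d, 1:4, 1:4, 1:4)
  half <- cuboid_mask(d, 1:2, 1:4, 1:4)
  far <- cuboid_mask(d, 9:12, 9:12, 9:12)
  expect_equal(intermixing_fraction(target, list(far)), 0.0)
  expect_equal(intermixing_fraction(target, list(half, far)), 0.5)
  expect_equal(intermixing_fraction(target, list(target)), 1.0)
  expect_error(intermixing_fraction(array(FALSE, d), list(half)), "empty target")
})

test_that("contact means overlap or 26-adjacency", {
  d <- c(10L, 10L, 10L)
  a <- cuboid_mask(d, 1:3, 1:3, 1:3)
  b_overlap <- cuboid_mask(d, 3:5, 1:3, 1:3)
  b_face <- cuboid_mask(d, 4:6, 1:3, 1:3)
  b_gap <- cuboid_mask(d, 6:8, 1:3, 1:3)
  b_diag <- cuboid_mask(d, 4:5, 4:5, 4:5)   # corner-touching
  expect_true(in_contact(a, b_overlap))
  expect_true(in_contact(a, b_face))
  expect_true(in_contact(a, b_diag))
  expect_false(in_contact(a, b_gap))
  expect_false(in_contact(a, b_face, mode = "intersection"))
  expect_true(in_contact(a, b_overlap, mode = "intersection"))
})

test_that("minimal edge distance is the anisotropic pairwise minimum", {
  d <- c(16L, 16L, 16L)
  a <- cuboid_mask(d, 2, 2, 2)
  b <- cuboid_mask(d, 2, 2, 12)
  expect_equal(min_edge_distance(a, b, c(1, 1, 1)), 10)
  bz <- cuboid_mask(d, 4, 2, 2)
  expect_equal(min_edge_distance(a, bz, c(3, 1, 1)), 6)   # 2 voxels along z
  expect_equal(min_edge_distance(a, a, c(1, 1, 1)), 0)
  expect_error(min_edge_distance(a, array(FALSE, d), c(1, 1, 1)), "empty")
})

test_that("overlap/contact/distance invariants hold on random mask pairs", {
  set.seed(31)
  for (i in 1:20) {
    dims <- c(sample(6:14, 1), sample(6:14, 1), sample(6:14, 1))
    a <- rand_mask(dims, 0.15)
    b <- rand_mask(dims, 0.15)
    if (!any(a) || !any(b)) next
    # reciprocity
    expect_equal(overlap_fraction(a, b) * sum(b),
                 overlap_fraction(b, a) * sum(a), tolerance = 1e-12)
    # contact consistency: intersection implies contact; distance 0 iff overlap
    dist <- min_edge_distance(a, b, c(1, 1, 1))
    expect_identical(dist == 0, any(a & b))
    if (any(a & b)) expect_true(in_contact(a, b))
    # dilating A never decreases O(A|B)
    a_dil <- array(cpp_dilate26(a, dims), dims)
    expect_gte(overlap_fraction(a_dil, b), overlap_fraction(a, b))
  }
})

test_that("compacity hits the analytic shape limits", {
  expect_gte(compacity(ball_mask(20), c(1, 1, 1)), 0.95)
  cube <- array(TRUE, c(20L, 20L, 20L))
  expect_equal(as.numeric(compacity(cube, c(1, 1, 1))), (pi / 6)^(1 / 3),
               tolerance = 0.03 / 0.806)
  rod <- array(TRUE, c(1L, 1L, 100L))
  expect_lt(compacity(rod, c(1, 1, 1)), 0.30)
  # equal-volume boxes, increasingly elongated: strictly decreasing
  psis <- c(compacity(array(TRUE, c(20L, 20L, 20L)), c(1, 1, 1)),
            compacity(array(TRUE, c(13L, 13L, 50L)), c(1, 1, 1)),
            compacity(array(TRUE, c(8L, 8L, 126L)), c(1, 1, 1)))
  expect_true(all(diff(psis) < 0))
  # tiny masks are flagged unreliable but still scored
  tiny <- cuboid_mask(c(6L, 6L, 6L), 2:3, 2, 2)
  psi <- compacity(tiny, c(1, 1, 1))
  expect_true(isTRUE(attr(psi, "unreliable")))
  expect_true(psi > 0 && psi <= 1)
  expect_error(compacity(array(FALSE, c(4, 4, 4)), c(1, 1, 1)), "empty")
})

test_that("shell partition is equal-count, ordered, and center-seeking", {
  nuc <- ball_mask(12)
  sp <- c(1, 1, 1)
  shells <- shell_partition(nuc, 5L, sp)
  counts <- tabulate(shells[shells > 0L], 5L)
  expect_true(max(counts) - min(counts) <= 1L)
  expect_equal(sum(counts), sum(nuc))
  # the center voxel is in the innermost shell
  ctr <- (dim(nuc) + 1L) %/% 2L
  expect_equal(shells[ctr[1], ctr[2], ctr[3]], 5L)
  # distances are ordered across shells
  dist <- cpp_edt(!nuc, dim(nuc), sp)
  expect_lt(max(dist[shells == 1L]), min(dist[shells == 5L]))
  expect_error(shell_partition(cuboid_mask(c(4L, 4L, 4L), 1, 1, 1:3), 5L, sp),
               "smaller")
})

test_that("shell distributions are normalised fractions", {
  nuc <- ball_mask(10)
  sp <- c(1, 1, 1)
  shells <- shell_partition(nuc, 5L, sp)
  f_all <- shell_distribution(nuc, shells)
  expect_equal(sum(f_all), 1.0)
  expect_equal(f_all, rep(0.2, 5), tolerance = 1e-3)
  ctr <- (dim(nuc) + 1L) %/% 2L
  blob <- cuboid_mask(dim(nuc), ctr[1] + (-1:1), ctr[2] + (-1:1), ctr[3] + (-1:1))
  expect_equal(shell_distribution(blob, shells), c(0, 0, 0, 0, 1))
  set.seed(32)
  rnd <- nuc & rand_mask(dim(nuc), 0.3)
  expect_equal(sum(shell_distribution(rnd, shells)), 1.0)
  expect_error(shell_distribution(array(FALSE, dim(nuc)), shells), "empty")
})

test_that("a noiseless render measures back its exact ground truth", {
  p <- tiny_params(psf_sigma = c(0, 0, 0), read_noise_sd = 0,
                   shot_noise = FALSE, background = 0, seed = 41)
  tr <- simulate_cell(p)
  st <- render_microscopy(tr)
  # a perfect counterstain: the nucleoplasm texture is part of realistic
  # renders, but this check is about exact mask recovery
  st$voxels[, , , match("dna", st$channels)] <- 150 * tr$nucleus
  thr <- setNames(rep(list(c(low = 75, high = 75)), 3), names(tr$masks))
  cell <- segment_cell(st, thresholds = thr, background_subtract = FALSE,
                       refine = FALSE, min_volume = 0)
  # the DNA channel renders the nucleus; Otsu recovers it exactly
  expect_identical(cell$nucleus, tr$nucleus, ignore_attr = TRUE)
  mm <- measure_cell(cell)
  for (a in names(tr$masks)) for (b in names(tr$masks)) {
    if (a == b) next
    col <- paste0("ovf_", a, "_given_", b)
    expect_equal(mm[[col]], tr$overlap[a, b], tolerance = 1e-12)
  }
})

test_that("an empty channel yields missing fields without aborting the cell", {
  p <- tiny_params(seed = 42)
  tr <- simulate_cell(p)
  st <- render_microscopy(tr)
  # append a channel with no structure at all (flat background)
  d <- dim(st$voxels)
  vox <- array(0, c(d[1:3], d[4] + 1L))
  vox[, , , seq_len(d[4])] <- st$voxels
  vox[, , , d[4] + 1L] <- 100
  st2 <- ct_stack(vox, st$spacing, c(st$channels, "chEmpty"), st$cell_id)
  cell <- segment_cell(st2)
  mm <- measure_cell(cell)
  expect_true(is.na(mm$vol_chEmpty))
  expect_true(is.na(mm$paired_chEmpty))
  expect_false(is.na(mm$vol_chA))
  expect_true(is.na(mm$ovf_chA_given_chEmpty))
  expect_false(is.na(mm$ovf_chA_given_chB))
})
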