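test_that("stacks round-trip through OME-TIFF losslessly", {
  set.seed(11)
  for (shape in list(c(8L, 16L, 16L, 2L), c(3L, 7L, 5L, 1L), c(2L, 4L, 4L, 4L))) {
    vox <- array(sample(0:65535, prod(shape), replace = TRUE), shape)
    st <- ct_stack(vox, spacing = c(0.25, 0.1, 0.1),
                   channels = paste0("ch", seq_len(shape[4])), cell_id = "rt")
    path <- withr::local_tempfile(fileext = ".ome.tif")
    write_stack(st, path)
    back <- read_stack(path)
    expect_identical(dim(back$voxels), shape)
    expect_equal(back$voxels, st$voxels * 1.0, ignore_attr = TRUE)
    expect_equal(back$spacing, st$spacing)
    expect_identical(back$channels, st$channels)
    expect_identical(back$cell_id, "rt")
  }
})

test_that("spacing comes from OME metadata, config wins on mismatch", {
  vox <- array(sample(0:100, 2 * 4 * 6 * 6, replace = TRUE), c(4, 6, 6, 2))
  st <- ct_stack(vox, spacing = c(0.25, 0.1, 0.1), channels = c("dna", "chA"))
  path <- withr::local_tempfile(fileext = ".ome.tif")
  write_stack(st, path)
  expect_equal(read_stack(path)$spacing, c(0.25, 0.1, 0.1))
  expect_warning(
    back <- read_stack(path, config = list(spacing = c(0.5, 0.2, 0.2))),
    "config wins"
  )
  expect_equal(back$spacing, c(0.5, 0.2, 0.2))
})

test_that("channel count mismatch is an explicit error naming both counts", {
  pages <- lapply(1:3, function(i) matrix(i, 4, 5))
  path <- withr::local_tempfile(fileext = ".tif")
  write_tiff(pages, path, bits = 8L)
  expect_error(read_stack(path, config = list(channels = c("a", "b"),
                                              spacing = c(1, 1, 1))),
               "3 pages.*2 channels")
})

test_that("masks round-trip as 8-bit TIFF, including empty and full", {
  set.seed(12)
  masks <- list(
    rand_mask(c(5L, 9L, 7L), 0.3),
    array(FALSE, c(4L, 6L, 6L)),
    array(TRUE, c(4L, 6L, 6L))
  )
  for (m in masks) {
    path <- withr::local_tempfile(fileext = ".tif")
    write_mask(m, path, spacing = c(0.3, 0.1, 0.1))
    back <- read_mask(path)
    expect_identical(back$mask, m, ignore_attr = TRUE)
    expect_equal(back$spacing, c(0.3, 0.1, 0.1))
    expect_equal(sum(back$labels), sum(m) * 255L)
  }
})

test_that("physical quantities rescale consistently with voxel spacing", {
  set.seed(13)
  sp <- c(0.2, 0.1, 0.1)
  a <- cuboid_mask(c(10L, 20L, 20L), 2:4, 3:8, 3:8)
  b <- cuboid_mask(c(10L, 20L, 20L), 7:9, 12:16, 12:16)
  v1 <- sum(a) * prod(sp)
  d1 <- min_edge_distance(a, b, sp)
  for (f in c(2, 0.5)) {
    expect_equal(sum(a) * prod(sp * f), v1 * f^3)
    expect_equal(min_edge_distance(a, b, sp * f), d1 * f)
  }
})
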