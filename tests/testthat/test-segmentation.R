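test_that("hysteresis keeps or drops the dim ring depending on `low`", {
  # bright core ringed by intermediate intensity on dark background
  img <- array(10, c(16L, 16L, 16L))
  img[7:10, 7:10, 7:10] <- 200   # core
  img[6:11, 6:11, 6:11][img[6:11, 6:11, 6:11] == 10] <- 120  # ring
  hs <- hysteresis_segment(img, low = 100, high = 150, min_volume = 0,
                           spacing = c(1, 1, 1))
  expect_equal(nrow(hs$volumes), 1L)
  expect_equal(sum(hs$labels > 0), sum(img >= 100))
  expect_true(same_partition(hs$labels, bf_hysteresis(img, 100, 150)))
  # raising low excludes the ring
  hs2 <- hysteresis_segment(img, low = 150, high = 150, min_volume = 0,
                            spacing = c(1, 1, 1))
  expect_equal(sum(hs2$labels > 0), sum(img == 200))
  # nothing above low: no components
  hs3 <- hysteresis_segment(img, low = 300, high = 300, min_volume = 0,
                            spacing = c(1, 1, 1))
  expect_equal(nrow(hs3$volumes), 0L)
  expect_error(hysteresis_segment(img, low = 200, high = 100,
                                  spacing = c(1, 1, 1)), "low")
})

test_that("lowering `low` never shrinks a component (superset property)", {
  set.seed(21)
  for (i in 1:10) {
    img <- array(sample(0:255, 14^3, replace = TRUE), c(14L, 14L, 14L))
    hi <- 220
    m1 <- hysteresis_segment(img, low = 150, high = hi, min_volume = 0,
                             spacing = c(1, 1, 1))$labels > 0
    m2 <- hysteresis_segment(img, low = 100, high = hi, min_volume = 0,
                             spacing = c(1, 1, 1))$labels > 0
    expect_true(all(m2[m1]))
  }
})

test_that("auto thresholds match the exhaustive Otsu oracle on bimodal data", {
  set.seed(22)
  vox <- array(10, c(8L, 10L, 10L))
  vox[3:6, 3:6, 3:6] <- 200
  vox <- vox + sample(0:3, length(vox), replace = TRUE)
  st <- ct_stack(vox, c(1, 1, 1), "chA")
  nuc <- array(TRUE, dim(vox))
  thr <- auto_thresholds(st, "chA", nuc)
  oracle <- bf_otsu(as.numeric(vox))
  expect_gt(thr[["high"]], 13)            # above the background mode
  expect_lt(thr[["high"]], 200)           # below the signal mode
  expect_lt(abs(thr[["high"]] - oracle), 5)  # near the exhaustive optimum
  expect_equal(thr[["low"]], thr[["high"]] / 2)
  # config overrides are verbatim
  expect_equal(auto_thresholds(st, "chA", nuc, low = 40, high = 90),
               c(low = 40, high = 90))
  # constant channel cannot be thresholded
  flat <- ct_stack(array(7, c(4, 4, 4)), c(1, 1, 1), "chA")
  expect_error(auto_thresholds(flat, "chA", array(TRUE, c(4, 4, 4))),
               "constant")
})

test_that("nucleus segmentation fills holes and keeps the largest blob", {
  vox <- array(10, c(12L, 20L, 20L))
  vox[3:9, 4:14, 4:14] <- 200
  vox[6, 8, 8] <- 0                       # interior hole
  vox[10:11, 17:19, 17:19] <- 200         # smaller second blob
  st <- ct_stack(vox, c(0.25, 0.1, 0.1), "dna")
  nuc <- segment_nucleus(st, "dna")
  expect_true(nuc[6, 8, 8])               # hole filled
  expect_false(any(nuc[10:11, 17:19, 17:19]))  # smaller blob dropped
  expect_false(attr(nuc, "border_touching"))
  # a blob on the border is flagged
  vox2 <- array(10, c(8L, 10L, 10L))
  vox2[1:4, 2:8, 2:8] <- 200
  nuc2 <- segment_nucleus(ct_stack(vox2, c(0.25, 0.1, 0.1), "dna"), "dna")
  expect_true(attr(nuc2, "border_touching"))
})

test_that("nucleus recovery on a rendered synthetic cell reaches IoU >= 0.9", {
  p <- tiny_params(seed = 17)
  tr <- simulate_cell(p)
  st <- render_microscopy(tr)
  nuc <- segment_nucleus(st, "dna")
  iou <- sum(nuc & tr$nucleus) / sum(nuc | tr$nucleus)
  expect_gte(iou, 0.9)
})

test_that("LoG spot detection finds rendered foci at their true centers", {
  set.seed(23)
  d <- c(24L, 48L, 48L)
  sp <- c(0.25, 0.1, 0.1)
  k <- 6L
  centers <- cbind(sample(6:18, k), sample(8:40, k), sample(8:40, k))
  img <- array(0, d)
  sig_um <- c(0.3, 0.15, 0.15)
  for (i in seq_len(k)) {
    img[centers[i, 1], centers[i, 2], centers[i, 3]] <- 8000
  }
  img <- cpp_gaussian_blur(img, d, sig_um / sp)
  img <- img + rnorm(prod(d), 0, 0.5)
  dim(img) <- d
  st <- ct_stack(pmax(img, 0), sp, "foci")
  foci <- detect_spots_3d(st, "foci", scale_sigma = sig_um)
  expect_equal(nrow(foci), k)
  found <- cbind(foci$z / sp[1], foci$y / sp[2], foci$x / sp[3]) + 1
  for (i in seq_len(k)) {
    dd <- sqrt(rowSums(sweep(found, 2, centers[i, ])^2))
    expect_lte(min(dd), sqrt(3))   # within one voxel of a true center
  }
  # blank image: no foci
  blank <- ct_stack(array(0, d) + rnorm(prod(d), 10, 0.1), sp, "foci")
  expect_equal(nrow(detect_spots_3d(blank, "foci", sig_um)), 0L)
})

test_that("spot pairs resolve beyond 4 sigma and merge below 1 sigma", {
  d <- c(16L, 64L, 64L)
  sp <- c(1, 1, 1)
  sig <- c(2, 2, 2)
  render_pair <- function(sep_vox) {
    img <- array(0, d)
    img[8, 32, 32 - round(sep_vox / 2)] <- 5000
    img[8, 32, 32 + (sep_vox - round(sep_vox / 2))] <- 5000
    img <- cpp_gaussian_blur(img, d, sig)
    dim(img) <- d
    st <- ct_stack(img + 1e-6, sp, "foci")
    nrow(detect_spots_3d(st, "foci", scale_sigma = sig,
                         peak_threshold = max(img) * 0.05))
  }
  expect_equal(render_pair(9L), 2L)   # > 4 sigma apart
  expect_equal(render_pair(1L), 1L)   # < 1 sigma apart
})

test_that("pairing state counts signals above the speck filter", {
  expect_equal(pairing_state(c(5)), list(n_signals = 1L, paired = TRUE))
  expect_equal(pairing_state(c(5, 5)), list(n_signals = 2L, paired = FALSE))
  # 1000-voxel blob plus 20-voxel speck at relative_min 0.1: one signal
  expect_equal(pairing_state(c(1000, 20) * 1e-3, relative_min = 0.1),
               list(n_signals = 1L, paired = TRUE))
  expect_equal(pairing_state(numeric(0)), list(n_signals = 0L, paired = NA))
})
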