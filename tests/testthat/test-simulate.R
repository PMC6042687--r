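test_that("territory chains respect the confinement contract", {
  center <- c(4, 6.4, 6.4)
  radii <- c(1.6, 2.2, 2.2)
  # full pull: every bead within one step of the anchor
  ch <- generate_territory_chain(center, 50, 0.5, 1.0, center, radii, seed = 1)
  expect_true(all(sqrt(rowSums(sweep(ch, 2, center)^2)) <= 0.5 + 1e-12))
  # no pull, single bead: the chain is the anchor itself
  ch1 <- generate_territory_chain(center, 1, 0.5, 0, center, radii, seed = 2)
  expect_equal(ch1, matrix(center, 1, 3))
  # anchor outside the nucleus is rejected
  expect_error(
    generate_territory_chain(center + c(5, 0, 0), 5, 0.5, 0.5, center, radii),
    "outside"
  )
  # determinism in the seed
  expect_identical(
    generate_territory_chain(center, 30, 0.5, 0.3, center, radii, seed = 7),
    generate_territory_chain(center, 30, 0.5, 0.3, center, radii, seed = 7)
  )
})

test_that("stronger confinement compacts the walk (Monte-Carlo)", {
  center <- c(4, 6.4, 6.4)
  radii <- c(1.6, 2.2, 2.2)
  rg <- function(conf) {
    vapply(1:30, function(s) {
      ch <- generate_territory_chain(center, 60, 0.5, conf, center, radii,
                                     seed = 1000 + s)
      sqrt(mean(rowSums(sweep(ch, 2, colMeans(ch))^2)))
    }, 1)
  }
  expect_lt(mean(rg(0.9)), mean(rg(0.1)))
})

test_that("simulate_cell is deterministic and truth is contained/consistent", {
  p <- tiny_params(seed = 5)
  t1 <- simulate_cell(p)
  t2 <- simulate_cell(p)
  expect_identical(t1$masks, t2$masks)
  expect_identical(t1$overlap, t2$overlap)
  for (m in t1$masks) {
    expect_true(all(!m | t1$nucleus))  # every true mask inside the nucleus
  }
  ov <- t1$overlap
  off <- ov[row(ov) != col(ov)]
  expect_true(all(off >= 0 & off <= 1))
  # reciprocity: O(A|B) * V_B = O(B|A) * V_A (shared intersection volume)
  vols <- vapply(t1$masks, sum, 0)
  for (a in 1:2) for (b in (a + 1):3) {
    expect_equal(unname(ov[a, b] * vols[b]), unname(ov[b, a] * vols[a]),
                 tolerance = 1e-9)
  }
  # bead coordinates stay inside the nucleus ellipsoid
  ctr <- (p$grid_dim - 1L) * p$voxel_spacing / 2
  for (chains in t1$beads) for (ch in chains) {
    q <- sweep(ch, 2, ctr) / matrix(p$nucleus_radii, nrow(ch), 3, byrow = TRUE)
    expect_true(all(rowSums(q^2) <= 1 + 1e-9))
  }
})

test_that("pairing_prob = 1 collapses each channel to one signal cluster", {
  p <- tiny_params(pairing_prob = 1, seed = 9)
  tr <- simulate_cell(p)
  expect_true(all(tr$pairing))
  for (m in tr$masks) {
    lab <- bf_label(m, 26)
    expect_equal(max(lab), 1L)
  }
})

test_that("translocation elevates true donor-acceptor overlap (seed-paired)", {
  ov_da <- function(par) {
    vapply(1:30, function(i) {
      par$seed <- derive_seed(31L, i)
      simulate_cell(par)$overlap["chA", "chB"]
    }, 1)
  }
  base <- tiny_params()
  trans <- tiny_params(translocation = list(donor = "chA", acceptor = "chB",
                                            fraction = 0.3))
  expect_gt(median(ov_da(trans)), median(ov_da(base)))
})

test_that("rendering obeys the noiseless identity and is seed-deterministic", {
  p <- tiny_params(psf_sigma = c(0, 0, 0), read_noise_sd = 0, background = 50,
                   shot_noise = FALSE, seed = 3)
  tr <- simulate_cell(p)
  st <- render_microscopy(tr)
  for (ch in names(tr$masks)) {
    expect_equal(get_channel(st, ch),
                 p$photon_scale * tr$masks[[ch]] + 50, ignore_attr = TRUE)
  }
  p2 <- tiny_params(seed = 4)
  tr2 <- simulate_cell(p2)
  expect_identical(render_microscopy(tr2)$voxels, render_microscopy(tr2)$voxels)
})

test_that("doubling photon_scale doubles the in-mask signal within 2%", {
  ratios <- vapply(1:10, function(s) {
    p1 <- tiny_params(seed = 100 + s)
    tr <- simulate_cell(p1)
    st1 <- render_microscopy(tr, p1)
    p2 <- p1
    p2$photon_scale <- 2 * p1$photon_scale
    st2 <- render_microscopy(tr, p2)
    m <- tr$masks[[1]]
    bg <- p1$background
    mean(get_channel(st2, names(tr$masks)[1])[m] - bg) /
      mean(get_channel(st1, names(tr$masks)[1])[m] - bg)
  }, 1)
  expect_equal(mean(ratios), 2, tolerance = 0.02)
})

test_that("an undersampled PSF warns instead of failing", {
  p <- tiny_params(psf_sigma = c(0.01, 0.01, 0.01), seed = 2)
  tr <- simulate_cell(p)
  expect_warning(render_microscopy(tr), "undersampled")
})

test_that("parameter invariants are enforced", {
  expect_error(tiny_params(confinement = 1.2), "confinement")
  expect_error(tiny_params(pairing_prob = -0.1), "pairing_prob")
  expect_error(sim_params(channels = list(list(name = "a", n_chains = 1L,
                                               beads_per_chain = 10L,
                                               bead_radius = 0.05,
                                               step_length = 0.1))),
               "bead_radius")
  expect_error(tiny_params(band_probes = list(channel = "chA", cen = 1:10,
                                              mid = 8:20, tel = 30:40)),
               "disjoint")
  expect_error(tiny_params(translocation = list(donor = "chA", acceptor = "chA",
                                                fraction = 0.3)),
               "distinct")
})
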