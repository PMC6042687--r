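test_that("the classifier maps the 8 contact triples onto 8 distinct states", {
  grid <- expand.grid(cen_mid = c(FALSE, TRUE), mid_tel = c(FALSE, TRUE),
                      cen_tel = c(FALSE, TRUE))
  ids <- apply(grid, 1, function(r) {
    configuration_state_id(c(cen_mid = r[["cen_mid"]], mid_tel = r[["mid_tel"]],
                             cen_tel = r[["cen_tel"]]))
  })
  expect_equal(sort(ids), 0:7)
  closed <- ids[grid$cen_tel]
  expect_equal(sort(closed), 4:7)       # exactly the states with the high bit
  expect_equal(sum(grid$cen_tel), 4L)   # 4 closed, 4 open
})

test_that("mask-level classification follows the cen-tel contact rule", {
  d <- c(8L, 8L, 24L)
  cen <- cuboid_mask(d, 3:5, 3:5, 1:4)
  mid_far <- cuboid_mask(d, 3:5, 3:5, 10:13)
  tel_far <- cuboid_mask(d, 3:5, 3:5, 19:22)
  # none touching: open, state 0
  cfg0 <- classify_configuration(cen, mid_far, tel_far)
  expect_equal(cfg0$state_id, 0L)
  expect_false(cfg0$closed)
  # all three mutually touching: closed, all bits set
  mid_adj <- cuboid_mask(d, 3:5, 3:5, 5:8)
  tel_adj <- cuboid_mask(d, 3:5, 3:5, 4:7)   # touches both cen and mid
  cfg7 <- classify_configuration(cen, mid_adj, tel_adj)
  expect_equal(cfg7$state_id, 7L)
  expect_true(cfg7$closed)
  # only cen-tel touching: still closed (state 4)
  tel_on_cen <- cuboid_mask(d, 3:5, 3:5, 4:6)
  cfg4 <- classify_configuration(cen, mid_far, tel_on_cen)
  expect_equal(cfg4$state_id, 4L)
  expect_true(cfg4$closed)
  # an empty probe is unclassifiable, never silently open
  cfgNA <- classify_configuration(cen, array(FALSE, d), tel_far)
  expect_true(is.na(cfgNA$state_id))
  expect_true(is.na(cfgNA$closed))
})

test_that("configuration frequencies partition into open and closed halves", {
  cf <- configuration_frequencies(c(0L, 0L, 7L, 7L))
  expect_equal(cf$open_fraction, 0.5)
  expect_equal(cf$closed_fraction, 0.5)
  expect_equal(sum(cf$frequencies$fraction), 1.0)
  cf1 <- configuration_frequencies(rep(3L, 10))
  expect_equal(cf1$frequencies$fraction[cf1$frequencies$state == 3], 1.0)
  expect_equal(cf1$closed_fraction, 0.0)
  expect_equal(configuration_frequencies(c(NA, 5L))$n_missing, 1L)
  expect_error(configuration_frequencies(NA_integer_), "no classified")
})
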