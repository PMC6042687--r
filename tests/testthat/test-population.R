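test_that("aggregation takes medians over cells and frequencies of flags", {
  cells <- tibble::tibble(
    cell_id = sprintf("c%d", 1:4),
    volfrac_chA = c(0.1, 0.2, 0.15, 0.12),
    volfrac_chB = c(0.2, 0.25, 0.22, 0.21),
    ovf_chA_given_chB = c(0.1, 0.2, 0.3, NA),
    ovf_chB_given_chA = c(0.05, 0.1, 0.15, NA),
    contact_chA_chB = c(TRUE, TRUE, FALSE, FALSE),
    paired_chA = c(TRUE, TRUE, TRUE, FALSE),
    paired_chB = c(TRUE, TRUE, TRUE, TRUE)
  )
  s <- aggregate_cells(cells)
  expect_equal(s$overlap["chA", "chB"], 0.2)
  expect_equal(s$overlap_n["chA", "chB"], 3L)
  expect_equal(s$contact["chA", "chB"], 0.5)
  expect_equal(s$contact["chB", "chA"], 0.5)     # symmetric off-diagonal
  expect_equal(s$contact["chA", "chA"], 0.75)    # pairing on the diagonal
  expect_equal(s$contact["chB", "chB"], 1.0)
  td <- tidy(s)
  expect_true(all(td$value[td$metric == "contact_frequency"] >= 0 &
                    td$value[td$metric == "contact_frequency"] <= 1))
  expect_equal(glance(s)$n_cells, 4L)
})

test_that("r_squared matches the closed form and its conventions", {
  x <- 1:10
  expect_equal(r_squared(x, 2 * x), 1.0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 2)), 0.75)  # Sxy^2/(Sxx*Syy)
  expect_equal(r_squared(x, rep(5, 10)), 0.0)            # constant y
  expect_error(r_squared(rep(1, 5), 1:5), "constant")
  # affine invariance
  set.seed(51)
  y <- x + rnorm(10)
  expect_equal(r_squared(10 * x - 3, 0.5 * y + 7), r_squared(x, y))
})

test_that("tukey summaries use interpolated quartiles and 1.5 IQR fences", {
  ts <- tukey_summary(1:9)
  expect_equal(ts$median, 5)
  expect_equal(ts$q1, 3)
  expect_equal(ts$q3, 7)
  expect_equal(length(ts$outliers), 0L)
  tc <- tukey_summary(rep(4, 6))
  expect_equal(tc$q3 - tc$q1, 0)
  expect_equal(length(tc$outliers), 0L)
  to <- tukey_summary(c(1:9, 100))
  expect_equal(to$outliers, 100)
  expect_equal(to$whisker_high, 9)
})

test_that("group comparisons delegate to the standard exact/rank tests", {
  a <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  expect_gt(compare_groups(a, a, "rank_sum")$p_value, 0.9)   # identical groups
  f <- compare_groups(matrix(c(10, 0, 0, 10), 2, 2), kind = "fisher_2x2")
  expect_equal(f$p_value, 2 / choose(20, 10), tolerance = 1e-6)  # ~1.08e-5
  f2 <- compare_groups(matrix(c(5, 5, 5, 5), 2, 2), kind = "fisher_2x2")
  expect_equal(f2$p_value, 1.0)
  expect_error(compare_groups(numeric(0), a, "rank_sum"), "empty")
})

test_that("the translocation screen flags only elevated pairs", {
  mk_summary <- function(ovAB) {
    cells <- tibble::tibble(
      cell_id = sprintf("c%d", 1:5),
      volfrac_chA = runif(5), volfrac_chB = runif(5), volfrac_chC = runif(5),
      ovf_chA_given_chB = ovAB, ovf_chB_given_chA = ovAB,
      ovf_chA_given_chC = rep(0.05, 5), ovf_chC_given_chA = rep(0.05, 5),
      ovf_chB_given_chC = rep(0.05, 5), ovf_chC_given_chB = rep(0.05, 5)
    )
    aggregate_cells(cells)
  }
  none <- translocation_screen(mk_summary(rep(0.05, 5)))
  expect_false(any(none$flagged))
  one <- translocation_screen(mk_summary(rep(0.15, 5)))   # 3x the others
  expect_equal(one$flagged,
               one$channel_a == "chA" & one$channel_b == "chB")
})
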