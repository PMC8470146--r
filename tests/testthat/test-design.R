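test_that("design generation honours counts, bounds and the seed", {
  specs <- list(c(40, 4, 4), c(10, 0, 0), c(3, 5, 2))
  for (s in specs) {
    d <- generate_design(s[1], s[2], s[3], soa_bounds = c(2, 26), seed = 7)
    expect_equal(nrow(d), 3 * s[1] + s[2] + s[3])
    expect_equal(sum(d$condition == "AV"), 3 * s[1])
    expect_equal(sum(d$condition == "A"), s[2])
    expect_equal(sum(d$condition == "V"), s[3])
    soa <- diff(c(0, d$onset))
    expect_true(all(soa >= 2 & soa <= 26))
    expect_true(all(diff(d$onset) > 0))
  }
  d1 <- generate_design(5, 1, 1, c(2, 10), seed = 42)
  d2 <- generate_design(5, 1, 1, c(2, 10), seed = 42)
  expect_identical(d1, d2)
  d3 <- generate_design(5, 1, 1, c(2, 10), seed = 43)
  expect_false(identical(d1$onset, d3$onset))
})

test_that("empty and invalid designs are handled", {
  d0 <- generate_design(0, 0, 0, c(2, 26), seed = 1)
  expect_equal(nrow(d0), 0)
  expect_error(generate_design(5, 0, 0, c(0, 26), seed = 1),
               class = "bolddcm_invalid_argument")
  expect_error(generate_design(5, 0, 0, c(9, 2), seed = 1),
               class = "bolddcm_invalid_argument")
  expect_error(generate_design(40, 4, 4, c(2, 26), seed = 1,
                               session_length = 100),
               class = "bolddcm_invalid_argument")
})

test_that("rasterisation builds the right microtime grid", {
  d <- generate_design(40, 4, 4, c(2, 26), seed = 11)
  ip <- rasterize_inputs(d, n_scans = 261, bins_per_scan = 16,
                         scan_period = 8)
  expect_equal(nrow(ip$values), 4176)
  expect_equal(ncol(ip$values), 3)
  expect_true(all(ip$values %in% c(0, 1)))
  # counts are conserved per condition column
  expect_equal(unname(colSums(ip$values)), c(120, 4, 4))
  expect_equal(sum(ip$values), nrow(d))
  expect_equal(ip$bin_width, 0.5)
})

test_that("rasterisation rejects onsets beyond the session", {
  d <- generate_design(10, 1, 1, c(2, 10), seed = 3)
  expect_error(rasterize_inputs(d, n_scans = 2, bins_per_scan = 16,
                                scan_period = 2),
               "outside the session", class = "bolddcm_invalid_argument")
})

test_that("an empty design rasterises to an all-zero matrix", {
  d0 <- generate_design(0, 0, 0, c(2, 26), seed = 1)
  ip <- rasterize_inputs(d0, 10, 16, 2)
  expect_equal(sum(ip$values), 0)
  expect_equal(dim(ip$values), c(160, 3))
})
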