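test_that("the printed cohort mixture is sampled faithfully", {
  x <- sample_printed_mixture(635, seed = 2)
  # pooled age mean from mixture-mean arithmetic
  target <- 0.46 * 44.77 + 0.54 * 62.07
  pooled_sd <- sqrt(0.46 * 289.71 + 0.54 * 238.31 +
                      0.46 * 0.54 * (62.07 - 44.77)^2)
  expect_lt(abs(mean(x$age) - target), 3 * pooled_sd / sqrt(635))
  # component age SD at large n
  big <- sample_printed_mixture(20000, seed = 3)
  s1 <- stats::sd(big$age[big$component == "negative"])
  expect_lt(abs(s1 - sqrt(289.71)) / sqrt(289.71), 0.03)
  # single draw and determinism
  one <- sample_printed_mixture(1, seed = 4)
  expect_equal(nrow(one), 1)
  expect_identical(sample_printed_mixture(50, seed = 9),
                   sample_printed_mixture(50, seed = 9))
})

test_that("cohort sampling reproduces requested group deltas", {
  neg <- negative_responder_model()
  spec <- cohort_spec(n_subjects = 500,
                      base_parameters = list(negative = neg, positive = neg),
                      group_deltas = c("A:lSMA->rM1" = 0.3), seed = 21)
  coh <- sample_cohort(spec)
  g <- coh$group
  expect_setequal(unique(g), c("negative", "positive"))
  v <- coh$theta[, "A:lSMA->rM1"]
  diffm <- mean(v[g == "positive"]) - mean(v[g == "negative"])
  se <- sqrt(stats::var(v[g == "positive"]) / sum(g == "positive") +
               stats::var(v[g == "negative"]) / sum(g == "negative"))
  expect_lt(abs(diffm - 0.3), 3 * se)
  # reproducibility and the single-subject edge case
  expect_identical(sample_cohort(spec)$theta, coh$theta)
  one <- sample_cohort(cohort_spec(n_subjects = 1, seed = 5))
  expect_length(one$models, 1)
  expect_error(cohort_spec(group_deltas = c("A:nope->rM1" = 1)),
               class = "bolddcm_invalid_argument")
})

test_that("sampled subjects always admit a stable forward simulation", {
  d <- generate_design(6, 1, 1, c(2, 6), seed = 31)
  ip <- rasterize_inputs(d, ceiling(attr(d, "session_length") / 2), 8, 2)
  for (s in 1:5) {
    coh <- sample_cohort(cohort_spec(n_subjects = 6, seed = 100 + s))
    for (m in coh$models) expect_silent(integrate_forward(m, ip))
  }
})

test_that("simulated timeseries obey the noise specification", {
  m <- negative_responder_model()
  d <- generate_design(40, 4, 4, c(2, 26), seed = 8)
  n_scans <- ceiling(attr(d, "session_length") / 2)
  ip <- rasterize_inputs(d, n_scans, 16, 2)
  clean <- simulate_subject_timeseries(m, ip, list(model = "white",
                                                   snr = Inf), seed = 1)
  expect_identical(unclass(clean)[, ], unclass(attr(clean, "signal"))[, ])
  expect_equal(dim(clean), c(n_scans, 6))
  noisy <- simulate_subject_timeseries(m, ip, list(model = "white", snr = 1),
                                       seed = 2)
  resid <- noisy - attr(noisy, "signal")
  ratio <- apply(resid, 2, stats::sd) / apply(attr(noisy, "signal"), 2,
                                              stats::sd)
  expect_true(all(abs(ratio - 1) < 0.10))
  # same seed, same realisation; AR(1) has positive lag-1 autocorrelation
  noisy2 <- simulate_subject_timeseries(m, ip, list(model = "white", snr = 1),
                                        seed = 2)
  expect_identical(unclass(noisy)[, ], unclass(noisy2)[, ])
  ar <- simulate_subject_timeseries(m, ip, list(model = "ar1", snr = 1,
                                                ar = 0.5), seed = 3)
  e <- ar - attr(ar, "signal")
  r1 <- mean(vapply(seq_len(6), function(j) {
    stats::cor(e[-1, j], e[-nrow(e), j])
  }, 0))
  expect_gt(r1, 0.3)
})

test_that("exclusion bookkeeping matches the study roster", {
  excl <- cohort_exclusions(652, c(missing_or_dropout = 9, stroke = 8))
  expect_equal(excl$n_final, 635)
  expect_equal(excl$n_excluded, 17)
  expect_error(cohort_exclusions(10, c(a = 20)),
               class = "bolddcm_invalid_argument")
})
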