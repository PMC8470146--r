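test_that("a zero offset reproduces the base kernel bitwise", {
  base <- negative_responder_model()
  k0 <- volterra_kernel(base, 1)
  for (pp in c("A:lSMA->rM1", "selfA:rM1", "transit:rM1", "decay")) {
    sw <- perturb_and_predict(base, pp, c(-0.5, 0, 0.5))
    expect_identical(sw$kernels[, 2], unname(k0[, "rM1"]))
    expect_false(any(sw$failed))
  }
  expect_error(perturb_and_predict(base, "A:bogus", 0),
               class = "bolddcm_invalid_argument")
})

test_that("the rM1 extremum rises monotonically with inter-hemispheric drive", {
  base <- negative_responder_model()
  offsets <- seq(-1, 1, length.out = 9)
  for (pp in c("A:lM1->rM1", "A:lPMd->rM1", "A:lSMA->rM1")) {
    sw <- perturb_and_predict(base, pp, offsets)
    ext <- apply(sw$kernels, 2, function(col) col[which.max(abs(col))])
    expect_true(all(diff(ext) > -1e-12), label = pp)
  }
})

test_that("haemodynamic sweeps modulate amplitude but never the sign", {
  base <- negative_responder_model()
  for (pp in c("transit:rM1", "decay")) {
    sw <- perturb_and_predict(base, pp, seq(-1, 1, length.out = 9))
    ext <- apply(sw$kernels, 2, function(col) col[which.max(abs(col))])
    expect_true(all(ext < 0), label = pp)
    expect_gt(diff(range(abs(ext))) / max(abs(ext)), 0.01)
  }
})

test_that("constructed inhibitory drives appear in the sign-flip set", {
  vals <- c("C:lSMA:AV" = 0.25, "C:lPMd:AV" = 0.2,
            "A:lSMA->lM1" = 0.3, "A:lPMd->lM1" = 0.3,
            "A:lPMd->rM1" = -0.35, "A:lSMA->rM1" = -0.3)
  base <- dcm_model()
  for (nm in names(vals)) base <- set_parameter(base, nm, vals[[nm]])
  conns <- c("A:lPMd->rM1", "A:lSMA->rM1", "A:lM1->rM1", "transit:rM1")
  res <- sign_flip_set(base, range = 1, n_grid = 11, parameters = conns)
  expect_true(res$flips[res$parameter == "A:lPMd->rM1"])
  expect_true(res$flips[res$parameter == "A:lSMA->rM1"])
  expect_false(res$flips[res$parameter == "transit:rM1"])
  # flip offsets are resolved and lie inside the sweep
  fo <- res$flip_offset[res$flips]
  expect_true(all(is.finite(fo) & abs(fo) <= 1))
  # membership is stable under grid refinement
  res2 <- sign_flip_set(base, range = 1, n_grid = 21, parameters = conns)
  expect_identical(res$flips, res2$flips)
  expect_true(all(abs(res$flip_offset[res$flips] -
                        res2$flip_offset[res2$flips]) < 0.1))
})

test_that("a response-free base has no defined sign", {
  base <- dcm_model()   # no driving input at all
  expect_error(sign_flip_set(base, parameters = "A:lM1->rM1"),
               class = "bolddcm_indeterminate_sign")
})

test_that("on a positive-responder base the connections flip back down", {
  base <- positive_responder_model()
  conns <- c("A:lM1->rM1", "A:lPMd->rM1", "A:lSMA->rM1")
  res <- sign_flip_set(base, range = 1, n_grid = 11, parameters = conns)
  expect_gt(attr(res, "base_extremum"), 0)
  expect_true(all(res$flips))
})

test_that("peak metrics find the extremum with the stated rounding", {
  tm <- seq(0, 32, by = 0.02)
  bump <- exp(-(tm - 6)^2 / 2)
  pk <- peak_metrics(bump, time = tm)
  expect_equal(pk$amplitude, 1)
  expect_equal(pk$latency, 6)
  expect_equal(pk$latency_half, 6)
  neg <- peak_metrics(-bump, time = tm)
  expect_equal(neg$amplitude, -1)
  expect_equal(neg$latency, pk$latency)
  # half-second rounding, half-up
  late <- peak_metrics(exp(-(tm - 5.26)^2 / 0.5), time = tm)
  expect_equal(late$latency_half, 5.5)
  zero <- peak_metrics(rep(0, 10), time = seq_len(10))
  expect_true(is.na(zero$amplitude) && is.na(zero$latency))
})

test_that("amplitude regression matches the normal equations", {
  withr::with_seed(77, {
    n <- 60
    c1 <- stats::rnorm(n)
    c2 <- 0.6 * c1 + stats::rnorm(n, 0, 0.8)
    amp <- 2 * c1 + stats::rnorm(n, 0, 0.5)
  })
  res <- connection_amplitude_regression(cbind(lSMA = c1, lPMd = c2), amp)
  expect_equal(res$per_connection$R[1], stats::cor(c1, amp))
  expect_equal(res$per_connection$R2, res$per_connection$R^2)
  # brute-force normal equations for the joint model
  X <- cbind(1, c1, c2)
  bh <- solve(crossprod(X), crossprod(X, amp))
  pred <- X %*% bh
  r2 <- 1 - sum((amp - pred)^2) / sum((amp - mean(amp))^2)
  expect_equal(res$joint_R2, r2, tolerance = 1e-10)
  expect_gte(res$joint_R2, max(res$per_connection$R2))
  # exact linear relation and a pure-noise predictor
  exact <- connection_amplitude_regression(cbind(x = c1), 3 * c1)
  expect_equal(exact$per_connection$R2, 1)
  noise <- connection_amplitude_regression(cbind(x = stats::rnorm(n)), amp)
  expect_lt(noise$per_connection$R2, 0.2)
  flat <- connection_amplitude_regression(cbind(x = rep(1, n)), amp)
  expect_true(is.na(flat$per_connection$R2))
})
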