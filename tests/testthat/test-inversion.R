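test_that("prior switching encodes the driving-input hypotheses", {
  p1 <- dcm_priors("m1")
  p2 <- dcm_priors("m2")
  on_C <- function(p) {
    nm <- names(p$var)[p$var > 0 & startsWith(names(p$var), "C:")]
    unique(sub("^C:([^:]+):.*$", "\\1", nm))
  }
  expect_setequal(on_C(p1), c("lSMA", "lPMd"))
  expect_setequal(on_C(p2), c("rSMA", "rPMd"))
  # all between-region connections informed, all prior means zero
  isA <- startsWith(names(p1$var), "A:")
  expect_true(all(p1$var[isA] > 0))
  expect_true(all(p1$mean == 0))
  expect_error(dcm_priors("m3"))
})

test_that("the inversion reproduces the conjugate linear-Gaussian posterior", {
  withr::with_seed(42, {
    n <- 40; p <- 3
    X <- matrix(stats::rnorm(n * p), n, p)
    sigma <- 0.3
    y <- matrix(X %*% c(0.5, -1, 0.3) + stats::rnorm(n, 0, sigma), n, 1)
  })
  g <- function(th) X %*% th
  pm <- stats::setNames(rep(0, 3), paste0("b", 1:3))
  fit <- vl_laplace(y, g, pm, rep(1, 3),
                    settings = dcm_settings(h_var = 0,
                                            h_mean = log(1 / 0.3^2)))
  oracle <- conjugate_posterior(X, y, rep(1, 3), 0.3^2)
  expect_lt(max(abs(fit$mean - oracle$mean)) / max(abs(oracle$mean)), 1e-6)
  expect_lt(max(abs(fit$cov - oracle$cov)) / max(abs(oracle$cov)), 1e-6)
  # the free energy matches the analytic log evidence
  expect_lt(abs(fit$free_energy - conjugate_evidence(X, y, rep(1, 3),
                                                     0.3^2)), 1e-4)
  expect_true(all(diff(fit$trace) > 0))
})

test_that("noiseless data at the prior mean stay at the prior mean", {
  pri <- two_region_priors()
  ip <- toy_inputs()
  m0 <- dcm_model(regions = c("r1", "r2"), conditions = "u")  # all zero
  y0 <- integrate_forward(m0, ip)   # identically zero
  fit <- dcm_fit(y0 + 1e-9, ip, pri, fast_settings())
  free <- pri$var > 0
  expect_lt(max(abs(fit$posterior$mean[free])), 1e-3)
})

test_that("zero-prior-variance parameters pass through untouched", {
  truth <- two_region_truth()
  ip <- toy_inputs()
  y <- simulate_subject_timeseries(truth, ip,
                                   list(model = "white", snr = 3), seed = 6)
  pri <- two_region_priors()
  fit <- dcm_fit(y, ip, pri, fast_settings())
  off <- pri$var == 0
  expect_identical(unname(fit$posterior$mean[off]), unname(pri$mean[off]))
  expect_true(all(fit$posterior$cov[off, ] == 0))
  expect_true(all(diff(fit$trace) > 0))
  # recovery of the toy parameters under light noise
  expect_lt(abs(coef(fit)["A:r1->r2"] - 0.4), 0.15)
  expect_gt(min(explained_variance(fit)), 50)
})

test_that("re-estimation keeps whichever fit has higher evidence", {
  truth <- two_region_truth()
  ip <- toy_inputs()
  y <- simulate_subject_timeseries(truth, ip,
                                   list(model = "white", snr = 2), seed = 7)
  pri <- two_region_priors()
  fit <- dcm_fit(y, ip, pri, fast_settings())
  again <- dcm_reestimate(fit, pri$mean)   # restart at the prior mean
  expect_gte(again$posterior$free_energy, fit$posterior$free_energy)
  start <- fit$posterior$mean
  best <- dcm_reestimate(fit, start)
  expect_gte(best$posterior$free_energy, fit$posterior$free_energy)
})

test_that("explained variance reads 100 for perfect fits and 0 for none", {
  truth <- two_region_truth()
  ip <- toy_inputs()
  y0 <- integrate_forward(truth, ip)
  fit <- dcm_fit(y0, ip, two_region_priors(), fast_settings())
  expect_true(all(explained_variance(fit) > 99))
  # a null prediction on pure noise explains nothing
  fake <- fit
  fake$data <- matrix(stats::rnorm(60), 30, 2,
                      dimnames = list(NULL, c("r1", "r2")))
  fake$prediction <- matrix(0, 30, 2)
  ev <- explained_variance(fake)
  expect_true(all(abs(ev) < 30))
})

test_that("evidence comparison follows softmax arithmetic", {
  even <- compare_evidence(c(m1 = 0, m2 = 0))
  expect_equal(unname(even$probability), c(0.5, 0.5))
  # a log Bayes factor of 2.584e4 is certainty at displayed precision
  huge <- compare_evidence(c(m1 = 2.584e4, m2 = 0))
  expect_equal(unname(huge$probability["m1"]), 1)
  expect_equal(huge$log_bf["m1", "m2"], 2.584e4)
  shifted <- compare_evidence(c(m1 = 2.584e4 + 123, m2 = 123))
  expect_equal(shifted$probability, huge$probability)
  expect_error(compare_evidence(c(1, NA)),
               class = "bolddcm_invalid_argument")
  expect_error(compare_evidence(3), class = "bolddcm_invalid_argument")
})

test_that("fit methods expose the usual modelling interface", {
  truth <- two_region_truth()
  ip <- toy_inputs()
  y <- simulate_subject_timeseries(truth, ip,
                                   list(model = "white", snr = 3), seed = 9)
  fit <- dcm_fit(y, ip, two_region_priors(), fast_settings())
  expect_output(print(fit), "free energy")
  expect_output(print(summary(fit)), "Explained variance")
  expect_named(coef(fit))
  expect_equal(dim(vcov(fit)), rep(length(coef(fit)), 2))
  expect_equal(as.numeric(logLik(fit)), fit$posterior$free_energy)
  expect_equal(fitted(fit) + residuals(fit), unclass(y)[, ],
               ignore_attr = TRUE)
  expect_equal(predict(fit), fitted(fit), ignore_attr = TRUE)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), dim(y))
})
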