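test_that("parameterisation identities hold", {
  expect_identical(self_connection_strength(0), -0.5)
  expect_equal(self_connection_strength(log(2)), -1.0)
  expect_identical(decay_rate(0), 0.64)
  expect_identical(transit_time(0), 2)
  # positivity by construction over a wide grid
  expect_true(all(self_connection_strength(seq(-5, 5, by = 0.25)) < 0))
  expect_error(self_connection_strength(NaN),
               class = "bolddcm_invalid_argument")
})

test_that("observation constants follow the field-strength rule", {
  k <- bold_constants()
  expect_equal(k$nu0, 28.265 * 3)
  expect_lt(abs(k$nu0 - 84.8), 0.1)
  kc <- bold_coefficients(k)
  # arithmetic oracle over the coefficient formulas
  expect_equal(unname(kc["k1"]), 4.3 * 84.795 * 0.4 * 0.03)
  expect_equal(unname(kc["k2"]), 0.46 * 110 * 0.4 * 0.03)
  expect_equal(unname(kc["k3"]), 0.54)
  expect_error(bold_constants(V0 = 1.2), class = "bolddcm_invalid_argument")
})

test_that("neural derivative matches hand-computed cases", {
  m1 <- dcm_model(regions = "r", conditions = "u", C = matrix(1, 1, 1))
  expect_equal(neural_derivative(0, 0, m1), 0, ignore_attr = TRUE)
  expect_equal(neural_derivative(0, 1, m1), 1, ignore_attr = TRUE)
  m2 <- dcm_model(regions = c("a", "b"), conditions = "u")
  m2 <- set_parameter(m2, "A:a->b", 0.3)
  # source-row orientation: activity in a drives b
  expect_equal(neural_derivative(c(1, 0), 0, m2), c(-0.5, 0.3),
               ignore_attr = TRUE)
  expect_error(neural_derivative(c(1, 0, 0), 0, m2),
               class = "bolddcm_invalid_argument")
})

test_that("the resting state is an exact fixed point", {
  m <- negative_responder_model()
  rest <- list(z = rep(0, 6), s = rep(0, 6), f = rep(1, 6), v = rep(1, 6),
               q = rep(1, 6))
  dd <- haemodynamic_derivative(rest, m)
  expect_true(all(unlist(dd) == 0))
  expect_identical(bold_observation(rest, m$constants), rep(0, 6))
  expect_error(haemodynamic_derivative(modifyList(rest, list(f = rep(-1, 6))),
                                       m),
               class = "bolddcm_invalid_argument")
  # less deoxyhaemoglobin at constant volume reads as positive BOLD
  expect_true(all(bold_observation(list(v = 1, q = 0.9)) > 0))
})

test_that("zero input integrates to an identically zero prediction", {
  m <- negative_responder_model()
  ip <- rasterize_inputs(generate_design(0, 0, 0, c(2, 26), seed = 1),
                         20, 16, 2)
  y <- integrate_forward(m, ip)
  expect_true(all(y == 0))
})

test_that("halving the integration step barely changes the prediction", {
  m <- negative_responder_model()
  d <- generate_design(4, 1, 1, c(2, 8), seed = 5)
  ip <- rasterize_inputs(d, ceiling(attr(d, "session_length") / 2), 16, 2)
  y1 <- integrate_forward(m, ip)
  y2 <- integrate_forward(m, ip, substeps = 2)
  expect_lt(norm(y1 - y2, "F") / norm(y2, "F"), 1e-4)
})

test_that("the compiled integrator matches an adaptive ODE solver", {
  skip_if_not_installed("deSolve")
  m <- two_region_truth()
  ip <- toy_inputs()
  y <- integrate_forward(m, ip)
  # independent route: stiff-capable adaptive integration in plain R
  At <- t(full_connectivity(m)); C <- m$C; k <- m$constants
  kap <- decay_rate(m$lambda_kappa); tau <- transit_time(m$lambda_tau)
  U <- ip$values; dt <- ip$bin_width
  deriv <- function(t, x, parms) {
    R <- 2
    z <- x[1:R]; s <- x[R + 1:R]; f <- x[2 * R + 1:R]
    v <- x[3 * R + 1:R]; q <- x[4 * R + 1:R]
    bin <- min(nrow(U), floor(t / dt) + 1)
    fout <- v^(1 / k$alpha)
    E <- 1 - (1 - k$E0)^(1 / f)
    list(c(drop(At %*% z + C %*% U[bin, ]),
           z - kap * s - k$gamma * (f - 1),
           s,
           (f - fout) / tau,
           (f * E / k$E0 - fout * q / v) / tau))
  }
  bps <- ip$bins_per_scan
  t_samp <- ((seq_len(ip$n_scans) - 1) * bps + floor(bps / 2)) * dt
  sol <- deSolve::ode(c(rep(0, 4), rep(1, 6)), c(0, t_samp), deriv, NULL,
                      method = "ode45", rtol = 1e-8, atol = 1e-10,
                      hmax = dt / 2)  # never step over a one-bin pulse
  kc <- bold_coefficients(k)
  vq <- sol[-1, -1, drop = FALSE]
  y_ref <- k$V0 * (kc[["k1"]] * (1 - vq[, 9:10]) +
                     kc[["k2"]] * (1 - vq[, 9:10] / vq[, 7:8]) +
                     kc[["k3"]] * (1 - vq[, 7:8]))
  expect_lt(max(abs(y - y_ref)) / max(abs(y_ref)), 2e-3)
})

test_that("unstable parameterisations raise an informative error", {
  m <- two_region_truth()
  m <- set_parameter(m, "A:r1->r2", 5)
  m <- set_parameter(m, "A:r2->r1", 5)
  err <- tryCatch(integrate_forward(m, toy_inputs()),
                  bolddcm_instability = function(e) e)
  expect_s3_class(err, "bolddcm_instability")
  expect_match(conditionMessage(err), "A:r")
})

test_that("the impulse response behaves like a canonical haemodynamic kernel", {
  m <- dcm_model(regions = "r", conditions = "u", C = matrix(1, 1, 1))
  k <- volterra_kernel(m, 1, duration = 32)
  tm <- attr(k, "time")
  expect_gt(max(k), 0)
  peak <- tm[which.max(k)]
  expect_gt(peak, 3); expect_lt(peak, 8)
  # settles back towards baseline by the end of the window
  expect_lt(abs(k[length(k)]), 1e-3 * max(abs(k)))
  # near-linear scaling for small inputs
  k2 <- volterra_kernel(m, 1, duration = 32, input_height = 0.5)
  expect_lt(max(abs(2 * k2 - k)) / max(abs(k)), 0.05)
  # no drive, no response
  m0 <- dcm_model(regions = "r", conditions = "u")
  expect_true(all(volterra_kernel(m0, 1) == 0))
})

test_that("the intra/extra-vascular ratio prior matches its closed form", {
  single <- epsilon_prior_fit(c(20, 20), c(40, 40), step = 1, TE = 30)
  expect_equal(single$values, exp(30 / 40 - 30 / 20))
  expect_equal(single$meanlog, -0.75)
  fit <- epsilon_prior_fit()
  expect_equal(fit$n, 21 * 31)
  expect_lt(abs(fit$meanlog - log(0.46)), 0.1)
  expect_lt(abs(fit$sdlog2 - 0.06), 0.02)
  expect_gte(fit$sdlog2, 0)
  expect_error(epsilon_prior_fit(step = -1),
               class = "bolddcm_invalid_argument")
})
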