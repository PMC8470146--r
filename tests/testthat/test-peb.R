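test_that("the between-subjects design is orthogonal and centred", {
  withr::with_seed(11, {
    age <- stats::rnorm(40, 55, 18)
    g <- rep(c(1, 0), 20)
    amp <- stats::rnorm(40, 0, 3) - 0.1 * g
  })
  X <- peb_design(age, g, amp)
  G <- crossprod(X)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))
  expect_true(all(X[, 1] == 1))
  expect_equal(sum(X[, "group"]), 0)
  expect_length(unique(round(X[, "group"], 12)), 2)
  # independent residualisation oracle for the age column
  ref <- stats::residuals(stats::lm(I(age - mean(age)) ~ g))
  expect_equal(unname(X[, "age"]), unname(ref), tolerance = 1e-10)
  expect_equal(stats::cor(X[, "age"], X[, "group"]), 0, tolerance = 1e-10)
  expect_error(peb_design(age, rep(1, 40), amp),
               class = "bolddcm_degenerate_design")
  expect_error(peb_design(rep(50, 40), g, amp),
               class = "bolddcm_degenerate_design")
})

test_that("identical subjects with a constant design recover the shared mean", {
  fx <- fake_cohort_fits(12, effects = list("A:r1->r2" = c(0.3, 0, 0, 0),
                                            "C:r1:u" = c(0.5, 0, 0, 0)),
                         noise_sd = 0, obs_sd = 0.01, seed = 2)
  X <- matrix(1, 12, 1, dimnames = list(NULL, "constant"))
  peb <- peb_fit(fx$fits, X)
  expect_equal(length(peb$beta), length(peb$parameters))
  expect_lt(abs(coef(peb, "constant")["A:r1->r2"] - 0.3), 0.02)
  expect_lt(abs(coef(peb, "constant")["C:r1:u"] - 0.5), 0.02)
})

test_that("the group model recovers known second-level effects", {
  # average 0.3 on A:r1->r2 with a +0.4 group effect, nothing elsewhere
  fx <- fake_cohort_fits(30, effects = list("A:r1->r2" = c(0.3, 0.4, 0, 0)),
                         seed = 3)
  peb <- peb_fit(fx$fits, fx$design)
  # Kronecker layout: one coefficient per covariate per parameter
  expect_length(peb$beta, 4 * length(peb$parameters))
  expect_lt(abs(coef(peb, "constant")["A:r1->r2"] - 0.3), 0.1)
  bg <- coef(peb, "group")["A:r1->r2"]
  sdg <- sqrt(diag(peb$beta_cov))[match("group:A:r1->r2",
                                        names(peb$beta))]
  expect_lt(abs(bg - 0.4), 2 * max(sdg, 0.05))
})

test_that("Bayesian model reduction agrees with direct refitting", {
  # conjugate toy: Gaussian likelihood kernel with known precision
  withr::with_seed(4, {
    p <- 3
    Lam <- crossprod(matrix(stats::rnorm(9), 3)) + diag(3)
    m_hat <- c(0.8, 0.01, -0.5)
    w <- drop(Lam %*% m_hat)
  })
  prior_var <- rep(1, p)
  post_from <- function(pv) {
    P <- Lam + diag(1 / pv, p)
    S <- solve(P)
    mu <- drop(S %*% w)
    lz <- 0.5 * drop(crossprod(mu, P %*% mu)) +
      0.5 * determinant(S)$modulus - 0.5 * sum(log(pv))
    list(mean = mu, cov = S, logz = lz)
  }
  full <- post_from(prior_var)
  red_var <- c(1, 1e-8, 1)
  refit <- post_from(red_var)
  bmr <- gaussian_bmr(full$mean, full$cov, rep(0, p), prior_var,
                      red_var = red_var)
  expect_lt(abs(bmr$dF - (refit$logz - full$logz)), 1e-4)
  expect_equal(bmr$mean, refit$mean, tolerance = 1e-6)
  expect_equal(bmr$cov, refit$cov, tolerance = 1e-6)
  # identity reduction changes nothing
  same <- gaussian_bmr(full$mean, full$cov, rep(0, p), prior_var,
                       red_var = prior_var)
  expect_equal(same$dF, 0, tolerance = 1e-10)
  expect_equal(same$mean, full$mean, tolerance = 1e-10)
  # widening is unsupported
  expect_error(gaussian_bmr(full$mean, full$cov, rep(0, p), prior_var,
                            red_var = c(2, 1, 1)),
               class = "bolddcm_unsupported_reduction")
  # switching off a near-zero parameter saves complexity
  off2 <- gaussian_bmr(full$mean, full$cov, rep(0, p), prior_var,
                       red_var = c(1, 1e-8, 1))
  expect_gt(off2$dF, 0)
})

test_that("the model space enumerates 64 reduced models", {
  fx <- fake_cohort_fits(24, effects = list("A:r1->r2" = c(0.4, 0.5, 0, 0)),
                         seed = 5)
  peb <- peb_fit(fx$fits, fx$design)
  ms <- compare_model_space(peb)
  expect_equal(dim(ms$F), c(8, 8))
  expect_equal(length(ms$probability), 64)
  expect_equal(sum(ms$probability), 1)
  # effects only in A: the winner keeps A in both average and difference
  expect_match(ms$winner["average"], "A")
  expect_match(ms$winner["difference"], "A")
  # softmax is invariant to a common shift
  z1 <- exp(ms$F - max(ms$F)); z1 <- z1 / sum(z1)
  z2 <- exp(ms$F + 57 - max(ms$F + 57)); z2 <- z2 / sum(z2)
  expect_equal(z1, z2)
})

test_that("greedy search prunes null effects and keeps strong ones", {
  null <- fake_cohort_fits(24, effects = list("A:r1->r2" = c(0.4, 0, 0, 0)),
                           seed = 6)
  peb0 <- peb_fit(null$fits, null$design)
  sr0 <- peb_search(peb0)
  M <- length(peb0$parameters)
  diff_idx <- M + seq_len(M)   # group column coefficients
  expect_true(all(!sr0$on[diff_idx]))
  expect_equal(sum(sr0$weights), 1)
  strong <- fake_cohort_fits(24,
                             effects = list("A:r1->r2" = c(0.4, 0.5, 0, 0)),
                             seed = 7)
  peb1 <- peb_fit(strong$fits, strong$design)
  sr1 <- peb_search(peb1)
  expect_true(sr1$on["group:A:r1->r2"])
  expect_gt(abs(sr1$bma_mean["group:A:r1->r2"]), 0.2)
})

test_that("presence probabilities follow the two-model softmax", {
  fx <- fake_cohort_fits(24, effects = list("A:r1->r2" = c(0.4, 0.5, 0, 0)),
                         seed = 8)
  peb <- peb_fit(fx$fits, fx$design)
  pr <- parameter_probability(peb, c("group:A:r1->r2", "age:decay"))
  expect_gt(pr[1], 0.99)
  expect_lt(pr[2], 0.6)
  # softmax arithmetic: an evidence gap of log(19) gives 0.95
  expect_equal(1 / (1 + exp(-log(19))), 0.95)
  expect_error(parameter_probability(peb, "nope"),
               class = "bolddcm_invalid_argument")
})
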