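# Shared fixtures: small networks, designs and oracles used across files.

# a two-region chain driven in region 1, one condition
two_region_truth <- function() {
  m <- dcm_model(regions = c("r1", "r2"), conditions = "u")
  m <- set_parameter(m, "C:r1:u", 0.3)
  set_parameter(m, "A:r1->r2", 0.4)
}

two_region_priors <- function() {
  dcm_priors("m1", regions = c("r1", "r2"), conditions = "u",
             driving = "r1")
}

# sparse event train for the two-region toy
toy_inputs <- function(n_scans = 30, bins_per_scan = 8) {
  d <- data.frame(onset = c(4, 13, 21, 33, 44), condition = "AV",
                  tone_hz = NA, duration = 0.3)
  ip <- rasterize_inputs(d, n_scans, bins_per_scan, 2)
  # collapse to the single condition of the toy
  ip$values <- ip$values[, "AV", drop = FALSE]
  ip$conditions <- "u"
  ip
}

fast_settings <- function(...) dcm_settings(max_iterations = 32, ...)

# closed-form Bayesian linear regression oracle (known noise variance)
conjugate_posterior <- function(X, y, prior_var, sigma2) {
  P0 <- diag(1 / prior_var, ncol(X))
  S <- solve(crossprod(X) / sigma2 + P0)
  list(mean = drop(S %*% crossprod(X, y) / sigma2), cov = S)
}

# analytic log evidence of the same model (zero prior mean)
conjugate_evidence <- function(X, y, prior_var, sigma2) {
  n <- nrow(X)
  po <- conjugate_posterior(X, y, prior_var, sigma2)
  -0.5 * n * log(2 * pi * sigma2) - 0.5 * sum(y^2) / sigma2 +
    0.5 * drop(crossprod(po$mean, solve(po$cov, po$mean))) +
    0.5 * determinant(po$cov)$modulus - 0.5 * sum(log(prior_var))
}

# construct synthetic subject "fits" (Gaussian posteriors around generated
# parameters) for group-level tests that do not need real inversions
fake_cohort_fits <- function(N, effects = list(), noise_sd = 0.02,
                             obs_sd = 0.02, seed = 1,
                             priors = dcm_priors("m1",
                                                 regions = c("r1", "r2"),
                                                 conditions = "u",
                                                 driving = "r1"),
                             design = NULL) {
  p <- length(priors$mean)
  withr::with_seed(seed, {
    if (is.null(design)) {
      g <- rep(c(1, 0), length.out = N)
      design <- peb_design(stats::rnorm(N, 50, 15), g, stats::rnorm(N, 0, 2))
    }
    fits <- lapply(seq_len(N), function(i) {
      th <- stats::setNames(numeric(p), names(priors$mean))
      for (nm in names(effects)) {
        ef <- effects[[nm]]
        th[nm] <- ef[1] + sum(ef[-1] * design[i, -1]) +
          stats::rnorm(1, 0, noise_sd)
      }
      obs <- th + ifelse(priors$var > 0, stats::rnorm(p, 0, obs_sd), 0)
      cv <- diag(ifelse(priors$var > 0, obs_sd^2, 0), p)
      dimnames(cv) <- list(names(th), names(th))
      list(posterior = list(names = names(th), mean = obs, cov = cv,
                            free_energy = -100),
           priors = priors)
    })
    list(fits = fits, design = design)
  })
}
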