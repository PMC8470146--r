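test_that("a single component reduces to the sample moments", {
  x <- sample_printed_mixture(200, seed = 1)[, 1:2]
  g1 <- gmm_fit(x, K = 1)
  n <- nrow(x)
  expect_equal(unname(g1$means[1, ]), unname(colMeans(x)))
  expect_equal(g1$covariances[[1]],
               stats::cov(x) * (n - 1) / n,
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(g1$weights, 1)
  # information criteria bookkeeping: K-1 + 2K + 3K parameters
  expect_equal(g1$AIC, 2 * 5 - 2 * g1$log_likelihood)
  expect_equal(g1$BIC, 5 * log(n) - 2 * g1$log_likelihood)
})

test_that("EM never decreases the log-likelihood", {
  for (s in 1:3) {
    x <- sample_printed_mixture(300, seed = s)[, 1:2]
    g2 <- gmm_fit(x, K = 2, seed = s)
    expect_true(all(diff(g2$trace) > -1e-8))
  }
  # seeded restarts are deterministic
  x <- sample_printed_mixture(150, seed = 5)[, 1:2]
  a <- gmm_fit(x, K = 2, init = "random", seed = 9)
  b <- gmm_fit(x, K = 2, init = "random", seed = 9)
  expect_identical(a$means, b$means)
})

test_that("the EM fit agrees with an independent reference implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))  # Mclust needs its helpers attached
  for (s in 1:5) {
    x <- sample_printed_mixture(400, seed = 10 + s)[, 1:2]
    own <- gmm_fit(x, K = 2, seed = s, tol = 1e-10)
    # the reference EM, started at our solution, must not move away from it:
    # both implementations share the fixed points of the same objective
    sig <- array(unlist(own$covariances), c(2, 2, 2))
    par0 <- list(pro = own$weights, mean = t(own$means),
                 variance = list(modelName = "VVV", d = 2, G = 2,
                                 sigma = sig,
                                 cholsigma = array(apply(sig, 3, chol),
                                                   c(2, 2, 2))))
    ref <- mclust::em(modelName = "VVV", data = as.matrix(x),
                      parameters = par0)
    ref_means <- t(ref$parameters$mean)
    o <- order(own$means[, 2]); r <- order(ref_means[, 2])
    expect_equal(unname(own$means[o, ]), unname(ref_means[r, ]),
                 tolerance = 1e-3)
    # and the log-likelihoods of the shared optimum agree
    expect_equal(ref$loglik, own$log_likelihood, tolerance = 1e-6)
  }
})

test_that("information criteria favour the generating structure", {
  # data from one Gaussian: the single-cluster control wins
  withr::with_seed(21, {
    x1 <- cbind(stats::rnorm(400, 50, 15), stats::rnorm(400, 0, 2))
  })
  c1 <- suppressWarnings(compare_components(x1, c(1, 2), seed = 1))
  expect_lt(c1$dBIC[c1$K == 2], 0)
  # data from the printed two-component mixture: two clusters win
  x2 <- sample_printed_mixture(635, seed = 22)[, 1:2]
  c2 <- compare_components(x2, c(1, 2), seed = 2)
  expect_gt(c2$dAIC[c2$K == 2], 0)
  expect_gt(c2$dBIC[c2$K == 2], 0)
  expect_equal(c2$dAIC[c2$K == 1], 0)
})

test_that("assignment labels the lower-amplitude component as negative", {
  x <- sample_printed_mixture(500, seed = 30)[, 1:2]
  g2 <- gmm_fit(x, K = 2, seed = 3)
  asg <- gmm_assign(g2, x)
  expect_equal(sum(asg$proportions), 1)
  # a point at a component mean belongs to that component
  neg <- asg$negative_component
  at_mean <- gmm_assign(g2, g2$means)
  expect_equal(at_mean$component, c(1, 2))
  expect_identical(at_mean$label[neg], "negative")
  # label symmetry: permuting the components leaves labels unchanged
  perm <- g2
  perm$weights <- rev(g2$weights)
  perm$means <- g2$means[2:1, ]
  perm$covariances <- g2$covariances[2:1]
  asg_p <- gmm_assign(perm, x)
  expect_identical(asg_p$label, asg$label)
})

test_that("degenerate components are regularised with a warning", {
  x <- withr::with_seed(1, {
    rbind(matrix(rep(c(1, 1), 40), ncol = 2, byrow = TRUE),
          cbind(stats::rnorm(40, 10), stats::rnorm(40)))
  })
  w <- capture_warnings(gmm_fit(x, K = 2, seed = 1))
  expect_true(any(grepl("regularised", w)))
})
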