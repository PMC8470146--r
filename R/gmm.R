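#' Fit a bivariate Gaussian mixture by expectation-maximisation
#'
#' Full-covariance K-component mixture over (age, response amplitude)
#' pairs, fitted by EM to convergence. The default initialisation splits
#' the sample at the amplitude median - one cluster of mainly positive
#' and one of mainly negative responders - mirroring how the responder
#' groups were seeded in the motivating analysis; k-means and random
#' initialisations are available (random uses seeded restarts and keeps
#' the best log-likelihood). Component covariances are regularised by an
#' eigenvalue floor to prevent collapse onto single points.
#'
#' @param x N x 2 numeric matrix or data.frame (columns: age, amplitude)
#' @param K number of components
#' @param init \code{"split"} (amplitude-median split), \code{"kmeans"} or
#'   \code{"random"}
#' @param seed integer seed (used by kmeans/random initialisation)
#' @param n_restarts restarts for random initialisation
#' @param tol log-likelihood convergence threshold
#' @param max_iter iteration cap
#' @param eig_floor eigenvalue floor for component covariances
#' @return object of class \code{gmm}: list with \code{weights},
#'   \code{means} (K x 2), \code{covariances}, \code{log_likelihood},
#'   \code{trace}, \code{AIC}, \code{BIC}, \code{responsibilities},
#'   \code{K}, \code{n}
#' @export
gmm_fit <- function(x, K = 2, init = c("split", "kmeans", "random"),
                    seed = 1L, n_restarts = 5L, tol = 1e-8, max_iter = 500L,
                    eig_floor = 1e-6) {
  init <- match.arg(init)
  x <- as.matrix(x)
  if (ncol(x) != 2) stop_invalid("'x' must have two columns")
  if (any(!is.finite(x))) stop_invalid("'x' must be finite")
  n <- nrow(x)
  if (n <= 3 * K) stop_invalid("need more than 3K points")
  run <- function(labels) em_gmm(x, K, labels, tol, max_iter, eig_floor)
  fit <- with_seed(seed, {
    if (init == "split" || K == 1) {
      cut <- stats::median(x[, 2])
      labels <- if (K == 1) rep(1L, n) else {
        lb <- ifelse(x[, 2] <= cut, 1L, 2L)
        if (K > 2) lb <- ((seq_len(n) - 1L) %% K) + 1L
        lb
      }
      run(labels)
    } else if (init == "kmeans") {
      run(stats::kmeans(scale(x), K, nstart = 5)$cluster)
    } else {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        f <- run(sample.int(K, n, replace = TRUE))
        if (is.null(best) || f$log_likelihood > best$log_likelihood) best <- f
      }
      best
    }
  })
  k_params <- (K - 1) + 2 * K + 3 * K
  fit$AIC <- 2 * k_params - 2 * fit$log_likelihood
  fit$BIC <- k_params * log(n) - 2 * fit$log_likelihood
  fit$k_params <- k_params
  fit$n <- n
  fit$K <- K
  fit$init <- init
  class(fit) <- "gmm"
  fit
}

dmvnorm2 <- function(x, mu, S) {
  ch <- chol(S)
  z <- forwardsolve(t(ch), t(x) - mu)
  exp(-0.5 * colSums(z^2) - sum(log(diag(ch))) - log(2 * pi))
}

regularise_cov <- function(S, eig_floor) {
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (all(eg$values >= eig_floor)) return((S + t(S)) / 2)
  warning("degenerate mixture component regularised", call. = FALSE)
  eg$vectors %*% (pmax(eg$values, eig_floor) * t(eg$vectors))
}

em_gmm <- function(x, K, labels, tol, max_iter, eig_floor) {
  n <- nrow(x)
  w <- tabulate(labels, K) / n
  w[w == 0] <- 1 / n
  w <- w / sum(w)
  mu <- matrix(0, K, 2)
  Sg <- vector("list", K)
  for (k in seq_len(K)) {
    xk <- x[labels == k, , drop = FALSE]
    if (nrow(xk) < 2) xk <- x
    mu[k, ] <- colMeans(xk)
    Sg[[k]] <- regularise_cov(stats::cov(xk) * (nrow(xk) - 1) / nrow(xk),
                              eig_floor)
  }
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k) w[k] * dmvnorm2(x, mu[k, ],
                                                           Sg[[k]]),
                   numeric(n))
    dens <- matrix(dens, n, K)
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    trace <- c(trace, ll)
    r <- dens / rowsum_d
    nk <- colSums(r)
    w <- nk / n
    for (k in seq_len(K)) {
      mu[k, ] <- colSums(r[, k] * x) / nk[k]
      xc <- sweep(x, 2, mu[k, ])
      Sg[[k]] <- regularise_cov(crossprod(xc * sqrt(r[, k])) / nk[k],
                                eig_floor)
    }
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  dens <- vapply(seq_len(K), function(k) w[k] * dmvnorm2(x, mu[k, ],
                                                         Sg[[k]]),
                 numeric(n))
  dens <- matrix(dens, n, K)
  colnames(mu) <- colnames(x) %||% c("age", "rm1_amplitude")
  list(weights = w, means = mu, covariances = Sg,
       log_likelihood = trace[length(trace)], trace = trace,
       responsibilities = dens / rowSums(dens))
}

#' @export
print.gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture: K = %d, n = %d, logL = %.2f (AIC %.2f, BIC %.2f)\n",
              x$K, x$n, x$log_likelihood, x$AIC, x$BIC))
  for (k in seq_len(x$K)) {
    cat(sprintf("  comp %d: weight %.3f, mean (%.2f, %.2f)\n", k,
                x$weights[k], x$means[k, 1], x$means[k, 2]))
  }
  invisible(x)
}

#' @export
logLik.gmm <- function(object, ...) {
  structure(object$log_likelihood, df = object$k_params, class = "logLik")
}

#' Information-criterion comparison across component counts
#'
#' Fits a mixture for each requested K and tabulates AIC and BIC with
#' differences relative to the single-cluster control model, reported as
#' criterion(K = 1) minus criterion(K), so positive differences favour the
#' multi-cluster model.
#'
#' @param x data matrix as in \code{\link{gmm_fit}}
#' @param K_list component counts to compare (must include 1)
#' @param ... passed to \code{\link{gmm_fit}}
#' @return data.frame with columns \code{K}, \code{logLik}, \code{AIC},
#'   \code{BIC}, \code{dAIC}, \code{dBIC}, plus attribute \code{"fits"}
#' @export
compare_components <- function(x, K_list = c(1, 2), ...) {
  if (!1 %in% K_list) K_list <- c(1, K_list)
  fits <- lapply(K_list, function(K) gmm_fit(x, K = K, ...))
  tab <- data.frame(K = K_list,
                    logLik = vapply(fits, function(f) f$log_likelihood, 0),
                    AIC = vapply(fits, function(f) f$AIC, 0),
                    BIC = vapply(fits, function(f) f$BIC, 0))
  base <- which(K_list == 1)[1]
  tab$dAIC <- tab$AIC[base] - tab$AIC
  tab$dBIC <- tab$BIC[base] - tab$BIC
  attr(tab, "fits") <- fits
  tab
}

#' Assign points to mixture components
#'
#' Maximum-responsibility assignment. The "negative responder" label is
#' attached to the component with the lower amplitude mean (second
#' column), so labels are invariant to component permutations.
#'
#' @param model a fitted \code{\link{gmm_fit}} with K = 2 (any K is
#'   accepted; labels beyond two components are numeric)
#' @param x points to assign (defaults: the responsibilities stored in the
#'   model are reused if \code{x} is missing -- only possible immediately
#'   after fitting)
#' @return list with \code{component} (index), \code{label}
#'   (\code{"negative"}/\code{"positive"} for K = 2), \code{proportions}
#'   (per label) and \code{negative_component}
#' @export
gmm_assign <- function(model, x = NULL) {
  stopifnot(inherits(model, "gmm"))
  r <- if (is.null(x)) model$responsibilities else {
    x <- as.matrix(x)
    dens <- vapply(seq_len(model$K),
                   function(k) model$weights[k] *
                     dmvnorm2(x, model$means[k, ], model$covariances[[k]]),
                   numeric(nrow(x)))
    dens <- matrix(dens, nrow(x), model$K)
    dens / rowSums(dens)
  }
  comp <- max.col(r, ties.method = "first")
  neg <- which.min(model$means[, 2])
  label <- if (model$K == 2) {
    ifelse(comp == neg, "negative", "positive")
  } else {
    as.character(comp)
  }
  prop <- table(factor(label, levels = sort(unique(label)))) / length(label)
  list(component = comp, label = label,
       proportions = as.numeric(prop) |>
         stats::setNames(names(prop)),
       negative_component = neg)
}

#' @export
predict.gmm <- function(object, newdata, ...) {
  gmm_assign(object, newdata)$component
}

#' @export
plot.gmm <- function(x, data = NULL, ...) {
  if (is.null(data)) stop_invalid("supply the data used for fitting")
  asg <- gmm_assign(x, data)
  cols <- c(negative = "steelblue", positive = "firebrick")
  graphics::plot(data[, 1], data[, 2], col = cols[asg$label], pch = 16,
                 xlab = "age (years)", ylab = "rM1 amplitude", ...)
  graphics::points(x$means[, 1], x$means[, 2], pch = 3, cex = 2, lwd = 2)
  invisible(x)
}
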