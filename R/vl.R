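# Variational Laplace core: Gaussian fixed-form variational inference for a
# nonlinear observation model y = g(theta) + e with per-region Gaussian
# noise whose log-precisions are optimised alongside the parameters.
#
# The scheme is Gauss-Newton ascent on the free energy with
# Levenberg-Marquardt damping: each iteration proposes a damped step from
# the best point so far, evaluates the free energy exactly (residuals and
# Jacobian recomputed at the proposal), and accepts only proposals that
# increase it. The recorded trace over accepted iterations is therefore
# non-decreasing by construction.

#' Inversion settings
#'
#' @param max_iterations iteration cap
#' @param tolerance free-energy change below which an accepted iteration
#'   counts towards convergence
#' @param consecutive number of consecutive small changes required
#' @param fd_step finite-difference step for the Jacobian
#' @param fd_method \code{"central"} (default, two model evaluations per
#'   parameter) or \code{"forward"} (one; half the cost per iteration,
#'   useful for large simulation studies)
#' @param h_var prior variance of the per-region noise log-precisions
#'   (0 fixes them at their prior mean)
#' @param h_mean optional prior mean for the noise log-precisions; by
#'   default set from the data variance (noise at half the data variance)
#' @param damping,damp_down,damp_up initial Levenberg-Marquardt damping and
#'   its multipliers on acceptance/rejection
#' @param max_rejections consecutive rejected proposals before the search
#'   stops (the current best is returned)
#' @return list of class \code{dcm_settings}
#' @export
dcm_settings <- function(max_iterations = 128, tolerance = 0.01,
                         consecutive = 4, fd_step = 1e-4,
                         fd_method = c("central", "forward"), h_var = 1,
                         h_mean = NULL, damping = 0.5, damp_down = 0.5,
                         damp_up = 8, max_rejections = 8) {
  if (max_iterations < 1) stop_invalid("'max_iterations' must be >= 1")
  if (tolerance <= 0) stop_invalid("'tolerance' must be > 0")
  fd_method <- match.arg(fd_method)
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, consecutive = as.integer(consecutive),
                 fd_step = fd_step, fd_method = fd_method, h_var = h_var,
                 h_mean = h_mean,
                 damping = damping, damp_down = damp_down, damp_up = damp_up,
                 max_rejections = as.integer(max_rejections)),
            class = "dcm_settings")
}

logdet_chol <- function(M) 2 * sum(log(diag(chol(M))))

chol_solve <- function(M, b = NULL, jitter = 1e-10) {
  for (k in 0:6) {
    eps <- if (k == 0) 0 else jitter * 10^k * max(1, mean(diag(M)))
    ch <- tryCatch(chol(M + diag(eps, nrow(M))), error = function(e) NULL)
    if (!is.null(ch)) {
      return(if (is.null(b)) chol2inv(ch) else backsolve(ch, forwardsolve(t(ch), b)))
    }
  }
  stop("matrix could not be factorised")
}

# Evaluate the free energy and sufficient statistics at theta.
# Returns NULL if g() fails (e.g. integrator instability).
vl_eval <- function(theta, y, g, free, mu0, P0, ldetS0, h, h0, hv, fd_step,
                    fd_method = "central") {
  V <- nrow(y); R <- ncol(y); pf <- length(free)
  g0 <- tryCatch(g(theta), error = function(e) NULL)
  if (is.null(g0) || any(!is.finite(g0))) return(NULL)
  e <- y - g0
  J <- matrix(0, V * R, pf)
  for (k in seq_len(pf)) {
    tp <- theta
    tp[free[k]] <- tp[free[k]] + fd_step
    gp <- tryCatch(g(tp), error = function(e) NULL)
    if (is.null(gp)) return(NULL)
    if (fd_method == "central") {
      tm <- theta
      tm[free[k]] <- tm[free[k]] - fd_step
      gm <- tryCatch(g(tm), error = function(e) NULL)
      if (is.null(gm)) return(NULL)
      J[, k] <- (as.numeric(gp) - as.numeric(gm)) / (2 * fd_step)
    } else {
      J[, k] <- (as.numeric(gp) - as.numeric(g0)) / fd_step
    }
  }
  ee <- colSums(e^2)
  JtJ_r <- vector("list", R)
  for (r in seq_len(R)) {
    Jr <- J[(r - 1) * V + seq_len(V), , drop = FALSE]
    JtJ_r[[r]] <- crossprod(Jr)
  }
  # optimise noise log-precisions by Newton ascent (cheap given J, e)
  h_free <- hv > 0
  for (it in 1:8) {
    lam <- exp(h)
    H <- P0
    for (r in seq_len(R)) H <- H + lam[r] * JtJ_r[[r]]
    Sig <- chol_solve(H)
    tr_r <- vapply(seq_len(R), function(r) sum(Sig * JtJ_r[[r]]), 0)
    if (!any(h_free)) break
    gr <- 0.5 * V - 0.5 * lam * (ee + tr_r) - ifelse(h_free, (h - h0) / hv, 0)
    he <- -0.5 * lam * (ee + tr_r) - ifelse(h_free, 1 / hv, Inf)
    step <- ifelse(h_free, pmax(-2, pmin(2, gr / (-he))), 0)
    h <- h + step
    if (max(abs(step)) < 1e-6) break
  }
  lam <- exp(h)
  H <- P0
  for (r in seq_len(R)) H <- H + lam[r] * JtJ_r[[r]]
  Sig <- chol_solve(H)
  tr_r <- vapply(seq_len(R), function(r) sum(Sig * JtJ_r[[r]]), 0)
  dth <- theta[free] - mu0
  acc <- sum(-0.5 * lam * (ee + tr_r) + 0.5 * V * h - 0.5 * V * log(2 * pi))
  klth <- 0.5 * (sum(P0 * Sig) + drop(crossprod(dth, P0 %*% dth)) - pf +
                   ldetS0 - logdet_chol(Sig))
  klh <- 0
  if (any(h_free)) {
    s2 <- 1 / (0.5 * lam * (ee + tr_r) + 1 / hv)
    klh <- sum((0.5 * (s2 / hv + (h - h0)^2 / hv - 1 + log(hv / s2)))[h_free])
  }
  Fv <- acc - klth - klh
  if (!is.finite(Fv)) return(NULL)
  list(F = Fv, e = e, J = J, H = H, Sig = Sig, h = h, lam = lam,
       pred = g0, tr_r = tr_r, ee = ee)
}

#' Variational Laplace inversion of a nonlinear Gaussian model
#'
#' Fits \code{y = g(theta) + e} under a Gaussian prior on \code{theta},
#' with independent Gaussian noise per data column whose log-precision is a
#' hyperparameter. Parameters with exactly zero prior variance are fixed at
#' their prior mean and returned unchanged. Used directly for toy models
#' and as the engine behind \code{\link{dcm_fit}}.
#'
#' @param y data matrix (rows = samples, columns = channels/regions)
#' @param g forward model: function taking the full named parameter vector
#'   and returning a matrix conformable with \code{y}
#' @param prior_mean named numeric vector
#' @param prior_cov prior covariance: a vector of variances or a full
#'   matrix over the same names
#' @param settings a \code{\link{dcm_settings}} list
#' @param start optional starting value for the optimisation (full-length,
#'   named); priors are untouched
#' @return list with \code{mean} (full named posterior mean), \code{cov}
#'   (full posterior covariance; zero rows/columns for fixed parameters),
#'   \code{free_energy}, \code{h} (noise log-precisions), \code{trace}
#'   (free energy over accepted iterations), \code{prediction},
#'   \code{converged}, \code{iterations}
#' @export
vl_laplace <- function(y, g, prior_mean, prior_cov,
                       settings = dcm_settings(), start = NULL) {
  y <- as.matrix(y)
  if (any(!is.finite(y))) stop_invalid("data contain non-finite values")
  V <- nrow(y); R <- ncol(y)
  p <- length(prior_mean)
  nms <- names(prior_mean)
  if (is.null(nms)) stop_invalid("'prior_mean' must be named")
  if (is.matrix(prior_cov)) {
    vdiag <- diag(prior_cov)
  } else {
    vdiag <- as.numeric(prior_cov)
    if (length(vdiag) != p) stop_invalid("'prior_cov' length mismatch")
  }
  free <- which(vdiag > 0)
  if (!length(free)) stop_invalid("no free parameters")
  S0 <- if (is.matrix(prior_cov)) prior_cov[free, free, drop = FALSE] else
    diag(vdiag[free], length(free))
  P0 <- chol_solve(S0)
  ldetS0 <- logdet_chol(S0)
  mu0 <- prior_mean[free]

  # noise hyperparameter priors
  vy <- apply(y, 2, stats::var)
  vy[vy <= 0 | !is.finite(vy)] <- max(vy[vy > 0], 1e-12)
  h0 <- settings$h_mean %||% log(2 / vy)
  h0 <- rep_len(h0, R)
  hv <- rep_len(settings$h_var, R)

  theta <- prior_mean
  if (!is.null(start)) {
    if (length(start) != p) stop_invalid("'start' must match the prior length")
    if (!is.null(names(start))) start <- start[nms]
    theta[free] <- start[free]
  }
  theta[-free] <- prior_mean[-free]   # fixed exactly at the prior mean

  ev <- vl_eval(theta, y, g, free, mu0, P0, ldetS0, h0, h0, hv,
                settings$fd_step, settings$fd_method %||% "central")
  if (is.null(ev)) {
    stop(structure(class = c("bolddcm_convergence", "error", "condition"),
                   list(message = "free energy undefined at the starting point",
                        call = sys.call(-1))))
  }
  best <- list(theta = theta, ev = ev)
  trace <- ev$F
  lm <- settings$damping
  n_small <- 0L; n_reject <- 0L
  converged <- FALSE
  iter <- 0L
  while (iter < settings$max_iterations) {
    iter <- iter + 1L
    be <- best$ev
    grad <- drop(crossprod(be$J, as.numeric(be$e) *
                             rep(be$lam, each = V))) -
      P0 %*% (best$theta[free] - mu0)
    Hd <- be$H + lm * diag(diag(be$H), length(free))
    step <- drop(chol_solve(Hd, grad))
    th_p <- best$theta
    th_p[free] <- th_p[free] + step
    ev_p <- vl_eval(th_p, y, g, free, mu0, P0, ldetS0, be$h, h0, hv,
                    settings$fd_step, settings$fd_method %||% "central")
    if (!is.null(ev_p) && ev_p$F > be$F) {
      dF <- ev_p$F - be$F
      best <- list(theta = th_p, ev = ev_p)
      trace <- c(trace, ev_p$F)
      lm <- max(lm * settings$damp_down, 1e-4)
      n_reject <- 0L
      n_small <- if (dF < settings$tolerance) n_small + 1L else 0L
      if (n_small >= settings$consecutive) {
        converged <- TRUE
        break
      }
    } else {
      lm <- lm * settings$damp_up
      n_reject <- n_reject + 1L
      if (n_reject >= settings$max_rejections) break
    }
  }
  cov_full <- matrix(0, p, p, dimnames = list(nms, nms))
  cov_full[free, free] <- best$ev$Sig
  mean_full <- best$theta
  mean_full[-free] <- prior_mean[-free]
  list(mean = mean_full, cov = cov_full, free_energy = best$ev$F,
       h = best$ev$h, trace = trace, prediction = best$ev$pred,
       converged = converged, iterations = iter, free = free)
}
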