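#' Default priors for subject-level model inversion
#'
#' Gaussian shrinkage priors over the canonical parameter vector. All
#' between-region connections and self-connection log-scalers are
#' informed by the data ("switched on"); driving inputs are switched on
#' only for the hypothesised input regions: lSMA and lPMd under the
#' left-hemisphere-driving variant \code{m1}, rSMA and rPMd under the
#' right-driving variant \code{m2}. Switched-off parameters have exactly
#' zero prior variance and stay at their prior mean (zero) in the
#' posterior.
#'
#' Default variances: between-region A and self log-scalers 1/16; driving
#' inputs 1; decay and transit log-scalers 1/256; per-region observation
#' offsets 1/16. All prior means are zero.
#'
#' @param variant \code{"m1"} (left driving) or \code{"m2"} (right driving)
#' @param regions,conditions label vectors
#' @param driving optional explicit character vector of driving regions,
#'   overriding the variant rule
#' @param variances optional named overrides of the per-field prior
#'   variances (names among \code{A}, \code{selfA}, \code{C}, \code{decay},
#'   \code{transit}, \code{offset})
#' @return object of class \code{dcm_priors} with named \code{mean} and
#'   \code{var} vectors over the \code{\link{par_table}} layout
#' @export
dcm_priors <- function(variant = c("m1", "m2"), regions = motor_regions(),
                       conditions = task_conditions(), driving = NULL,
                       variances = NULL) {
  variant <- match.arg(variant)
  if (is.null(driving)) {
    driving <- switch(variant,
                      m1 = intersect(c("lSMA", "lPMd"), regions),
                      m2 = intersect(c("rSMA", "rPMd"), regions))
  }
  if (!all(driving %in% regions)) stop_invalid("unknown driving regions")
  v_field <- c(A = 1 / 16, selfA = 1 / 16, C = 1, decay = 1 / 256,
               transit = 1 / 256, offset = 1 / 16)
  if (!is.null(variances)) v_field[names(variances)] <- variances
  pt <- par_table(regions, conditions)
  vr <- v_field[pt$field]
  # driving-input switching: C rows only for the driving regions
  isC <- pt$field == "C"
  vr[isC] <- ifelse(regions[pt$i[isC]] %in% driving, v_field[["C"]], 0)
  structure(list(mean = stats::setNames(numeric(nrow(pt)), pt$name),
                 var = stats::setNames(as.numeric(vr), pt$name),
                 table = pt, variant = variant, regions = regions,
                 conditions = conditions, driving = driving),
            class = "dcm_priors")
}

#' @export
print.dcm_priors <- function(x, ...) {
  cat("DCM priors (variant ", x$variant, "): driving input to ",
      paste(x$driving, collapse = ", "), "\n", sep = "")
  on <- sum(x$var > 0)
  cat(on, "of", length(x$var), "parameters switched on\n")
  invisible(x)
}

# Fast forward-model closure: maps the canonical parameter vector straight
# into the integrator without going through set_parameter().
make_dcm_g <- function(template, inputs, method, sample, substeps) {
  R <- length(template$regions); P <- length(template$conditions)
  nA <- R * (R - 1)
  idxA <- which(row(diag(R)) != col(diag(R)))   # column-major off-diagonal
  i_selfA <- nA + seq_len(R)
  i_C <- nA + R + seq_len(R * P)
  i_decay <- nA + R + R * P + 1L
  i_transit <- i_decay + seq_len(R)
  i_offset <- i_decay + R + seq_len(R)
  kc <- bold_coefficients(template$constants)
  cst <- template$constants
  U <- inputs$values
  bps <- inputs$bins_per_scan
  dt0 <- inputs$bin_width
  substeps <- max(1L, as.integer(substeps))
  if (substeps > 1L) {
    U <- U[rep(seq_len(nrow(U)), each = substeps), , drop = FALSE]
    bps <- bps * substeps
    dt0 <- dt0 / substeps
  }
  n_scans <- inputs$n_scans
  sample_bins <- switch(sample,
                        start = (seq_len(n_scans) - 1L) * bps + 1L,
                        mid = (seq_len(n_scans) - 1L) * bps +
                          max(1L, floor(bps / 2)),
                        end = seq_len(n_scans) * bps)
  mcode <- if (method == "rk4") 1L else 0L
  function(theta) {
    A <- matrix(0, R, R)
    A[idxA] <- theta[seq_len(nA)]
    diag(A) <- -0.5 * exp(theta[i_selfA])
    C <- matrix(theta[i_C], R, P)
    res <- dcm_integrate_cpp(
      At = t(A), drive = U %*% t(C),
      kappa = 0.64 * exp(theta[i_decay]),
      tau = 2 * exp(theta[i_transit]),
      gam = cst$gamma, alpha = cst$alpha, E0 = cst$E0, dt = dt0,
      k1 = kc[["k1"]], k2 = kc[["k2"]], k3 = kc[["k3"]], V0 = cst$V0,
      sample_bins = as.integer(sample_bins), method = mcode,
      state_bound = 1e6)
    if (!res$ok) stop("integration diverged")
    sweep(res$y, 2, theta[i_offset], `+`)
  }
}

#' Fit a dynamic causal model to one subject's timeseries
#'
#' Bayesian inversion of the six-region generative model by variational
#' Laplace: Gauss-Newton ascent on the free energy with
#' Levenberg-Marquardt damping, per-region noise log-precisions optimised
#' alongside the parameters, and finite-difference gradients of the
#' integrated forward model. The free energy of the returned fit
#' approximates the log model evidence and is the currency of model
#' comparison (see \code{\link{compare_evidence}}).
#'
#' @param data scans x regions matrix of (mean-corrected) BOLD timeseries;
#'   column order must match \code{priors$regions}
#' @param inputs a \code{\link{rasterize_inputs}} object
#' @param priors a \code{\link{dcm_priors}} object
#' @param settings a \code{\link{dcm_settings}} list
#' @param start optional named starting vector (e.g. a group mean) for the
#'   optimisation; priors are untouched
#' @param constants observation constants for the forward model
#' @param method integrator passed to the forward model
#' @param sample within-scan sampling rule
#' @param substeps integration substeps per microtime bin
#' @return an object of class \code{dcm_fit} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{vcov}, \code{logLik},
#'   \code{fitted}, \code{residuals}, \code{predict}, \code{simulate} and
#'   \code{plot}
#' @seealso \code{\link{dcm_reestimate}}, \code{\link{explained_variance}}
#' @export
dcm_fit <- function(data, inputs, priors = dcm_priors("m1"),
                    settings = dcm_settings(), start = NULL,
                    constants = bold_constants(),
                    method = c("rk4", "euler"),
                    sample = c("mid", "start", "end"), substeps = 1L) {
  method <- match.arg(method)
  sample <- match.arg(sample)
  stopifnot(inherits(priors, "dcm_priors"))
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop_invalid("data contain non-finite values")
  R <- length(priors$regions)
  if (ncol(data) != R) {
    stop_invalid("data have ", ncol(data), " columns; priors expect ", R)
  }
  if (nrow(data) != inputs$n_scans) {
    stop_invalid("data rows (", nrow(data), ") must equal inputs$n_scans (",
                 inputs$n_scans, ")")
  }
  template <- dcm_model(priors$regions, priors$conditions,
                        constants = constants)
  g <- make_dcm_g(template, inputs, method, sample, substeps)
  res <- vl_laplace(data, g, priors$mean, priors$var, settings = settings,
                    start = start)
  structure(list(posterior = list(names = names(priors$mean),
                                  mean = res$mean, cov = res$cov,
                                  free_energy = res$free_energy),
                 h = res$h, trace = res$trace, prediction = res$prediction,
                 converged = res$converged, iterations = res$iterations,
                 data = data, inputs = inputs, priors = priors,
                 settings = settings, template = template, method = method,
                 sample = sample, substeps = substeps),
            class = "dcm_fit")
}

#' Re-estimate a fitted model from an alternative starting point
#'
#' Re-runs the inversion initialised at \code{start_mean} (typically a
#' group-average connectivity) while leaving the priors untouched, and
#' returns whichever of the original and re-estimated fits has the higher
#' free energy. This rescues subjects whose first estimate was stuck in a
#' local optimum.
#'
#' @param fit an existing \code{\link{dcm_fit}}
#' @param start_mean named numeric vector conformable with the priors
#' @return a \code{dcm_fit}, with attribute \code{"improved"} indicating
#'   whether the restart won
#' @export
dcm_reestimate <- function(fit, start_mean) {
  stopifnot(inherits(fit, "dcm_fit"))
  refit <- dcm_fit(fit$data, fit$inputs, fit$priors, fit$settings,
                   start = start_mean, constants = fit$template$constants,
                   method = fit$method, sample = fit$sample,
                   substeps = fit$substeps)
  improved <- refit$posterior$free_energy > fit$posterior$free_energy
  out <- if (improved) refit else fit
  attr(out, "improved") <- improved
  out
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat("Variational Laplace DCM fit\n")
  cat(sprintf("  %d scans x %d regions; variant %s; %d free parameters\n",
              nrow(x$data), ncol(x$data), x$priors$variant,
              sum(x$priors$var > 0)))
  cat(sprintf("  free energy %.2f after %d iterations (%s)\n",
              x$posterior$free_energy, x$iterations,
              if (x$converged) "converged" else "iteration limit"))
  invisible(x)
}

#' @export
summary.dcm_fit <- function(object, ...) {
  free <- object$priors$var > 0
  tab <- data.frame(
    estimate = object$posterior$mean[free],
    sd = sqrt(diag(object$posterior$cov)[free]),
    prior_sd = sqrt(object$priors$var[free]))
  ev <- explained_variance(object)
  out <- list(fit = object, table = tab, explained_variance = ev)
  class(out) <- "summary.dcm_fit"
  out
}

#' @export
print.summary.dcm_fit <- function(x, ...) {
  print(x$fit)
  cat("Explained variance per region (%):\n")
  print(round(x$explained_variance, 1))
  big <- x$table[order(-abs(x$table$estimate / x$table$sd)), ]
  cat("Largest effects (posterior mean, sd):\n")
  print(round(utils::head(big, 10), 4))
  invisible(x)
}

#' @export
coef.dcm_fit <- function(object, ...) object$posterior$mean

#' @export
vcov.dcm_fit <- function(object, ...) object$posterior$cov

#' @export
logLik.dcm_fit <- function(object, ...) {
  structure(object$posterior$free_energy,
            df = sum(object$priors$var > 0), class = "logLik")
}

#' @export
fitted.dcm_fit <- function(object, ...) object$prediction

#' @export
residuals.dcm_fit <- function(object, ...) object$data - object$prediction

#' @export
predict.dcm_fit <- function(object, inputs = object$inputs, ...) {
  g <- make_dcm_g(object$template, inputs, object$method, object$sample,
                  object$substeps)
  y <- g(object$posterior$mean)
  colnames(y) <- object$template$regions
  y
}

#' @export
simulate.dcm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  seed <- seed %||% 1L
  free <- which(object$priors$var > 0)
  L <- t(chol(object$posterior$cov[free, free] +
                diag(1e-12, length(free))))
  g <- make_dcm_g(object$template, object$inputs, object$method,
                  object$sample, object$substeps)
  V <- nrow(object$data); R <- ncol(object$data)
  with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      th <- object$posterior$mean
      th[free] <- th[free] + drop(L %*% stats::rnorm(length(free)))
      y <- g(th) + matrix(stats::rnorm(V * R), V, R) %*%
        diag(exp(-object$h / 2), R)
      colnames(y) <- object$template$regions
      y
    })
  })
}

#' @export
plot.dcm_fit <- function(x, regions = colnames(x$data), ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(regions)),
                       mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  tm <- attr(x$prediction, "time") %||% seq_len(nrow(x$data))
  for (r in regions) {
    graphics::plot(tm, x$data[, r], type = "l", col = "grey60",
                   xlab = "time (s)", ylab = "BOLD", main = r, ...)
    graphics::lines(tm, x$prediction[, r], col = "firebrick", lwd = 2)
  }
  invisible(x)
}

#' Variance explained by the posterior-mean prediction
#'
#' Per-region percentage of (mean-corrected) data variance explained:
#' \code{100 * (1 - RSS / TSS)}. Can be negative for predictions worse
#' than the mean. More than about 10 percent per region is conventionally
#' considered an acceptable fit for this model family. Zero-variance data
#' columns are reported as \code{NA}.
#'
#' @param fit a \code{\link{dcm_fit}}
#' @return named numeric vector of percentages
#' @export
explained_variance <- function(fit) {
  stopifnot(inherits(fit, "dcm_fit"))
  e <- fit$data - fit$prediction
  tss <- apply(fit$data, 2, function(col) sum((col - mean(col))^2))
  out <- 100 * (1 - colSums(e^2) / tss)
  out[tss == 0] <- NA_real_
  stats::setNames(out, colnames(fit$data))
}

#' Compare model evidence via free energies
#'
#' Pairwise log Bayes factors and posterior model probabilities (softmax of
#' the free energies, i.e. uniform model priors). Probabilities are
#' invariant to adding a constant to all free energies.
#'
#' @param free_energies numeric vector (length >= 2), optionally named, of
#'   free energies / log evidences
#' @return list with \code{log_bf} (matrix of \code{F_i - F_j}) and
#'   \code{probability}
#' @examples
#' compare_evidence(c(m1 = 0, m2 = 0))$probability
#' @export
compare_evidence <- function(free_energies) {
  f <- unlist(free_energies)
  if (length(f) < 2) stop_invalid("need at least two models")
  if (any(!is.finite(f))) stop_invalid("free energies must be finite")
  nm <- names(f) %||% paste0("m", seq_along(f))
  lbf <- outer(f, f, `-`)
  dimnames(lbf) <- list(nm, nm)
  z <- exp(f - max(f))
  list(log_bf = lbf, probability = stats::setNames(z / sum(z), nm))
}
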