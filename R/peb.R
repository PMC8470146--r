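#' Between-subjects design matrix
#'
#' Builds the four-regressor second-level design: a constant, the
#' responder-group indicator (1 for negative responders before
#' mean-centring), the residual effect of age after accounting for group,
#' and the residual rM1 response amplitude after accounting for group and
#' age. Columns 2-4 are produced by recursive Gram-Schmidt
#' orthogonalisation with mean-centring, so they are mutually orthogonal
#' and the constant column reads as the group average.
#'
#' @param age numeric vector, years
#' @param group group labels: \code{"negative"}/\code{"positive"}, a
#'   factor, or a 0/1 vector with 1 = negative responder
#' @param rm1_amplitude numeric vector of ipsilateral M1 response
#'   amplitudes
#' @return object of class \code{peb_design}: an N x 4 matrix with column
#'   labels \code{constant}, \code{group}, \code{age}, \code{rm1}
#' @export
peb_design <- function(age, group, rm1_amplitude) {
  n <- length(age)
  if (length(group) != n || length(rm1_amplitude) != n) {
    stop_invalid("covariates must have equal length")
  }
  if (n < 5) stop_invalid("need at least 5 subjects")
  g <- if (is.numeric(group)) as.numeric(group) else
    as.numeric(group == "negative")
  for (nm in c("age", "rm1_amplitude")) {
    if (stats::sd(get(nm)) == 0) {
      stop(structure(class = c("bolddcm_degenerate_design", "error",
                               "condition"),
                     list(message = paste0("covariate '", nm,
                                           "' has zero variance"),
                          call = sys.call(-1))))
    }
  }
  if (stats::sd(g) == 0) {
    stop(structure(class = c("bolddcm_degenerate_design", "error",
                             "condition"),
                   list(message = "only one group present",
                        call = sys.call(-1))))
  }
  X <- matrix(1, n, 1)
  orth <- function(X, v) {           # centre, then residualise on X
    v <- v - mean(v)
    v - X %*% qr.coef(qr(X), v)
  }
  x2 <- orth(X, g)
  x3 <- orth(cbind(X, x2), age)
  x4 <- orth(cbind(X, x2, x3), rm1_amplitude)
  out <- cbind(constant = 1, group = drop(x2), age = drop(x3),
               rm1 = drop(x4))
  structure(out, class = c("peb_design", class(out)),
            orthogonalisation = "recursive Gram-Schmidt with mean-centring")
}

# Per-subject Gaussian likelihood kernel over the selected parameters,
# obtained from the posterior and prior by Bayes rule:
#   ln L_i(theta) = c_i - 0.5 theta' Lambda theta + theta' w
peb_kernels <- function(posteriors, prior_var, free_energies, sel) {
  lapply(seq_along(posteriors), function(i) {
    po <- posteriors[[i]]
    Sig <- po$cov[sel, sel, drop = FALSE]
    mu <- po$mean[sel]
    Pi <- chol_solve(Sig)
    P0 <- diag(1 / prior_var[sel], length(sel))
    Lam <- Pi - P0
    eg <- eigen(Lam, symmetric = TRUE)
    lam_clamped <- pmax(eg$values, 0)
    Lam <- eg$vectors %*% (lam_clamped * t(eg$vectors))
    w <- drop(Pi %*% mu)
    ci <- (free_energies[i] - 0.5 * drop(crossprod(mu, Pi %*% mu)) -
             0.5 * logdet_chol(Sig) + 0.5 * sum(log(prior_var[sel])))
    list(Lam = Lam, w = w, c = ci)
  })
}

#' Hierarchical (parametric empirical Bayes) group model
#'
#' Places a general linear model over per-subject posterior densities:
#' subject parameters are modelled as \code{theta_i = X_i beta + e2} with
#' \code{X_i} the Kronecker expansion of the subject's design row over the
#' M selected parameters, and between-subject covariance \code{e2}
#' estimated with one variance component per parameter field (A, C, decay,
#' transit). Subject posteriors enter as Gaussian likelihood kernels
#' (posterior divided by prior), so the group posterior over the
#' second-level coefficients \code{beta} and the group free energy are
#' available in closed form given the component log-precisions, which are
#' optimised numerically.
#'
#' @param fits list of \code{\link{dcm_fit}} objects (or lists with
#'   \code{posterior} and \code{priors} entries) sharing one parameter
#'   layout and one prior
#' @param design an N x K design matrix, typically \code{\link{peb_design}}
#' @param fields parameter fields entering the group model; self-connection
#'   log-scalers count as field \code{A}
#' @param gamma_var prior variance of the component log-precisions
#' @param scale prior between-subject variance as a fraction of the
#'   first-level prior variance (component baseline); default 1/16
#' @return object of class \code{peb_fit}: list with \code{beta} (named
#'   posterior mean over K x M coefficients, covariate-major),
#'   \code{beta_cov}, \code{free_energy}, \code{gamma}, \code{sigma2}
#'   (between-subject variances per parameter), \code{parameters},
#'   \code{covariates}, \code{design}, plus internals used by
#'   \code{\link{peb_bmr}} and \code{\link{peb_search}}
#' @export
peb_fit <- function(fits, design, fields = c("A", "C", "decay", "transit"),
                    gamma_var = 1, scale = 1 / 16) {
  if (length(fits) < 2) stop_invalid("need at least two subjects")
  design <- as.matrix(design)
  if (nrow(design) != length(fits)) {
    stop_invalid("design rows must match the number of subjects")
  }
  covariates <- colnames(design) %||% paste0("x", seq_len(ncol(design)))
  pri <- fits[[1]]$priors
  nms <- names(pri$mean)
  for (f in fits) {
    if (!identical(names(f$priors$mean), nms) ||
        !identical(unname(f$priors$var), unname(pri$var))) {
      stop_invalid("all subjects must share the same parameters and priors")
    }
  }
  fmap <- pri$table$field
  fmap[fmap == "selfA"] <- "A"
  sel <- which(fmap %in% fields & pri$var > 0)
  if (!length(sel)) stop_invalid("no selected parameters")
  M <- length(sel)
  K <- ncol(design)
  pnames <- nms[sel]
  pfield <- fmap[sel]
  ufields <- intersect(c("A", "C", "decay", "transit"), unique(pfield))
  v0 <- pri$var[sel]

  posts <- lapply(fits, function(f) f$posterior)
  Fs <- vapply(fits, function(f) f$posterior$free_energy, 0)
  kern <- peb_kernels(posts, pri$var, Fs, sel)
  cbeta <- rep(v0, K)                       # prior variance per beta entry
  Cb_inv <- 1 / cbeta
  N <- length(fits)

  evalF <- function(gamma, want_post = FALSE) {
    gf <- stats::setNames(gamma, ufields)
    s2 <- exp(-gf[pfield]) * v0 * scale     # between-subject variances
    S2inv <- 1 / s2
    H <- diag(Cb_inv, K * M)
    gvec <- numeric(K * M)
    const <- 0
    for (i in seq_len(N)) {
      Lam <- kern[[i]]$Lam
      w <- kern[[i]]$w
      Km <- Lam + diag(S2inv, M)
      chK <- chol(Km)
      Kinv <- chol2inv(chK)
      W <- Lam - Lam %*% Kinv %*% Lam
      W <- (W + t(W)) / 2
      b <- S2inv * drop(Kinv %*% w)
      x <- design[i, ]
      H <- H + kronecker(tcrossprod(x), W)
      gvec <- gvec + kronecker(x, b)
      const <- const + kern[[i]]$c -
        0.5 * (2 * sum(log(diag(chK))) + sum(log(s2))) +
        0.5 * drop(crossprod(w, Kinv %*% w))
    }
    Sb <- chol_solve(H)
    mb <- drop(Sb %*% gvec)
    Fv <- const + 0.5 * drop(crossprod(gvec, mb)) -
      0.5 * (sum(log(cbeta)) - logdet_chol(Sb)) -
      0.5 * sum(gamma^2) / gamma_var
    if (!want_post) return(Fv)
    list(F = Fv, beta = mb, Sb = Sb, s2 = s2)
  }

  opt <- stats::optim(rep(0, length(ufields)),
                      function(gm) -evalF(gm),
                      method = if (length(ufields) > 1) "Nelder-Mead" else
                        "Brent",
                      lower = if (length(ufields) == 1) -8 else -Inf,
                      upper = if (length(ufields) == 1) 8 else Inf,
                      control = list(maxit = 400))
  fin <- evalF(opt$par, want_post = TRUE)
  bnames <- as.vector(outer(pnames, covariates,
                            function(p, cv) paste0(cv, ":", p)))
  structure(list(beta = stats::setNames(fin$beta, bnames),
                 beta_cov = fin$Sb,
                 beta_prior_var = stats::setNames(cbeta, bnames),
                 free_energy = fin$F,
                 gamma = stats::setNames(opt$par, ufields),
                 sigma2 = stats::setNames(fin$s2, pnames),
                 parameters = pnames, fields = pfield,
                 covariates = covariates, design = design,
                 n_subjects = N),
            class = "peb_fit")
}

#' @export
print.peb_fit <- function(x, ...) {
  cat("Parametric empirical Bayes group model\n")
  cat(sprintf("  %d subjects, %d parameters x %d covariates (%d coefficients)\n",
              x$n_subjects, length(x$parameters), length(x$covariates),
              length(x$beta)))
  cat(sprintf("  free energy %.2f; component log-precisions: %s\n",
              x$free_energy,
              paste(sprintf("%s = %.2f", names(x$gamma), x$gamma),
                    collapse = ", ")))
  invisible(x)
}

#' @export
coef.peb_fit <- function(object, covariate = NULL, ...) {
  b <- object$beta
  if (is.null(covariate)) return(b)
  M <- length(object$parameters)
  k <- match(covariate, object$covariates)
  if (is.na(k)) stop_invalid("unknown covariate")
  stats::setNames(b[(k - 1) * M + seq_len(M)], object$parameters)
}

#' @export
summary.peb_fit <- function(object, ...) {
  sdv <- sqrt(diag(object$beta_cov))
  data.frame(coefficient = names(object$beta), estimate = object$beta,
             sd = sdv, z = object$beta / sdv, row.names = NULL)
}

#' Bayesian model reduction of a Gaussian posterior
#'
#' Re-evaluates the log evidence and posterior of a Gaussian model under a
#' reduced prior (variances shrunk and/or means moved) without refitting,
#' using the analytic change-of-prior identity. Widening a prior variance
#' beyond the full prior is not supported.
#'
#' @param post_mean,post_cov full-model posterior
#' @param prior_mean,prior_var full-model prior (variance vector)
#' @param red_mean,red_var reduced prior
#' @return list with \code{dF} (reduced minus full log evidence),
#'   \code{mean} and \code{cov} of the reduced posterior
#' @export
gaussian_bmr <- function(post_mean, post_cov, prior_mean, prior_var,
                         red_mean = prior_mean, red_var) {
  if (any(red_var > prior_var * (1 + 1e-9))) {
    stop(structure(class = c("bolddcm_unsupported_reduction", "error",
                             "condition"),
                   list(message = "reduced prior may not be wider than the full prior",
                        call = sys.call(-1))))
  }
  P <- chol_solve(post_cov)
  P0 <- diag(1 / prior_var, length(prior_var))
  Pr0 <- diag(1 / red_var, length(red_var))
  Pr <- P + Pr0 - P0
  Sr <- chol_solve(Pr)
  mr <- drop(Sr %*% (P %*% post_mean + Pr0 %*% red_mean - P0 %*% prior_mean))
  dF <- 0.5 * (logdet_chol(Sr) - logdet_chol(post_cov) +
                 sum(log(prior_var)) - sum(log(red_var))) +
    0.5 * (drop(crossprod(mr, Pr %*% mr)) -
             drop(crossprod(post_mean, P %*% post_mean)) +
             sum(prior_mean^2 / prior_var) - sum(red_mean^2 / red_var))
  list(dF = dF, mean = mr, cov = Sr)
}

#' Reduce a group model by switching off coefficients
#'
#' Applies \code{\link{gaussian_bmr}} to a fitted group model with the
#' named (or indexed) second-level coefficients switched off (prior
#' variance shrunk to near zero, mean zero).
#'
#' @param peb a \code{\link{peb_fit}}
#' @param off coefficient names or indices to switch off
#' @param off_var prior variance representing "off"
#' @return list with \code{dF}, reduced \code{mean} and \code{cov}
#' @export
peb_bmr <- function(peb, off, off_var = 1e-8) {
  stopifnot(inherits(peb, "peb_fit"))
  idx <- if (is.character(off)) match(off, names(peb$beta)) else
    as.integer(off)
  if (any(is.na(idx)) || any(idx < 1) || any(idx > length(peb$beta))) {
    stop_invalid("unknown coefficients in 'off'")
  }
  rv <- peb$beta_prior_var
  rv[idx] <- off_var
  gaussian_bmr(peb$beta, peb$beta_cov, rep(0, length(peb$beta)),
               peb$beta_prior_var, red_var = rv)
}

#' The eight parameter-field sets of the model space
#' @return named list of character vectors over \{A, C, transit, decay\}
#' @export
field_sets <- function() {
  list("all" = c("A", "C", "transit", "decay"),
       "A+C" = c("A", "C"),
       "A+tau+kappa" = c("A", "transit", "decay"),
       "C+tau+kappa" = c("C", "transit", "decay"),
       "A" = "A",
       "C" = "C",
       "tau+kappa" = c("transit", "decay"),
       "none" = character(0))
}

#' Exhaustive comparison over the 64-model space
#'
#' Crosses the eight parameter-field sets for the group-average
#' coefficients with the same eight sets for the group-difference
#' coefficients: each of the 64 candidate reduced group models keeps only
#' the average (constant-column) coefficients of fields in its row set and
#' the difference (group-column) coefficients of fields in its column set,
#' evaluated by Bayesian model reduction. Other covariate columns are left
#' untouched.
#'
#' @param peb a \code{\link{peb_fit}} whose design has \code{constant} and
#'   \code{group} columns (positions 1 and 2 otherwise)
#' @param sets list of field sets, by default \code{\link{field_sets}}
#' @return list with \code{F} (8 x 8 free-energy grid, relative to the full
#'   model), \code{probability} (softmax over the 64 cells) and the
#'   winning cell
#' @export
compare_model_space <- function(peb, sets = field_sets()) {
  stopifnot(inherits(peb, "peb_fit"))
  M <- length(peb$parameters)
  i_avg <- match("constant", peb$covariates)
  i_grp <- match("group", peb$covariates)
  if (is.na(i_avg)) i_avg <- 1L
  if (is.na(i_grp)) i_grp <- 2L
  nS <- length(sets)
  Fg <- matrix(0, nS, nS, dimnames = list(average = names(sets),
                                          difference = names(sets)))
  for (a in seq_len(nS)) {
    for (d in seq_len(nS)) {
      off <- c((i_avg - 1) * M + which(!peb$fields %in% sets[[a]]),
               (i_grp - 1) * M + which(!peb$fields %in% sets[[d]]))
      Fg[a, d] <- if (length(off)) peb_bmr(peb, off)$dF else 0
    }
  }
  z <- exp(Fg - max(Fg))
  pr <- z / sum(z)
  win <- which(Fg == max(Fg), arr.ind = TRUE)[1, ]
  list(F = Fg, probability = pr,
       winner = c(average = names(sets)[win[1]],
                  difference = names(sets)[win[2]]))
}

# Fast single-coefficient switch-off: rank-one change-of-prior identity.
# dF = 0.5*[ln(1 + c*C_kk) - ln(1 + c*S_kk) - c*mu_k^2/(1 + c*S_kk)]
# with c the added prior precision.
bmr_drop_one <- function(mu, Sig, cbeta, k, off_var = 1e-8) {
  cc <- 1 / off_var - 1 / cbeta[k]
  skk <- Sig[k, k]
  0.5 * (log1p(cc * cbeta[k]) - log1p(cc * skk)) -
    0.5 * cc * mu[k]^2 / (1 + cc * skk)
}

#' Greedy search over reduced group models with model averaging
#'
#' Iteratively switches off the second-level coefficient whose removal
#' most increases (or least decreases, while non-negative) the free
#' energy, re-evaluating after every removal, until no single removal
#' improves the evidence. Ties are broken towards the first index. The
#' final model set - the terminal model and its one-coefficient-off
#' neighbours - is averaged weighted by evidence.
#'
#' @param peb a \code{\link{peb_fit}}
#' @param covariates indices of design columns whose coefficients are
#'   searched (default: all)
#' @param off_var prior variance representing "off"
#' @return object of class \code{peb_search}: list with \code{on}
#'   (logical per coefficient), \code{pruned} (names), \code{dF_total},
#'   \code{bma_mean}, \code{bma_cov}, \code{weights}
#' @export
peb_search <- function(peb, covariates = seq_along(peb$covariates),
                       off_var = 1e-8) {
  stopifnot(inherits(peb, "peb_fit"))
  M <- length(peb$parameters)
  nb <- length(peb$beta)
  searchable <- as.vector(outer(seq_len(M), (covariates - 1) * M, `+`))
  mu <- peb$beta
  Sig <- peb$beta_cov
  cb <- peb$beta_prior_var
  on <- rep(TRUE, nb)
  dF_total <- 0
  repeat {
    cand <- intersect(which(on), searchable)
    if (!length(cand)) break
    dFs <- vapply(cand, function(k) bmr_drop_one(mu, Sig, cb, k, off_var), 0)
    best <- which(dFs == max(dFs))[1]
    if (dFs[best] < 0) break
    k <- cand[best]
    cc <- 1 / off_var - 1 / cb[k]
    denom <- 1 + cc * Sig[k, k]
    mu <- mu - (cc * mu[k] / denom) * Sig[, k]
    Sig <- Sig - (cc / denom) * tcrossprod(Sig[, k])
    cb[k] <- off_var
    on[k] <- FALSE
    dF_total <- dF_total + dFs[best]
  }
  # model average over the terminal model and its single-off neighbours
  cand <- intersect(which(on), searchable)
  dFs <- vapply(cand, function(k) bmr_drop_one(mu, Sig, cb, k, off_var), 0)
  w <- exp(c(0, dFs) - max(c(0, dFs)))
  w <- w / sum(w)
  means <- vector("list", length(cand) + 1L)
  covs <- vector("list", length(cand) + 1L)
  means[[1]] <- mu; covs[[1]] <- Sig
  for (j in seq_along(cand)) {
    k <- cand[j]
    cc <- 1 / off_var - 1 / cb[k]
    denom <- 1 + cc * Sig[k, k]
    means[[j + 1L]] <- mu - (cc * mu[k] / denom) * Sig[, k]
    covs[[j + 1L]] <- Sig - (cc / denom) * tcrossprod(Sig[, k])
  }
  bma_mean <- Reduce(`+`, Map(`*`, means, w))
  second <- Reduce(`+`, Map(function(m, S, wt) wt * (S + tcrossprod(m)),
                            means, covs, w))
  bma_cov <- second - tcrossprod(bma_mean)
  structure(list(on = stats::setNames(on, names(peb$beta)),
                 pruned = names(peb$beta)[!on],
                 dF_total = dF_total,
                 bma_mean = stats::setNames(bma_mean, names(peb$beta)),
                 bma_cov = bma_cov, weights = w),
            class = "peb_search")
}

#' @export
print.peb_search <- function(x, ...) {
  cat(sprintf("Greedy model search: %d of %d coefficients pruned (dF = %+.2f)\n",
              length(x$pruned), length(x$on), x$dF_total))
  invisible(x)
}

#' Posterior probability that a coefficient is present
#'
#' Compares the evidence of the fitted group model with the same model
#' with one coefficient switched off: \code{p = 1 / (1 + exp(dF_off))}.
#'
#' @param peb a \code{\link{peb_fit}}
#' @param index coefficient index or name (vectorised)
#' @return probability the coefficient is present
#' @export
parameter_probability <- function(peb, index) {
  stopifnot(inherits(peb, "peb_fit"))
  idx <- if (is.character(index)) match(index, names(peb$beta)) else
    as.integer(index)
  if (any(is.na(idx))) stop_invalid("unknown coefficient")
  vapply(idx, function(k) {
    dF <- bmr_drop_one(peb$beta, peb$beta_cov, peb$beta_prior_var, k)
    1 / (1 + exp(dF))
  }, 0)
}
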