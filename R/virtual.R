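#' Sweep one parameter and predict the ipsilateral M1 response
#'
#' Re-computes the first-order Volterra kernel of a base model with one
#' parameter offset over a range, all other parameters held fixed. Offsets
#' are in Hz for connectivity and driving-input parameters and in log
#' units for the haemodynamic and self-connection log-scalers. A zero
#' offset reproduces the base kernel exactly. Offsets at which the
#' integration diverges are recorded as failures rather than raising.
#'
#' @param base a \code{\link{dcm_model}}
#' @param parameter canonical parameter name (see \code{\link{par_table}})
#' @param offsets numeric vector of offsets around the base value
#' @param condition condition of the impulse (default first, audio+visual)
#' @param region region whose kernel is returned
#' @param duration,bin_width kernel window, seconds
#' @return object of class \code{dcm_sweep}: list with \code{time},
#'   \code{kernels} (time x offsets matrix for \code{region}, NA where
#'   unstable), \code{offsets}, \code{parameter}, \code{failed}
#' @export
perturb_and_predict <- function(base, parameter, offsets,
                                condition = 1L, region = "rM1",
                                duration = 32, bin_width = 0.125) {
  stopifnot(inherits(base, "dcm_model"))
  v0 <- get_parameter(base, parameter)   # validates the name
  if (!region %in% base$regions) stop_invalid("unknown region '", region, "'")
  nt <- max(2L, ceiling(duration / bin_width))
  kern <- matrix(NA_real_, nt, length(offsets))
  failed <- logical(length(offsets))
  tm <- NULL
  for (j in seq_along(offsets)) {
    m <- set_parameter(base, parameter, v0 + offsets[j])
    k <- tryCatch(volterra_kernel(m, condition, duration, bin_width),
                  bolddcm_instability = function(e) NULL,
                  error = function(e) NULL)
    if (is.null(k)) {
      failed[j] <- TRUE
    } else {
      kern[, j] <- k[, region]
      if (is.null(tm)) tm <- attr(k, "time")
    }
  }
  structure(list(time = tm %||% (seq_len(nt) - 0.5) * bin_width,
                 kernels = kern, offsets = offsets, parameter = parameter,
                 region = region, failed = failed, base_value = v0),
            class = "dcm_sweep")
}

#' @export
print.dcm_sweep <- function(x, ...) {
  ext <- apply(x$kernels, 2, function(col) {
    if (all(is.na(col))) NA_real_ else col[which.max(abs(col))]
  })
  cat(sprintf("Parameter sweep of %s (%s): %d offsets, extremum %.3g to %.3g\n",
              x$parameter, x$region, length(x$offsets),
              min(ext, na.rm = TRUE), max(ext, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.dcm_sweep <- function(x, ...) {
  graphics::matplot(x$time, x$kernels, type = "l", lty = 1,
                    col = grDevices::hcl.colors(ncol(x$kernels), "Zissou 1"),
                    xlab = "time (s)", ylab = paste(x$region, "BOLD"),
                    main = x$parameter, ...)
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}

#' Signed extremum and latency of a kernel
#'
#' The response "peak" is the sample of largest absolute value (ties
#' broken towards earlier time); its latency is also reported rounded
#' half-up to the nearest 0.5 s. An all-zero kernel has no defined peak
#' and returns missing values.
#'
#' @param kernel a \code{\link{volterra_kernel}} result, a
#'   \code{\link{perturb_and_predict}} column, or any numeric vector with
#'   a \code{"time"} attribute (otherwise \code{time} must be given)
#' @param region region column when \code{kernel} is a matrix
#' @param time sample times in seconds
#' @return list with \code{amplitude} (signed), \code{latency} (s) and
#'   \code{latency_half} (rounded to the 0.5 s grid)
#' @export
peak_metrics <- function(kernel, region = "rM1", time = attr(kernel, "time")) {
  y <- if (is.matrix(kernel)) {
    if (!is.null(colnames(kernel)) && region %in% colnames(kernel)) {
      kernel[, region]
    } else {
      kernel[, 1]
    }
  } else {
    as.numeric(kernel)
  }
  if (!length(y)) stop_invalid("empty kernel")
  if (is.null(time)) time <- seq_along(y)
  if (all(y == 0)) {
    return(list(amplitude = NA_real_, latency = NA_real_,
                latency_half = NA_real_))
  }
  i <- which.max(abs(y))          # which.max takes the earliest maximum
  lat <- time[i]
  list(amplitude = y[i], latency = lat,
       latency_half = floor(lat * 2 + 0.5) / 2)
}

default_sweep_parameters <- function(base) {
  pt <- par_table(base$regions, base$conditions)
  pt <- pt[pt$field != "offset", ]
  keep <- pt$field %in% c("A", "selfA", "decay", "transit")
  isC <- pt$field == "C"
  keep[isC] <- vapply(pt$name[isC],
                      function(nm) get_parameter(base, nm) != 0, TRUE)
  pt$name[keep]
}

#' Which parameters can flip the sign of the ipsilateral response?
#'
#' Sweeps each parameter of a base model across a symmetric range
#' (connectivity and inputs in Hz; log-scalers in log units) and reports
#' the parameters whose sweep produces rM1 kernels of both signs. For each
#' flipping parameter the sign-change offset is located by bisection to
#' 0.01 resolution. The base kernel must itself have a well-defined sign.
#'
#' @param base a \code{\link{dcm_model}}
#' @param range half-width of the sweep (1 by default: +/- 1 Hz or +/- 1
#'   log unit)
#' @param n_grid sweep grid size (odd keeps a zero offset)
#' @param parameters parameter names to sweep; defaults to all neural
#'   parameters, the nonzero driving inputs, and the haemodynamic
#'   log-scalers
#' @param condition,region,duration,bin_width as in
#'   \code{\link{perturb_and_predict}}
#' @param sign_floor absolute extremum below which a kernel's sign is
#'   treated as indeterminate
#' @return data.frame with one row per swept parameter: \code{parameter},
#'   \code{flips}, \code{flip_offset} (NA when no flip), \code{min_ext},
#'   \code{max_ext}
#' @export
sign_flip_set <- function(base, range = 1, n_grid = 21L, parameters = NULL,
                          condition = 1L, region = "rM1", duration = 32,
                          bin_width = 0.125, sign_floor = 1e-6) {
  stopifnot(inherits(base, "dcm_model"))
  base_kernel <- volterra_kernel(base, condition, duration, bin_width)
  base_ext <- peak_metrics(base_kernel, region)$amplitude
  if (is.na(base_ext) || abs(base_ext) < sign_floor) {
    stop(structure(class = c("bolddcm_indeterminate_sign", "error",
                             "condition"),
                   list(message = "base kernel has no well-defined sign",
                        call = sys.call(-1))))
  }
  parameters <- parameters %||% default_sweep_parameters(base)
  offsets <- seq(-range, range, length.out = n_grid)
  ext_at <- function(parameter, off) {
    sw <- perturb_and_predict(base, parameter, off, condition, region,
                              duration, bin_width)
    apply(sw$kernels, 2, function(col) {
      if (all(is.na(col))) NA_real_ else col[which.max(abs(col))]
    })
  }
  rows <- lapply(parameters, function(pp) {
    ex <- ext_at(pp, offsets)
    valid <- !is.na(ex) & abs(ex) >= sign_floor
    flips <- any(ex[valid] > 0) && any(ex[valid] < 0)
    flip_offset <- NA_real_
    if (flips) {
      # bracket the first sign change between valid grid points (they need
      # not be adjacent if an indeterminate band separates them)
      iv <- which(valid)
      ch <- iv[which(sign(ex[iv][-1]) != sign(ex[iv][-length(iv)]))[1]]
      ch2 <- iv[iv > ch][1]
      lo <- offsets[ch]; hi <- offsets[ch2]
      s_lo <- sign(ex[ch])
      while (hi - lo > 0.01) {
        mid <- (lo + hi) / 2
        em <- ext_at(pp, mid)
        if (is.na(em) || sign(em) == s_lo) lo <- mid else hi <- mid
      }
      flip_offset <- (lo + hi) / 2
    }
    data.frame(parameter = pp, flips = flips, flip_offset = flip_offset,
               min_ext = min(ex, na.rm = TRUE),
               max_ext = max(ex, na.rm = TRUE), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "base_extremum") <- base_ext
  out
}

#' Regression of response amplitudes on connection estimates
#'
#' Ordinary least squares of per-subject rM1 response amplitudes on
#' per-subject connection estimates: per-connection Pearson correlation R
#' and variance explained R-squared, and the joint R-squared of the
#' multi-predictor linear model.
#'
#' @param estimates N x k matrix or data.frame of connection estimates
#'   (one column per connection)
#' @param amplitudes length-N numeric vector
#' @return list with \code{per_connection} (data.frame: connection, R,
#'   R2), \code{joint_R2} and \code{joint_R}
#' @export
connection_amplitude_regression <- function(estimates, amplitudes) {
  X <- as.matrix(estimates)
  n <- length(amplitudes)
  if (nrow(X) != n) stop_invalid("lengths differ")
  if (n < 3) stop_invalid("need at least 3 subjects")
  cn <- colnames(X) %||% paste0("c", seq_len(ncol(X)))
  per <- lapply(seq_len(ncol(X)), function(j) {
    if (stats::sd(X[, j]) == 0) {
      return(data.frame(connection = cn[j], R = NA_real_, R2 = NA_real_))
    }
    r <- stats::cor(X[, j], amplitudes)
    data.frame(connection = cn[j], R = r, R2 = r^2)
  })
  per <- do.call(rbind, per)
  ok <- apply(X, 2, stats::sd) > 0
  joint <- if (any(ok)) {
    Xd <- cbind(1, X[, ok, drop = FALSE])
    beta <- qr.coef(qr(Xd), amplitudes)
    beta[is.na(beta)] <- 0
    pred <- drop(Xd %*% beta)
    1 - sum((amplitudes - pred)^2) / sum((amplitudes - mean(amplitudes))^2)
  } else {
    NA_real_
  }
  list(per_connection = per, joint_R2 = joint, joint_R = sqrt(joint))
}
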