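#' Neural drift of the linear dynamic model
#'
#' Implements \code{dz/dt = A_full z + C u}, where \code{A_full} is the
#' connectivity with parameterised (strictly negative) self-connections on
#' the diagonal. Because the stored convention puts sources in rows, the
#' rate of change of region \code{j} is \code{sum_i A[i, j] z_i}.
#'
#' @param z length-R vector of neural activity (a.u.)
#' @param u length-P vector of condition inputs
#' @param model a \code{\link{dcm_model}}
#' @return length-R vector of rates (Hz)
#' @export
neural_derivative <- function(z, u, model) {
  stopifnot(inherits(model, "dcm_model"))
  R <- length(model$regions); P <- length(model$conditions)
  if (length(z) != R) stop_invalid("'z' must have length ", R)
  if (length(u) != P) stop_invalid("'u' must have length ", P)
  drop(t(full_connectivity(model)) %*% z + model$C %*% u)
}

#' Balloon/windkessel state derivatives
#'
#' Per region: the vasoactive signal decays at rate
#' \code{kappa = 0.64 exp(lambda_kappa)} Hz and is corrected by flow
#' feedback; inflow integrates the signal; venous volume and
#' deoxyhaemoglobin follow the windkessel with transit time
#' \code{tau_j = 2 exp(lambda_tau_j)} s, outflow \code{v^(1/alpha)} and
#' flow-dependent oxygen extraction.
#'
#' @param state list with numeric vectors \code{z}, \code{s}, \code{f},
#'   \code{v}, \code{q}, one entry per region; \code{f}, \code{v}, \code{q}
#'   must be strictly positive
#' @param model a \code{\link{dcm_model}}
#' @return list of derivatives \code{ds}, \code{df}, \code{dv}, \code{dq}
#' @examples
#' m <- dcm_model(regions = "r", conditions = "u")
#' rest <- list(z = 0, s = 0, f = 1, v = 1, q = 1)
#' haemodynamic_derivative(rest, m)  # all zero at the resting fixed point
#' @export
haemodynamic_derivative <- function(state, model) {
  stopifnot(inherits(model, "dcm_model"))
  k <- model$constants
  f <- state$f; v <- state$v; q <- state$q
  if (any(f <= 0) || any(v <= 0) || any(q <= 0)) {
    stop_invalid("'f', 'v' and 'q' must be strictly positive")
  }
  kappa <- decay_rate(model$lambda_kappa)
  tau <- transit_time(model$lambda_tau)
  fout <- v^(1 / k$alpha)
  extraction <- 1 - (1 - k$E0)^(1 / f)
  list(ds = state$z - kappa * state$s - k$gamma * (f - 1),
       df = state$s,
       dv = (f - fout) / tau,
       dq = (f * extraction / k$E0 - fout * q / v) / tau)
}

#' BOLD observation equation
#'
#' Fractional signal change given normalised venous volume and
#' deoxyhaemoglobin; zero at rest (\code{v = q = 1}).
#'
#' @param state list with positive numeric vectors \code{v} and \code{q}
#' @param constants a \code{\link{bold_constants}} object
#' @return fractional BOLD signal change per region
#' @export
bold_observation <- function(state, constants = bold_constants()) {
  v <- state$v; q <- state$q
  if (any(v <= 0) || any(q <= 0)) {
    stop_invalid("'v' and 'q' must be strictly positive")
  }
  k <- bold_coefficients(constants)
  constants$V0 * (k[["k1"]] * (1 - q) + k[["k2"]] * (1 - q / v) +
                    k[["k3"]] * (1 - v))
}

#' Integrate the generative model forward from rest
#'
#' Numerically integrates the coupled neural and haemodynamic system over
#' the microtime grid of the input matrix and samples the predicted BOLD
#' signal once per scan. Haemodynamic states are propagated in log space so
#' flow, volume and deoxyhaemoglobin stay strictly positive. The default
#' integrator is fixed-step fourth-order Runge-Kutta at the bin width
#' (around TR/16, small against all haemodynamic time constants); a forward
#' Euler mode is available for cross-checks.
#'
#' @param model a \code{\link{dcm_model}}
#' @param inputs a \code{\link{rasterize_inputs}} result (or a compatible
#'   list with \code{values}, \code{bins_per_scan}, \code{n_scans},
#'   \code{bin_width})
#' @param method \code{"rk4"} or \code{"euler"}
#' @param sample within-scan sampling rule: \code{"mid"} (default),
#'   \code{"start"}, \code{"end"}, or \code{"bins"} to return every
#'   microtime bin (used for kernels)
#' @param substeps integration substeps per microtime bin (>= 1); 1 uses the
#'   bin width directly
#' @param state_bound abort threshold on the state norm; exceeding it raises
#'   an instability error naming the extreme parameters
#' @return matrix (scans x regions, or bins x regions for
#'   \code{sample = "bins"}) of fractional BOLD change, with a \code{"time"}
#'   attribute in seconds
#' @export
integrate_forward <- function(model, inputs, method = c("rk4", "euler"),
                              sample = c("mid", "start", "end", "bins"),
                              substeps = 1L, state_bound = 1e6) {
  stopifnot(inherits(model, "dcm_model"))
  method <- match.arg(method)
  sample <- match.arg(sample)
  U <- inputs$values
  R <- length(model$regions); P <- length(model$conditions)
  if (ncol(U) != P) stop_invalid("inputs have ", ncol(U), " conditions, model has ", P)
  bps <- inputs$bins_per_scan
  n_scans <- inputs$n_scans
  dt <- inputs$bin_width
  substeps <- max(1L, as.integer(substeps))
  if (substeps > 1L) {  # refine the grid, repeating each bin's input
    U <- U[rep(seq_len(nrow(U)), each = substeps), , drop = FALSE]
    bps <- bps * substeps
    dt <- dt / substeps
  }
  sample_bins <- switch(
    sample,
    bins = seq_len(nrow(U)),
    start = (seq_len(n_scans) - 1L) * bps + 1L,
    mid = (seq_len(n_scans) - 1L) * bps + max(1L, floor(bps / 2)),
    end = seq_len(n_scans) * bps)
  kc <- bold_coefficients(model$constants)
  drive <- U %*% t(model$C)
  res <- dcm_integrate_cpp(
    At = t(full_connectivity(model)), drive = drive,
    kappa = decay_rate(model$lambda_kappa),
    tau = transit_time(model$lambda_tau),
    gam = model$constants$gamma, alpha = model$constants$alpha,
    E0 = model$constants$E0, dt = dt,
    k1 = kc[["k1"]], k2 = kc[["k2"]], k3 = kc[["k3"]],
    V0 = model$constants$V0,
    sample_bins = as.integer(sample_bins),
    method = if (method == "rk4") 1L else 0L,
    state_bound = state_bound)
  if (!res$ok) {
    th <- model_to_theta(model)
    th <- th[!startsWith(names(th), "offset")]
    worst <- names(sort(abs(th), decreasing = TRUE))[seq_len(min(3, length(th)))]
    stop(structure(
      class = c("bolddcm_instability", "error", "condition"),
      list(message = sprintf(
        "forward integration diverged at bin %d (t = %.2f s); largest-magnitude parameters: %s",
        res$bad_bin, res$bad_bin * dt,
        paste(sprintf("%s = %.3g", worst, th[worst]), collapse = ", ")),
        call = sys.call(-1), bad_bin = res$bad_bin, parameters = th)))
  }
  y <- res$y
  colnames(y) <- model$regions
  attr(y, "time") <- (sample_bins - 0.5) * dt
  y
}

#' First-order Volterra kernel of the generative model
#'
#' The model's impulse response: the predicted BOLD timecourse following a
#' single unit event in one condition at time zero, starting from rest.
#' Sampled on the microtime grid so peak latencies can be resolved finely.
#'
#' @param model a \code{\link{dcm_model}}
#' @param condition condition index or label receiving the impulse
#' @param duration kernel length in seconds (default 32 s, enough for the
#'   haemodynamic response to return to baseline)
#' @param bin_width microtime resolution in seconds
#' @param input_height indicator height of the impulse (1 for a unit event)
#' @param ... passed to \code{\link{integrate_forward}}
#' @return object of class \code{dcm_kernel}: matrix (time x regions) with a
#'   \code{"time"} attribute
#' @export
volterra_kernel <- function(model, condition = 1L, duration = 32,
                            bin_width = 0.125, input_height = 1, ...) {
  stopifnot(inherits(model, "dcm_model"))
  check_scalar(duration, "duration")
  if (duration <= 0) stop_invalid("'duration' must be positive")
  if (is.character(condition)) {
    condition <- match(condition, model$conditions)
    if (is.na(condition)) stop_invalid("unknown condition")
  }
  P <- length(model$conditions)
  nbin <- max(2L, ceiling(duration / bin_width))
  U <- matrix(0, nbin, P)
  U[1L, condition] <- input_height
  inputs <- list(values = U, bins_per_scan = 1L, n_scans = nbin,
                 bin_width = bin_width)
  y <- integrate_forward(model, inputs, sample = "bins", ...)
  class(y) <- c("dcm_kernel", class(y))
  y
}

#' @export
print.dcm_kernel <- function(x, ...) {
  tm <- attr(x, "time")
  cat(sprintf("First-order Volterra kernel: %d samples over %.1f s, %d regions\n",
              nrow(x), max(tm), ncol(x)))
  ext <- apply(x, 2, function(col) col[which.max(abs(col))])
  cat("Signed extrema (fractional signal):\n")
  print(signif(ext, 3))
  invisible(x)
}
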