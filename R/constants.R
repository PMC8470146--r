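#' BOLD observation constants
#'
#' Fixed physical constants of the BOLD observation equation and the balloon
#' model, tuned for a 3 Tesla echo-planar acquisition. The frequency offset
#' at the outer surface of magnetised vessels scales linearly with field
#' strength, \code{nu0 = 28.265 * B0}, giving 84.8 Hz at 3 T. The
#' intra/extra-vascular signal ratio \code{epsilon} is fixed (not estimated)
#' for numerical stability; the resting venous volume fraction is 4 percent
#' and the intravascular relaxation slope \code{r0} is 110 Hz.
#'
#' @param B0 main magnetic field strength in Tesla
#' @param TE echo time in seconds
#' @param epsilon ratio of intra- to extra-vascular signal contributions
#' @param V0 resting venous blood volume fraction, in (0, 1)
#' @param r0 intravascular relaxation slope in Hz
#' @param nu0 frequency offset at the vessel surface in Hz; derived from
#'   \code{B0} by default
#' @param E0 resting oxygen extraction fraction, in (0, 1)
#' @param gamma rate of flow-dependent feedback on the vasoactive signal, Hz
#' @param alpha Grubb's vessel stiffness exponent, in (0, 1)
#' @return an object of class \code{bold_constants}
#' @examples
#' k <- bold_constants()
#' k$nu0              # 84.795 Hz at 3 T
#' bold_coefficients(k)
#' @export
bold_constants <- function(B0 = 3, TE = 0.03, epsilon = 0.46, V0 = 0.04,
                           r0 = 110, nu0 = 28.265 * B0, E0 = 0.4,
                           gamma = 0.32, alpha = 0.32) {
  for (nm in c("B0", "TE", "epsilon", "V0", "r0", "nu0", "E0", "gamma",
               "alpha")) {
    v <- get(nm)
    check_scalar(v, nm)
    if (v <= 0) stop_invalid("'", nm, "' must be strictly positive")
  }
  if (V0 >= 1) stop_invalid("'V0' must lie in (0, 1)")
  if (E0 >= 1) stop_invalid("'E0' must lie in (0, 1)")
  if (alpha >= 1) stop_invalid("'alpha' must lie in (0, 1)")
  structure(
    list(B0 = B0, TE = TE, epsilon = epsilon, V0 = V0, r0 = r0, nu0 = nu0,
         E0 = E0, gamma = gamma, alpha = alpha),
    class = "bold_constants"
  )
}

#' @export
print.bold_constants <- function(x, ...) {
  cat("BOLD observation constants (", x$B0, "T):\n", sep = "")
  cat(sprintf("  TE = %g s, epsilon = %g, V0 = %g, r0 = %g Hz, nu0 = %g Hz\n",
              x$TE, x$epsilon, x$V0, x$r0, x$nu0))
  cat(sprintf("  E0 = %g, gamma = %g Hz, alpha = %g\n",
              x$E0, x$gamma, x$alpha))
  k <- bold_coefficients(x)
  cat(sprintf("  k1 = %.4f, k2 = %.4f, k3 = %.4f\n", k[1], k[2], k[3]))
  invisible(x)
}

#' Coefficients of the BOLD observation equation
#'
#' The observed fractional signal change is
#' \code{y = V0 * (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))} with
#' \code{k1 = 4.3 nu0 E0 TE}, \code{k2 = epsilon r0 E0 TE} and
#' \code{k3 = 1 - epsilon}, where \code{q} and \code{v} are normalised
#' deoxyhaemoglobin content and venous volume.
#'
#' @param constants a \code{\link{bold_constants}} object
#' @return named numeric vector \code{c(k1, k2, k3)}
#' @export
bold_coefficients <- function(constants = bold_constants()) {
  stopifnot(inherits(constants, "bold_constants"))
  c(k1 = 4.3 * constants$nu0 * constants$E0 * constants$TE,
    k2 = constants$epsilon * constants$r0 * constants$E0 * constants$TE,
    k3 = 1 - constants$epsilon)
}

#' Self-connection strength from its log-scaling parameter
#'
#' Self-connections must be inhibitory for the neural dynamics to be stable,
#' so they are parameterised as \code{-0.5 * exp(lambda)} Hz: negative for
#' every finite \code{lambda}, and -0.5 Hz at \code{lambda = 0}.
#'
#' @param lambda unitless log-scaling parameter (vectorised)
#' @return self-connection strength in Hz, always negative
#' @examples
#' self_connection_strength(0)       # -0.5
#' self_connection_strength(log(2))  # -1.0
#' @export
self_connection_strength <- function(lambda) {
  if (!is.numeric(lambda) || any(!is.finite(lambda))) {
    stop_invalid("'lambda' must be finite")
  }
  -0.5 * exp(lambda)
}

#' Vasoactive signal decay rate from its log-scaling parameter
#'
#' @param lambda unitless log-scaling parameter
#' @return decay rate kappa in Hz; 0.64 Hz at \code{lambda = 0}
#' @export
decay_rate <- function(lambda) {
  if (!is.numeric(lambda) || any(!is.finite(lambda))) {
    stop_invalid("'lambda' must be finite")
  }
  0.64 * exp(lambda)
}

#' Venous transit time from its log-scaling parameter
#'
#' @param lambda unitless log-scaling parameter
#' @return transit time tau in seconds; 2 s at \code{lambda = 0}
#' @export
transit_time <- function(lambda) {
  if (!is.numeric(lambda) || any(!is.finite(lambda))) {
    stop_invalid("'lambda' must be finite")
  }
  2 * exp(lambda)
}

#' Empirical prior over the intra/extra-vascular signal ratio
#'
#' Evaluates \code{epsilon = exp(-TE/T2i) / exp(-TE/T2e)} on a grid of
#' intravascular and extravascular relaxation times and fits a lognormal
#' density to the resulting set of ratios. With the literature ranges
#' (T2i* 15--25 ms, T2e* 30--45 ms, 0.5 ms steps, TE 30 ms) the fitted
#' location is close to \code{log(0.46)}, motivating the fixed value used in
#' \code{\link{bold_constants}}.
#'
#' @param T2i_range intravascular relaxation time range in ms
#' @param T2e_range extravascular relaxation time range in ms
#' @param step grid step in ms
#' @param TE echo time in ms
#' @param criterion \code{"mle"} fits by maximum likelihood on log ratios;
#'   \code{"moments"} matches the mean and variance of the log ratios (for a
#'   lognormal these coincide up to the n vs n-1 variance divisor)
#' @return list with \code{meanlog}, \code{sdlog2} (variance of the log),
#'   the grid size \code{n} and the evaluated \code{values}
#' @export
epsilon_prior_fit <- function(T2i_range = c(15, 25), T2e_range = c(30, 45),
                              step = 0.5, TE = 30,
                              criterion = c("mle", "moments")) {
  criterion <- match.arg(criterion)
  for (r in list(T2i_range, T2e_range)) {
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2]) {
      stop_invalid("relaxation time ranges must be positive with min <= max")
    }
  }
  check_scalar(step, "step")
  if (step <= 0) stop_invalid("'step' must be positive")
  t2i <- seq(T2i_range[1], T2i_range[2], by = step)
  t2e <- seq(T2e_range[1], T2e_range[2], by = step)
  if (!length(t2i) || !length(t2e)) stop_invalid("empty grid")
  grid <- expand.grid(T2i = t2i, T2e = t2e)
  eps <- exp(-TE / grid$T2i) / exp(-TE / grid$T2e)
  le <- log(eps)
  meanlog <- mean(le)
  n <- length(le)
  sdlog2 <- if (criterion == "mle") sum((le - meanlog)^2) / n else
    stats::var(le)
  list(meanlog = meanlog, sdlog2 = sdlog2, n = n, values = eps)
}
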