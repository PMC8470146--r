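#' Two-component (age, rM1 amplitude) mixture of the study cohort
#'
#' Parameters of the two-dimensional Gaussian mixture describing the joint
#' distribution of age (years) and ipsilateral M1 response amplitude in the
#' motivating cohort: a younger, mainly-negative-BOLD component (weight
#' 0.46) and an older, mainly-positive component (weight 0.54).
#'
#' @return list with \code{weights}, \code{means} (2 x 2, rows =
#'   components, columns = age/amplitude) and \code{covariances} (list of
#'   2 x 2 matrices)
#' @export
printed_mixture <- function() {
  list(
    weights = c(negative = 0.46, positive = 0.54),
    means = rbind(negative = c(age = 44.77, rm1_amplitude = -3.53),
                  positive = c(age = 62.07, rm1_amplitude = 4.51)),
    covariances = list(
      negative = matrix(c(289.71, -11.16, -11.16, 5.20), 2, 2,
                        dimnames = list(c("age", "rm1_amplitude"),
                                        c("age", "rm1_amplitude"))),
      positive = matrix(c(238.31, -12.43, -12.43, 8.12), 2, 2,
                        dimnames = list(c("age", "rm1_amplitude"),
                                        c("age", "rm1_amplitude"))))
  )
}

#' Sample (age, rM1 amplitude) pairs from the cohort mixture
#'
#' @param n number of subjects
#' @param seed integer seed
#' @param mixture mixture parameters, by default \code{\link{printed_mixture}}
#' @return data.frame with columns \code{age}, \code{rm1_amplitude} and the
#'   generating \code{component} label
#' @examples
#' head(sample_printed_mixture(5, seed = 1))
#' @export
sample_printed_mixture <- function(n, seed = 1L, mixture = printed_mixture()) {
  check_scalar(n, "n")
  if (n < 1 || n != round(n)) stop_invalid("'n' must be a count >= 1")
  comps <- rownames(mixture$means)
  with_seed(seed, {
    z <- sample(comps, n, replace = TRUE, prob = mixture$weights)
    out <- matrix(NA_real_, n, 2)
    for (cc in comps) {
      idx <- which(z == cc)
      if (!length(idx)) next
      L <- t(chol(mixture$covariances[[cc]]))
      e <- matrix(stats::rnorm(2 * length(idx)), 2)
      out[idx, ] <- t(mixture$means[cc, ] + L %*% e)
    }
    data.frame(age = out[, 1], rm1_amplitude = out[, 2], component = z,
               stringsAsFactors = FALSE)
  })
}

#' Roster exclusion bookkeeping
#'
#' Applies a set of named exclusion counts to an initial participant
#' roster, as when removing participants with missing data, signal
#' dropout or incidental findings before analysis.
#'
#' @param n_initial initial roster size
#' @param exclusions named integer vector of exclusion counts, applied in
#'   order
#' @return list with \code{n_initial}, \code{exclusions},
#'   \code{n_excluded} and \code{n_final}
#' @examples
#' cohort_exclusions(652, c(missing_or_dropout = 9, stroke = 8))$n_final
#' @export
cohort_exclusions <- function(n_initial, exclusions) {
  check_scalar(n_initial, "n_initial")
  if (any(exclusions < 0)) stop_invalid("exclusion counts must be >= 0")
  if (sum(exclusions) > n_initial) {
    stop_invalid("exclusions exceed the roster size")
  }
  list(n_initial = n_initial, exclusions = exclusions,
       n_excluded = sum(exclusions),
       n_final = n_initial - sum(exclusions))
}

#' Responder-group template models
#'
#' Reference parameterisations for the two responder phenotypes. Both share
#' task input to the left (contralateral) premotor regions and a
#' hierarchical left-to-right network. Negative responders have net
#' inhibitory inter-hemispheric drive onto right M1 (from lM1, lPMd and
#' lSMA), a slightly longer right-hemisphere venous transit and slower
#' vasoactive decay; positive responders have excitatory lSMA/lPMd to rM1
#' connections with a weak inhibitory lM1 to rM1 connection.
#'
#' @param constants observation constants
#' @return a \code{\link{dcm_model}}
#' @export
negative_responder_model <- function(constants = bold_constants()) {
  m <- dcm_model(constants = constants)
  base <- list(
    "C:lSMA:AV" = 0.25, "C:lPMd:AV" = 0.15,
    "C:lSMA:A" = 0.12, "C:lPMd:A" = 0.06,
    "C:lSMA:V" = 0.08, "C:lPMd:V" = 0.1,
    "A:lSMA->lPMd" = 0.2, "A:lSMA->lM1" = 0.15, "A:lPMd->lM1" = 0.35,
    "A:lSMA->rSMA" = 0.25, "A:lPMd->rPMd" = 0.25,
    "A:rSMA->rM1" = 0.1, "A:rPMd->rM1" = 0.1,
    "A:lM1->rM1" = -0.4, "A:lPMd->rM1" = -0.35, "A:lSMA->rM1" = -0.25)
  for (nm in names(base)) m <- set_parameter(m, nm, base[[nm]])
  m$lambda_tau[c("rM1", "rPMd", "rSMA")] <- 0.15
  m$lambda_kappa <- -0.1
  m
}

#' @rdname negative_responder_model
#' @export
positive_responder_model <- function(constants = bold_constants()) {
  m <- negative_responder_model(constants)
  m <- set_parameter(m, "A:lM1->rM1", -0.1)
  m <- set_parameter(m, "A:lPMd->rM1", 0.3)
  m <- set_parameter(m, "A:lSMA->rM1", 0.35)
  m$lambda_tau[c("rM1", "rPMd", "rSMA")] <- 0
  m$lambda_kappa <- 0
  m
}

#' Specification of a synthetic cohort
#'
#' @param n_subjects number of subjects
#' @param base_parameters named list with \code{negative} and
#'   \code{positive} template \code{\link{dcm_model}}s
#' @param p_negative probability of assignment to the negative-responder
#'   group (the cohort mixture weight by default)
#' @param group_deltas named numeric vector of group effects: for each named
#'   canonical parameter, the positive-group population mean is set to the
#'   negative-group template value plus the delta (overriding the positive
#'   template), so the positive-minus-negative mean difference equals the
#'   delta exactly
#' @param between_subject_sd named numeric vector of within-group standard
#'   deviations, keyed by field (\code{A}, \code{selfA}, \code{C},
#'   \code{decay}, \code{transit}) with optional per-parameter overrides by
#'   canonical name
#' @param noise list with \code{model} (\code{"ar1"} or \code{"white"}),
#'   \code{snr} (ratio of signal SD to noise SD, > 0, may be \code{Inf}) and
#'   \code{ar} (AR(1) coefficient in (-1, 1))
#' @param seed integer seed
#' @return an object of class \code{cohort_spec}
#' @export
cohort_spec <- function(n_subjects = 50,
                        base_parameters = list(
                          negative = negative_responder_model(),
                          positive = positive_responder_model()),
                        p_negative = 0.46,
                        group_deltas = numeric(0),
                        between_subject_sd = c(A = 0.08, selfA = 0.08,
                                               C = 0.08, decay = 0.05,
                                               transit = 0.05),
                        noise = list(model = "ar1", snr = 1, ar = 0.2),
                        seed = 1L) {
  check_scalar(n_subjects, "n_subjects")
  if (n_subjects < 1) stop_invalid("'n_subjects' must be >= 1")
  stopifnot(inherits(base_parameters$negative, "dcm_model"),
            inherits(base_parameters$positive, "dcm_model"))
  pt <- par_table(base_parameters$negative$regions,
                  base_parameters$negative$conditions)
  model_names <- pt$name[pt$field != "offset"]
  if (length(group_deltas)) {
    bad <- setdiff(names(group_deltas), model_names)
    if (length(bad)) {
      stop_invalid("group_deltas refer to unknown parameters: ",
                   paste(bad, collapse = ", "))
    }
  }
  if (is.null(noise$snr) || noise$snr <= 0) stop_invalid("'snr' must be > 0")
  if (identical(noise$model, "ar1")) {
    ar <- noise$ar %||% 0.2
    if (abs(ar) >= 1) stop_invalid("AR coefficient must lie in (-1, 1)")
    noise$ar <- ar
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 base_parameters = base_parameters,
                 p_negative = p_negative, group_deltas = group_deltas,
                 between_subject_sd = between_subject_sd, noise = noise,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Sample a synthetic cohort of subject models
#'
#' Draws group labels, applies the group mean structure (templates plus any
#' explicit deltas) and adds independent Gaussian between-subject variation
#' per parameter. Ages are drawn from the age marginal of the corresponding
#' cohort-mixture component so downstream covariate models see a realistic
#' age/group confound. A pure function of the spec (including its seed).
#'
#' @param spec a \code{\link{cohort_spec}}
#' @return list with \code{models} (list of \code{\link{dcm_model}}),
#'   \code{group} (character vector), \code{age} (years) and \code{theta}
#'   (subjects x parameters matrix of generating values)
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  tmpl_neg <- spec$base_parameters$negative
  tmpl_pos <- spec$base_parameters$positive
  th_neg <- model_to_theta(tmpl_neg)
  th_pos <- model_to_theta(tmpl_pos)
  if (length(spec$group_deltas)) {
    nms <- names(spec$group_deltas)
    th_pos[nms] <- th_neg[nms] + spec$group_deltas
  }
  pt <- par_table(tmpl_neg$regions, tmpl_neg$conditions)
  keep <- pt$field != "offset"
  sds <- numeric(sum(keep))
  names(sds) <- pt$name[keep]
  fld <- pt$field[keep]
  bsd <- spec$between_subject_sd
  lookup <- function(nm) if (nm %in% names(bsd)) bsd[[nm]] else NULL
  for (k in seq_along(sds)) {
    sds[k] <- lookup(pt$name[keep][k]) %||% lookup(fld[k]) %||% 0
  }
  # driving inputs are structural: regions without input in either template
  # (and without an explicit delta) do not acquire one through noise
  isC <- fld == "C"
  structural_zero <- isC & th_neg[names(sds)] == 0 & th_pos[names(sds)] == 0 &
    !(names(sds) %in% names(spec$group_deltas))
  sds[structural_zero] <- 0
  mix <- printed_mixture()
  with_seed(spec$seed, {
    group <- ifelse(stats::runif(spec$n_subjects) < spec$p_negative,
                    "negative", "positive")
    theta <- matrix(NA_real_, spec$n_subjects, length(sds),
                    dimnames = list(NULL, names(sds)))
    age <- numeric(spec$n_subjects)
    for (i in seq_len(spec$n_subjects)) {
      mu <- if (group[i] == "negative") th_neg[names(sds)] else
        th_pos[names(sds)]
      # reject draws whose neural dynamics are not dissipative (the model
      # class assumes a stable resting fixed point) or whose sustained
      # inhibition drives the balloon model outside its positive-flow
      # regime; screened with a deliberately dense, amplified event train
      for (try in 1:100) {
        th_i <- mu + stats::rnorm(length(sds), 0, sds)
        mm <- theta_to_model(th_i, tmpl_neg)
        if (max(Re(eigen(full_connectivity(mm),
                         only.values = TRUE)$values)) >= -0.01) next
        mm_amp <- mm
        mm_amp$C <- 1.25 * mm$C
        ok <- tryCatch({
          integrate_forward(mm_amp, screen_inputs(length(tmpl_neg$conditions)))
          TRUE
        }, error = function(e) FALSE)
        if (ok) break
        if (try == 100) stop("could not draw a stable subject")
      }
      theta[i, ] <- th_i
      age[i] <- stats::rnorm(1, mix$means[group[i], "age"],
                             sqrt(mix$covariances[[group[i]]][1, 1]))
    }
    models <- lapply(seq_len(spec$n_subjects), function(i) {
      theta_to_model(theta[i, ], tmpl_neg)
    })
    list(models = models, group = group, age = age, theta = theta)
  })
}

# worst-case screening input: one event per 2 s (the minimum SOA) in every
# condition simultaneously, for 120 s
screen_inputs <- function(P) {
  n_scans <- 60L
  bps <- 8L
  U <- matrix(0, n_scans * bps, P)
  U[seq(1L, n_scans * bps, by = bps), ] <- 1
  list(values = U, bins_per_scan = bps, n_scans = n_scans, bin_width = 0.25)
}

#' Simulate one subject's observed timeseries
#'
#' Integrates the forward model and adds observation noise per the noise
#' specification. The noise standard deviation in each region is the
#' region's prediction SD divided by \code{snr} (regions with a flat
#' prediction get the cohort-median signal SD, so pure-noise channels are
#' still realistic). AR(1) noise is scaled so its marginal SD matches the
#' white-noise case. \code{snr = Inf} returns the forward prediction
#' exactly.
#'
#' @param model a \code{\link{dcm_model}}
#' @param inputs a \code{\link{rasterize_inputs}} result
#' @param noise list with \code{model}, \code{snr}, \code{ar} (see
#'   \code{\link{cohort_spec}})
#' @param seed integer seed
#' @param ... passed to \code{\link{integrate_forward}}
#' @return scans x regions matrix with attribute \code{"signal"} holding
#'   the noiseless prediction
#' @export
simulate_subject_timeseries <- function(model, inputs,
                                        noise = list(model = "white",
                                                     snr = Inf),
                                        seed = 1L, ...) {
  pred <- integrate_forward(model, inputs, ...)
  snr <- noise$snr %||% Inf
  if (snr <= 0) stop_invalid("'snr' must be > 0")
  if (!is.finite(snr)) {
    attr(pred, "signal") <- pred
    return(pred)
  }
  V <- nrow(pred); R <- ncol(pred)
  sds <- apply(pred, 2, stats::sd)
  floor_sd <- stats::median(sds[sds > 0]) %||% 0
  if (!is.finite(floor_sd) || is.na(floor_sd)) floor_sd <- 0
  sds[sds == 0] <- floor_sd
  y <- with_seed(seed, {
    eps <- matrix(stats::rnorm(V * R), V, R)
    if (identical(noise$model, "ar1")) {
      a <- noise$ar %||% 0.2
      eps <- apply(eps, 2, function(e) {
        as.numeric(stats::filter(e * sqrt(1 - a^2), a, method = "recursive"))
      })
    }
    pred + sweep(eps, 2, sds / snr, `*`)
  })
  dimnames(y) <- dimnames(pred)
  attr(y, "time") <- attr(pred, "time")
  attr(y, "signal") <- pred
  y
}

#' Canonical-kernel amplitude of the rM1 response
#'
#' A light-weight stand-in for a voxelwise amplitude estimate: the region's
#' timeseries is regressed on the audio+visual event train convolved with a
#' canonical impulse response (the Volterra kernel of a default one-region
#' model), normalised to unit peak; the returned amplitude is the fitted
#' regression slope, i.e. the peak response in data units.
#'
#' @param data scans x regions timeseries matrix with region column names
#' @param inputs the \code{\link{rasterize_inputs}} object used to generate
#'   or model the data
#' @param region region column to summarise
#' @param condition condition driving the regressor
#' @return scalar fitted peak amplitude
#' @export
response_amplitude <- function(data, inputs, region = "rM1",
                               condition = "AV") {
  if (!region %in% colnames(data)) stop_invalid("region '", region,
                                                "' not in data")
  ref <- dcm_model(regions = "roi", conditions = "u",
                   C = matrix(1, 1, 1))
  h <- volterra_kernel(ref, 1L, duration = 32, bin_width = inputs$bin_width)
  h <- as.numeric(h) / max(abs(h))
  u <- inputs$values[, condition]
  x_bins <- stats::convolve(u, rev(h), type = "open")[seq_along(u)]
  bps <- inputs$bins_per_scan
  mid <- (seq_len(inputs$n_scans) - 1L) * bps + max(1L, floor(bps / 2))
  x <- x_bins[mid]
  y <- data[, region]
  if (stats::sd(x) == 0) return(NA_real_)
  unname(stats::coef(stats::lm(y ~ x))[2])
}
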