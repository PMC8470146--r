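#' Generate a synthetic experimental design
#'
#' Emulates the cued button-press task: audio+visual trials split evenly
#' over three tone frequencies, plus a few audio-only and visual-only
#' trials, in randomised order with stimulus onset asynchronies drawn
#' uniformly within the given bounds. The default counts (40 per tone, 4
#' audio-only, 4 visual-only) give the 128-trial session of the motivating
#' study.
#'
#' @param n_per_tone audio+visual trials per tone frequency
#' @param n_audio_only,n_visual_only unimodal trial counts
#' @param soa_bounds numeric pair: minimum and maximum SOA in seconds
#' @param seed integer seed; identical seeds give identical designs
#' @param tones tone frequencies in Hz
#' @param session_length optional maximum session length in seconds; onsets
#'   beyond it raise an error. By default the session is sized to fit the
#'   drawn onsets plus a 32 s washout.
#' @return an object of class \code{dcm_design}: a data.frame of trials
#'   (\code{onset}, \code{condition} in \{AV, A, V\}, \code{tone_hz},
#'   \code{duration}) with attributes \code{session_length} and
#'   \code{soa_bounds}. Stimulus durations (0.3 s tone, 0.034 s
#'   checkerboard) are carried for documentation; inputs are rasterised as
#'   events.
#' @examples
#' d <- generate_design(seed = 1)
#' nrow(d)               # 128 trials
#' table(d$condition)
#' @export
generate_design <- function(n_per_tone = 40, n_audio_only = 4,
                            n_visual_only = 4, soa_bounds = c(2, 26),
                            seed = 1L, tones = c(300, 600, 1200),
                            session_length = NULL) {
  for (nm in c("n_per_tone", "n_audio_only", "n_visual_only")) {
    v <- get(nm)
    check_scalar(v, nm)
    if (v < 0 || v != round(v)) stop_invalid("'", nm, "' must be a count >= 0")
  }
  if (length(soa_bounds) != 2L || any(!is.finite(soa_bounds)) ||
      soa_bounds[1] <= 0 || soa_bounds[1] > soa_bounds[2]) {
    stop_invalid("'soa_bounds' must satisfy 0 < min <= max")
  }
  n_av <- length(tones) * n_per_tone
  n <- n_av + n_audio_only + n_visual_only
  condition <- c(rep("AV", n_av), rep("A", n_audio_only),
                 rep("V", n_visual_only))
  tone <- c(rep(tones, each = n_per_tone), rep(tones[1], n_audio_only),
            rep(NA_real_, n_visual_only))
  trials <- with_seed(seed, {
    ord <- if (n > 0) sample.int(n) else integer(0)
    soa <- stats::runif(n, soa_bounds[1], soa_bounds[2])
    data.frame(onset = cumsum(soa), condition = condition[ord],
               tone_hz = tone[ord],
               duration = ifelse(condition[ord] == "V", 0.034, 0.3),
               stringsAsFactors = FALSE)
  })
  auto_length <- if (n > 0) max(trials$onset) + 32 else 32
  if (!is.null(session_length)) {
    check_scalar(session_length, "session_length")
    if (n > 0 && max(trials$onset) >= session_length) {
      stop_invalid("trial onsets overflow the requested session length (",
                   session_length, " s)")
    }
  }
  structure(trials,
            session_length = session_length %||% auto_length,
            soa_bounds = soa_bounds,
            class = c("dcm_design", "data.frame"))
}

#' Rasterise a design onto the microtime grid
#'
#' Builds the binary T x P input indicator matrix driving the neural model:
#' each trial sets the entry at the microtime bin containing its onset
#' (half-open bins \code{[t, t + dt)}, onset-to-bin mapping
#' \code{floor(onset / dt)}) in its condition's column. With 261 scans and
#' 16 bins per scan this gives the 4176-bin grid of the motivating study.
#'
#' @param design a \code{\link{generate_design}} result (or any data.frame
#'   with \code{onset} and \code{condition} columns)
#' @param n_scans number of fMRI volumes
#' @param bins_per_scan microtime bins per scan (default 16)
#' @param scan_period repetition time (TR) in seconds (default 2)
#' @return an object of class \code{dcm_inputs}: list with binary matrix
#'   \code{values} (T x 3, columns AV/A/V), \code{bins_per_scan},
#'   \code{n_scans}, \code{bin_width}, \code{scan_period},
#'   \code{conditions}
#' @export
rasterize_inputs <- function(design, n_scans = 261, bins_per_scan = 16,
                             scan_period = 2) {
  for (nm in c("n_scans", "bins_per_scan")) {
    v <- get(nm)
    check_scalar(v, nm)
    if (v < 1 || v != round(v)) stop_invalid("'", nm, "' must be a count >= 1")
  }
  check_scalar(scan_period, "scan_period")
  if (scan_period <= 0) stop_invalid("'scan_period' must be positive")
  conditions <- task_conditions()
  if (!all(c("onset", "condition") %in% names(design))) {
    stop_invalid("design must have 'onset' and 'condition' columns")
  }
  if (nrow(design) && !all(design$condition %in% conditions)) {
    stop_invalid("design conditions must be among ",
                 paste(conditions, collapse = ", "))
  }
  T_bins <- n_scans * bins_per_scan
  dt <- scan_period / bins_per_scan
  U <- matrix(0, T_bins, length(conditions),
              dimnames = list(NULL, conditions))
  if (nrow(design)) {
    bin <- floor(design$onset / dt) + 1L
    if (any(design$onset < 0) || any(bin > T_bins)) {
      bad <- which(design$onset < 0 | bin > T_bins)[1L]
      stop_invalid("trial ", bad, " onset (", design$onset[bad],
                   " s) lies outside the session [0, ",
                   n_scans * scan_period, " s)")
    }
    for (k in seq_len(nrow(design))) {
      U[bin[k], design$condition[k]] <- 1
    }
  }
  structure(list(values = U, bins_per_scan = as.integer(bins_per_scan),
                 n_scans = as.integer(n_scans), bin_width = dt,
                 scan_period = scan_period, conditions = conditions),
            class = "dcm_inputs")
}

#' @export
print.dcm_inputs <- function(x, ...) {
  cat(sprintf("Input matrix: %d bins (%d scans x %d bins/scan, dt = %g s)\n",
              nrow(x$values), x$n_scans, x$bins_per_scan, x$bin_width))
  cat("Events per condition:",
      paste(sprintf("%s = %d", x$conditions, colSums(x$values)),
            collapse = ", "), "\n")
  invisible(x)
}
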