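# Plain-text interchange: BIDS-style events tables, TSV timeseries and
# covariates, JSON model/posterior serialisations. All round-trips are
# lossless to full floating precision (17 significant digits).

read_table_checked <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_invalid(basename(path), ": missing column(s) ",
                 paste(missing, collapse = ", "))
  }
  for (cc in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & df[[cc]] != "n/a")
    if (length(bad)) {
      stop_invalid(basename(path), ": column '", cc, "', row ", bad[1],
                   ": not a number ('", df[[cc]][bad[1]], "')")
    }
    df[[cc]] <- v
  }
  df
}

#' Read and write event tables
#'
#' Tab-separated event tables in the BIDS events dialect with columns
#' \code{onset}, \code{duration}, \code{trial_type} (AV, A or V) and
#' \code{tone_hz} (\code{n/a} for visual-only trials).
#'
#' @param design a \code{\link{generate_design}} result (or compatible
#'   data.frame)
#' @param path file path
#' @return \code{read_events} returns a data.frame with the design
#'   columns; \code{write_events} returns \code{path} invisibly
#' @export
write_events <- function(design, path) {
  df <- data.frame(onset = design$onset, duration = design$duration,
                   trial_type = design$condition,
                   tone_hz = ifelse(is.na(design$tone_hz), "n/a",
                                    format(design$tone_hz)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read_table_checked(path, c("onset", "duration", "trial_type"),
                           c("onset", "duration", "tone_hz"))
  bad <- which(!df$trial_type %in% task_conditions())
  if (length(bad)) {
    stop_invalid(basename(path), ": column 'trial_type', row ", bad[1],
                 ": invalid condition '", df$trial_type[bad[1]], "'")
  }
  data.frame(onset = df$onset, condition = df$trial_type,
             tone_hz = if ("tone_hz" %in% names(df)) df$tone_hz else
               NA_real_,
             duration = df$duration, stringsAsFactors = FALSE)
}

#' Read and write region timeseries
#'
#' Tab-separated, one row per scan, one named column per region.
#' @param y scans x regions matrix with region column names
#' @param path file path
#' @param regions optional required region set (order is preserved from
#'   the file)
#' @export
write_timeseries <- function(y, path) {
  utils::write.table(format(y, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path, regions = NULL) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  if (!is.null(regions)) {
    missing <- setdiff(regions, names(df))
    if (length(missing)) {
      stop_invalid(basename(path), ": missing region column(s) ",
                   paste(missing, collapse = ", "))
    }
  }
  as.matrix(df)
}

#' Read and write subject covariates
#'
#' Tab-separated with columns \code{subject_id}, \code{age},
#' \code{rm1_amplitude} and optionally \code{group}.
#' @param df covariates data.frame
#' @param path file path
#' @export
write_covariates <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  read_table_checked(path, c("subject_id", "age", "rm1_amplitude"),
                     c("age", "rm1_amplitude"))
}

#' Serialise models and posteriors as JSON
#'
#' Lossless (full floating precision) JSON round-trips for
#' \code{\link{dcm_model}} objects and posterior densities.
#'
#' @param model a \code{\link{dcm_model}}
#' @param path file path
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "dcm_model"))
  obj <- list(regions = model$regions, conditions = model$conditions,
              A = unclass(model$A), lambda_A = unname(model$lambda_A),
              C = unclass(model$C), lambda_kappa = model$lambda_kappa,
              lambda_tau = unname(model$lambda_tau),
              constants = unclass(model$constants))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("regions", "conditions", "A", "C")) {
    if (is.null(obj[[f]])) stop_invalid(basename(path), ": missing '", f, "'")
  }
  dcm_model(regions = obj$regions, conditions = obj$conditions,
            A = matrix(unlist(obj$A), length(obj$regions)),
            lambda_A = obj$lambda_A,
            C = matrix(unlist(obj$C), length(obj$regions)),
            lambda_kappa = obj$lambda_kappa, lambda_tau = obj$lambda_tau,
            constants = do.call(bold_constants, as.list(obj$constants)))
}

#' @rdname write_model_json
#' @param fit a \code{\link{dcm_fit}} or a list with \code{names},
#'   \code{mean}, \code{cov}, \code{free_energy}
#' @export
write_posterior_json <- function(fit, path) {
  po <- if (inherits(fit, "dcm_fit")) fit$posterior else fit
  obj <- list(names = po$names %||% names(po$mean),
              mean = unname(po$mean), covariance = unclass(po$cov),
              free_energy = po$free_energy)
  if (inherits(fit, "dcm_fit")) {
    obj$settings <- unclass(fit$settings)
    obj$variant <- fit$priors$variant
  }
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @param peb a \code{\link{peb_fit}} group model
#' @export
write_group_json <- function(peb, path) {
  stopifnot(inherits(peb, "peb_fit"))
  obj <- list(parameters = peb$parameters, covariates = peb$covariates,
              beta = unname(peb$beta), beta_cov = unclass(peb$beta_cov),
              gamma = as.list(peb$gamma), sigma2 = unname(peb$sigma2),
              free_energy = peb$free_energy, design = unclass(peb$design),
              n_subjects = peb$n_subjects)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @param gmm a fitted \code{\link{gmm_fit}} mixture
#' @export
write_cluster_json <- function(gmm, path) {
  stopifnot(inherits(gmm, "gmm"))
  obj <- list(K = gmm$K, weights = gmm$weights, means = unclass(gmm$means),
              covariances = lapply(gmm$covariances, unclass),
              log_likelihood = gmm$log_likelihood, AIC = gmm$AIC,
              BIC = gmm$BIC, n = gmm$n)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_posterior_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("names", "mean", "covariance")) {
    if (is.null(obj[[f]])) stop_invalid(basename(path), ": missing '", f, "'")
  }
  p <- length(obj$names)
  cv <- matrix(unlist(obj$covariance), p, p,
               dimnames = list(obj$names, obj$names))
  list(names = obj$names,
       mean = stats::setNames(as.numeric(obj$mean), obj$names),
       cov = cv, free_energy = obj$free_energy)
}
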