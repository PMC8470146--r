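#' Default region and condition labels of the motor network
#'
#' Six motor regions (primary motor cortex, dorsal premotor cortex and SMA,
#' left and right) and the three task conditions (audio+visual, audio only,
#' visual only).
#' @export
motor_regions <- function() c("lM1", "lPMd", "lSMA", "rM1", "rPMd", "rSMA")

#' @rdname motor_regions
#' @export
task_conditions <- function() c("AV", "A", "V")

#' Subject-level generative model
#'
#' Container for all free parameters of one subject's dynamic causal model:
#' between-region effective connectivity \code{A} (Hz; element \code{A[i, j]}
#' is the rate of change of activity in region \code{j} per unit activity in
#' region \code{i}, i.e. rows index sources), self-connection log-scalers
#' \code{lambda_A}, driving inputs \code{C} (Hz, region x condition), the
#' pooled vasoactive decay log-scaler \code{lambda_kappa}, per-region venous
#' transit log-scalers \code{lambda_tau}, and the fixed observation
#' constants.
#'
#' Note on orientation: the stored convention is source-in-rows, so the
#' neural drift is \code{t(A_full) \%*\% z}. Many connectivity papers use
#' the transpose (targets in rows); all functions in this package follow
#' the source-row convention consistently.
#'
#' @param regions character vector of region labels
#' @param conditions character vector of condition labels
#' @param A R x R connectivity matrix in Hz; the diagonal is ignored (self
#'   connections come from \code{lambda_A})
#' @param lambda_A length-R unitless log-scalers for self-connections
#' @param C R x P driving input matrix in Hz
#' @param lambda_kappa scalar log-scaler of the vasoactive decay rate
#' @param lambda_tau length-R log-scalers of the venous transit times
#' @param constants a \code{\link{bold_constants}} object
#' @return an object of class \code{dcm_model}
#' @examples
#' m <- dcm_model()
#' m <- set_parameter(m, "A:lSMA->rM1", 0.3)
#' full_connectivity(m)["lSMA", "rM1"]
#' @export
dcm_model <- function(regions = motor_regions(),
                      conditions = task_conditions(),
                      A = NULL, lambda_A = NULL, C = NULL,
                      lambda_kappa = 0, lambda_tau = NULL,
                      constants = bold_constants()) {
  R <- length(regions)
  P <- length(conditions)
  if (R < 1L || P < 1L) stop_invalid("need at least one region and condition")
  if (is.null(A)) A <- matrix(0, R, R)
  if (is.null(C)) C <- matrix(0, R, P)
  if (is.null(lambda_A)) lambda_A <- rep(0, R)
  if (is.null(lambda_tau)) lambda_tau <- rep(0, R)
  A <- as.matrix(A); C <- as.matrix(C)
  if (!all(dim(A) == c(R, R))) stop_invalid("'A' must be ", R, " x ", R)
  if (!all(dim(C) == c(R, P))) stop_invalid("'C' must be ", R, " x ", P)
  if (length(lambda_A) != R) stop_invalid("'lambda_A' must have length ", R)
  if (length(lambda_tau) != R) stop_invalid("'lambda_tau' must have length ", R)
  check_scalar(lambda_kappa, "lambda_kappa")
  if (any(!is.finite(A)) || any(!is.finite(C)) || any(!is.finite(lambda_A)) ||
      any(!is.finite(lambda_tau))) {
    stop_invalid("model parameters must be finite")
  }
  diag(A) <- 0
  dimnames(A) <- list(source = regions, target = regions)
  dimnames(C) <- list(region = regions, condition = conditions)
  structure(
    list(regions = regions, conditions = conditions, A = A,
         lambda_A = stats::setNames(as.numeric(lambda_A), regions), C = C,
         lambda_kappa = as.numeric(lambda_kappa),
         lambda_tau = stats::setNames(as.numeric(lambda_tau), regions),
         constants = constants),
    class = "dcm_model"
  )
}

#' @export
print.dcm_model <- function(x, ...) {
  cat("Dynamic causal model:", length(x$regions), "regions,",
      length(x$conditions), "conditions\n")
  cat("Regions:", paste(x$regions, collapse = ", "), "\n")
  cat("Between-region connections (Hz, source rows):\n")
  print(round(x$A, 3))
  cat("Driving inputs (Hz):\n")
  print(round(x$C, 3))
  cat("Self log-scalers:", paste(round(x$lambda_A, 3), collapse = " "), "\n")
  cat(sprintf("decay log-scaler %.3f (kappa = %.3f Hz); transit log-scalers %s\n",
              x$lambda_kappa, decay_rate(x$lambda_kappa),
              paste(round(x$lambda_tau, 3), collapse = " ")))
  invisible(x)
}

#' Full connectivity matrix with parameterised self-connections
#'
#' Combines the off-diagonal connectivity with
#' \code{\link{self_connection_strength}} on the diagonal.
#' @param model a \code{\link{dcm_model}}
#' @return R x R matrix in Hz with strictly negative diagonal
#' @export
full_connectivity <- function(model) {
  stopifnot(inherits(model, "dcm_model"))
  A <- model$A
  diag(A) <- self_connection_strength(model$lambda_A)
  A
}

# ---- canonical parameter vocabulary ---------------------------------------

#' Parameter table for a region/condition layout
#'
#' Enumerates the canonical scalar parameters of a subject model in a fixed
#' order: off-diagonal connections \code{A:src->tgt}, self log-scalers
#' \code{selfA:region}, driving inputs \code{C:region:condition}, the pooled
#' \code{decay} log-scaler, per-region \code{transit:region} log-scalers and
#' per-region observation \code{offset:region} terms (used by the inversion
#' to absorb residual signal means).
#'
#' @param regions,conditions label vectors
#' @return data.frame with columns \code{name}, \code{field}, \code{i},
#'   \code{j} (indices into the relevant matrix or vector)
#' @export
par_table <- function(regions = motor_regions(),
                      conditions = task_conditions()) {
  key <- paste(c(regions, "|", conditions), collapse = "\r")
  hit <- .par_table_cache[[key]]
  if (!is.null(hit)) return(hit)
  R <- length(regions); P <- length(conditions)
  rows <- list()
  for (j in seq_len(R)) {        # target-major, sources within target
    for (i in seq_len(R)) {
      if (i == j) next
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0("A:", regions[i], "->", regions[j]),
        field = "A", i = i, j = j, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(R)) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0("selfA:", regions[i]), field = "selfA", i = i, j = NA,
      stringsAsFactors = FALSE)
  }
  for (p in seq_len(P)) {
    for (i in seq_len(R)) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0("C:", regions[i], ":", conditions[p]),
        field = "C", i = i, j = p, stringsAsFactors = FALSE)
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    name = "decay", field = "decay", i = 1L, j = NA, stringsAsFactors = FALSE)
  for (i in seq_len(R)) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0("transit:", regions[i]), field = "transit", i = i, j = NA,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(R)) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0("offset:", regions[i]), field = "offset", i = i, j = NA,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  .par_table_cache[[key]] <- out
  out
}

.par_table_cache <- new.env(parent = emptyenv())

#' Read or modify one canonical parameter of a subject model
#'
#' @param model a \code{\link{dcm_model}}
#' @param name canonical parameter name as listed by \code{\link{par_table}}
#'   (observation offsets are not part of the model and are rejected)
#' @param value replacement value
#' @return \code{get_parameter} returns the scalar value; \code{set_parameter}
#'   the modified model
#' @export
get_parameter <- function(model, name) {
  loc <- locate_parameter(model, name)
  switch(loc$field,
         A = model$A[loc$i, loc$j],
         selfA = unname(model$lambda_A[loc$i]),
         C = model$C[loc$i, loc$j],
         decay = model$lambda_kappa,
         transit = unname(model$lambda_tau[loc$i]))
}

#' @rdname get_parameter
#' @export
set_parameter <- function(model, name, value) {
  check_scalar(value, "value")
  loc <- locate_parameter(model, name)
  switch(loc$field,
         A = { model$A[loc$i, loc$j] <- value },
         selfA = { model$lambda_A[loc$i] <- value },
         C = { model$C[loc$i, loc$j] <- value },
         decay = { model$lambda_kappa <- value },
         transit = { model$lambda_tau[loc$i] <- value })
  model
}

locate_parameter <- function(model, name) {
  stopifnot(inherits(model, "dcm_model"), is.character(name),
            length(name) == 1L)
  pt <- par_table(model$regions, model$conditions)
  k <- match(name, pt$name)
  if (is.na(k)) stop_invalid("unknown parameter '", name, "'")
  loc <- pt[k, ]
  if (loc$field == "offset") {
    stop_invalid("'", name, "' is an observation parameter, not part of the model")
  }
  loc
}

#' Convert between a subject model and the canonical parameter vector
#'
#' @param model a \code{\link{dcm_model}}
#' @param theta named or ordered numeric vector over the full
#'   \code{\link{par_table}} layout (offsets allowed and ignored by the model)
#' @param template model providing layout and constants
#' @return \code{model_to_theta}: named vector (offsets zero);
#'   \code{theta_to_model}: a \code{dcm_model}
#' @export
model_to_theta <- function(model) {
  pt <- par_table(model$regions, model$conditions)
  th <- numeric(nrow(pt))
  for (k in seq_len(nrow(pt))) {
    th[k] <- switch(pt$field[k],
                    A = model$A[pt$i[k], pt$j[k]],
                    selfA = model$lambda_A[pt$i[k]],
                    C = model$C[pt$i[k], pt$j[k]],
                    decay = model$lambda_kappa,
                    transit = model$lambda_tau[pt$i[k]],
                    offset = 0)
  }
  stats::setNames(th, pt$name)
}

#' @rdname model_to_theta
#' @export
theta_to_model <- function(theta, template) {
  stopifnot(inherits(template, "dcm_model"))
  pt <- par_table(template$regions, template$conditions)
  if (is.null(names(theta))) {
    if (length(theta) != nrow(pt)) {
      stop_invalid("unnamed 'theta' must have length ", nrow(pt))
    }
    names(theta) <- pt$name
  }
  k <- match(names(theta), pt$name)
  if (any(is.na(k))) {
    stop_invalid("unknown parameter '", names(theta)[is.na(k)][1], "'")
  }
  m <- template
  fld <- pt$field[k]
  pick <- function(f) which(fld == f)
  for (idx in pick("A")) m$A[pt$i[k[idx]], pt$j[k[idx]]] <- theta[[idx]]
  for (idx in pick("C")) m$C[pt$i[k[idx]], pt$j[k[idx]]] <- theta[[idx]]
  for (idx in pick("selfA")) m$lambda_A[pt$i[k[idx]]] <- theta[[idx]]
  for (idx in pick("transit")) m$lambda_tau[pt$i[k[idx]]] <- theta[[idx]]
  didx <- pick("decay")
  if (length(didx)) m$lambda_kappa <- theta[[didx[1]]]
  m
}

#' Extract per-region observation offsets from a parameter vector
#' @keywords internal
#' @noRd
theta_offsets <- function(theta, regions) {
  off <- rep(0, length(regions))
  nm <- paste0("offset:", regions)
  hit <- nm %in% names(theta)
  off[hit] <- theta[nm[hit]]
  off
}
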