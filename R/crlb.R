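#' Finite-difference Jacobian of a fingerprint
#'
#' Central-difference Jacobian of the complex signal evolution with respect
#' to the parameter vector `theta = (T1, T2, B1, rho)`: T1/T2 in ms, B1 as
#' achieved flip in degrees for the nominal pulse, rho a real scale. The
#' same simulation code that generates the dictionary is differentiated.
#' Steps are relative (`rel_step * theta_i`), falling back to an absolute
#' step for a parameter at zero.
#'
#' @param program A `sequence_program`.
#' @param theta Named or positional numeric vector `(t1, t2, b1, rho)`.
#' @param rel_step Relative step size for the central differences.
#' @param nominal_flip Nominal flip referencing the B1 axis.
#' @param max_order EPG truncation order.
#' @param signal_fn Optional override: a function `theta -> complex vector`
#'   to differentiate instead of the EPG simulation (used for closed-form
#'   validation models).
#' @return Complex N x p Jacobian matrix (N readouts, p parameters).
#' @export
jacobian_fd <- function(program, theta, rel_step = 1e-3,
                        nominal_flip = 60, max_order = 64L,
                        signal_fn = NULL) {
  theta <- as.numeric(theta)
  if (is.null(signal_fn)) {
    if (length(theta) != 4) stop("theta must be (t1, t2, b1, rho)")
    if (theta[2] > theta[1]) stop("theta must satisfy t2 <= t1")
    signal_fn <- function(th) {
      sp <- spin_system(t1 = th[1], t2 = th[2],
                        b1_scale = th[3] / nominal_flip, rho = th[4])
      as.vector(simulate_fingerprint(program, sp, max_order = max_order))
    }
  }
  p <- length(theta)
  base <- signal_fn(theta)
  J <- matrix(0 + 0i, nrow = length(base), ncol = p)
  for (i in seq_len(p)) {
    h <- rel_step * abs(theta[i])
    if (h == 0) h <- rel_step
    up <- theta; up[i] <- up[i] + h
    dn <- theta; dn[i] <- dn[i] - h
    d <- (signal_fn(up) - signal_fn(dn)) / (2 * h)
    if (max(Mod(d)) < 1e-300)
      warning("finite-difference step underflows for parameter ", i)
    J[, i] <- d
  }
  J
}

#' Fisher information from a signal Jacobian
#'
#' Accumulates the Fisher information matrix over readouts for white
#' Gaussian noise of level `sigma` per real and imaginary channel:
#' \deqn{I(\theta) = \sigma^{-2} \sum_n \mathrm{Re}\,(J_n^H J_n)} in the
#' complex-aware convention (default). The `"real"` convention uses only
#' the real parts of the derivatives, matching a strictly real-valued
#' signal model.
#'
#' @param jacobian Complex N x p Jacobian.
#' @param sigma Noise level (only scales the result; protocol sets 1).
#' @param convention `"complex"` (default) or `"real"`.
#' @return Real symmetric p x p positive semi-definite matrix.
#' @export
fisher_information <- function(jacobian, sigma = 1,
                               convention = c("complex", "real")) {
  convention <- match.arg(convention)
  if (sigma <= 0) stop("sigma must be positive")
  fim <- switch(convention,
                complex = Re(Conj(t(jacobian)) %*% jacobian),
                real = crossprod(Re(jacobian)))
  (fim + t(fim)) / 2 / sigma^2
}

#' Normalised Cramer-Rao lower bounds
#'
#' Inverts the Fisher information matrix, takes the per-parameter variance
#' bounds from the diagonal and normalises them by the parameter values,
#' `nCRLB(theta_i) = CRLB(theta_i) / theta_i`. A singular information
#' matrix is handled with a pseudo-inverse: unencoded parameters are
#' reported as infinite and flagged rather than raising an error. An
#' alternative normalisation `sqrt(CRLB)/theta` (a relative standard
#' deviation) is available behind `sqrt_mode`.
#'
#' @param fim p x p Fisher information matrix.
#' @param theta Parameter values used for normalisation.
#' @param sqrt_mode Logical; normalise the root of the variance bound.
#' @return A list with `crlb`, `ncrlb`, `identifiable` (logical per
#'   parameter) and `singular` (logical).
#' @export
normalized_crlb <- function(fim, theta, sqrt_mode = FALSE) {
  theta <- as.numeric(theta)
  p <- ncol(fim)
  stopifnot(length(theta) == p)
  sv <- svd(fim)
  tol <- max(sv$d) * p * .Machine$double.eps * 64
  singular <- any(sv$d <= tol)
  if (!singular) {
    crlb <- diag(solve(fim))
    identifiable <- rep(TRUE, p)
  } else {
    pinv <- MASS::ginv(fim)
    crlb <- diag(pinv)
    null_space <- sv$v[, sv$d <= tol, drop = FALSE]
    identifiable <- apply(abs(null_space) < 1e-8, 1, all)
    crlb[!identifiable] <- Inf
  }
  ncrlb <- if (sqrt_mode) sqrt(crlb) / theta else crlb / theta
  list(crlb = crlb, ncrlb = ncrlb, identifiable = identifiable,
       singular = singular)
}

#' Per-sequence CRLB report
#'
#' @param program A `sequence_program`.
#' @param theta Parameter vector `(t1, t2, b1, rho)`.
#' @param sigma Noise level.
#' @param ... Passed to [jacobian_fd()].
#' @return A one-row tibble of normalised bounds.
#' @export
crlb_report <- function(program, theta, sigma = 1, ...) {
  J <- jacobian_fd(program, theta, ...)
  fim <- fisher_information(J, sigma)
  nc <- normalized_crlb(fim, theta)
  tibble::tibble(sequence = program$name,
                 t1 = theta[1], t2 = theta[2], b1 = theta[3],
                 ncrlb_t1 = nc$ncrlb[1], ncrlb_t2 = nc$ncrlb[2],
                 ncrlb_b1 = nc$ncrlb[3], ncrlb_rho = nc$ncrlb[4],
                 singular = nc$singular)
}

#' Compare the encoding power of sequence variants
#'
#' Computes the normalised CRLB of T1, T2, B1 and rho for every combination
#' of sequence program and tissue parameter vector, reproducing the layout
#' of the protocol's encoding-power comparison (three T2 values at fixed T1
#' and B1).
#'
#' @param programs List of `sequence_program`s.
#' @param theta_list List of parameter vectors `(t1, t2, b1, rho)`; entries
#'   with `t2 > t1` are rejected.
#' @param sigma Noise level.
#' @param ... Passed to [jacobian_fd()].
#' @return A tibble with one row per sequence and theta.
#' @export
compare_sequences <- function(programs, theta_list, sigma = 1, ...) {
  if (!length(programs) || !length(theta_list))
    stop("programs and theta_list must be non-empty")
  for (th in theta_list)
    if (th[2] > th[1]) stop("theta must satisfy t2 <= t1")
  rows <- list()
  for (prog in programs)
    for (th in theta_list)
      rows[[length(rows) + 1L]] <- crlb_report(prog, th, sigma, ...)
  do.call(rbind, rows)
}

#' Write a CRLB report to CSV or JSON
#'
#' @param report Tibble from [compare_sequences()].
#' @param path Output path; format chosen from the extension (.csv/.json).
#' @return The path, invisibly.
#' @export
write_crlb_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(report, path, digits = NA, auto_unbox = FALSE)
  } else {
    utils::write.csv(report, path, row.names = FALSE)
  }
  invisible(path)
}
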