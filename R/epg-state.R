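#' @useDynLib satmrf, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

EPG_AXES <- c("slice", "phase", "read")

# reverse an array along every dimension: a(k) -> a(-k)
rev_all <- function(a) {
  d <- dim(a)
  if (is.null(d)) return(rev(a))
  idx <- lapply(d, function(n) n:1)
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# index (one per axis) of the all-zero configuration
zero_index <- function(state) as.list(state$max_order + 1L)

#' Thermal-equilibrium EPG state
#'
#' Creates an extended-phase-graph configuration-state bank over one or more
#' tracked gradient axes, initialised at thermal equilibrium: unit
#' longitudinal magnetisation in the all-zero configuration and no transverse
#' coherence. The transverse spectrum `F` stores `Mx + i My` amplitudes for
#' configuration orders `-max_order .. max_order` on each axis; the conjugate
#' counterpart F-(k) = Conj(F(-k)) and the longitudinal redundancy
#' Z(-k) = Conj(Z(k)) are implicit.
#'
#' @param axes Character vector of tracked gradient axes, a subset of
#'   `c("slice", "phase", "read")`.
#' @param max_order Truncation order per axis (scalar recycled, or one value
#'   per axis). Must be at least 1.
#' @return An object of class `epg_state` with elements `F`, `Z` (complex
#'   arrays), `axes`, `max_order` and the truncation-loss counter `dropped`.
#' @examples
#' st <- equilibrium_state("slice", max_order = 10)
#' acquire(st)  # no transverse magnetisation yet
#' @export
equilibrium_state <- function(axes = "slice", max_order = 64L) {
  axes <- match.arg(axes, EPG_AXES, several.ok = TRUE)
  max_order <- as.integer(rep(max_order, length.out = length(axes)))
  if (any(max_order < 1)) stop("max_order must be at least 1")
  names(max_order) <- axes
  dims <- 2L * max_order + 1L
  Fm <- array(0 + 0i, dim = dims)
  Z <- array(0 + 0i, dim = dims)
  Z[matrix(max_order + 1L, nrow = 1)] <- 1 + 0i
  structure(list(F = Fm, Z = Z, axes = axes, max_order = max_order,
                 dropped = 0), class = "epg_state")
}

#' @export
print.epg_state <- function(x, ...) {
  cat(sprintf("<epg_state> axes [%s], max_order [%s], |F| %.4g, Z0 %.4g\n",
              paste(x$axes, collapse = ","),
              paste(x$max_order, collapse = ","),
              sqrt(sum(Mod(x$F)^2)),
              Mod(do.call(`[`, c(list(x$Z), zero_index(x))))))
  invisible(x)
}

#' Transverse configuration amplitudes
#'
#' Accessors for the transverse spectrum: `epg_f_plus()` returns F+(k) and
#' `epg_f_minus()` its conjugate counterpart F-(k) = Conj(F(-k)).
#'
#' @param state An `epg_state`.
#' @param order Integer configuration order, one value per tracked axis.
#' @return A complex scalar.
#' @export
epg_f_plus <- function(state, order) {
  idx <- as.list(as.integer(order) + state$max_order + 1L)
  do.call(`[`, c(list(state$F), idx))
}

#' @rdname epg_f_plus
#' @export
epg_f_minus <- function(state, order) {
  Conj(epg_f_plus(state, -as.integer(order)))
}

#' @rdname epg_f_plus
#' @export
epg_z <- function(state, order) {
  idx <- as.list(as.integer(order) + state$max_order + 1L)
  do.call(`[`, c(list(state$Z), idx))
}

#' Total magnetisation norm of an EPG state
#'
#' The square root of the summed squared magnitudes of all transverse and
#' longitudinal configuration amplitudes. By Parseval's identity this equals
#' the root-mean-square magnetisation magnitude over the intra-voxel
#' isochromat ensemble, and is conserved by RF rotations.
#'
#' @param state An `epg_state`.
#' @return A non-negative number.
#' @export
epg_norm <- function(state) {
  sqrt(sum(Mod(state$F)^2) + sum(Mod(state$Z)^2))
}

#' Acquire a sample from an EPG state
#'
#' Returns the rho-scaled transverse amplitude of the all-zero configuration
#' order, optionally demodulated at the transmitter phase of the exciting
#' pulse. Only the zero-order transverse state contributes to the acquired
#' signal.
#'
#' @param state An `epg_state`.
#' @param spin A [spin_system()] supplying `rho`, or `NULL` for `rho = 1`.
#' @param demod_phase Demodulation phase in degrees.
#' @return A complex sample.
#' @export
acquire <- function(state, spin = NULL, demod_phase = 0) {
  rho <- if (is.null(spin)) 1 + 0i else spin$rho
  f0 <- do.call(`[`, c(list(state$F), zero_index(state)))
  rho * f0 * exp(-1i * demod_phase * pi / 180)
}
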