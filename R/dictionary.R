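#' Geometric parameter grid axis
#'
#' Builds the geometric value ladder used for the relaxation-time axes of
#' the dictionary: `v[i] = start * (1 + step_percent/100)^(i-1)`.
#'
#' @param start First value (ms), positive.
#' @param n Number of entries.
#' @param step_percent Incremental step size in percent (protocol: 2.5).
#' @return Numeric vector of length `n`.
#' @examples
#' tail(build_geometric_grid(10, 160, 2.5), 1)  # 507.1 ms
#' @export
build_geometric_grid <- function(start, n, step_percent) {
  if (start <= 0) stop("start must be positive")
  if (n < 1) stop("n must be at least 1")
  start * (1 + step_percent / 100)^(seq_len(n) - 1)
}

#' Dictionary parameter grid
#'
#' Cartesian product of geometric T1 and T2 ladders with a linear ladder of
#' achieved flip angles (the B1 axis, stored in degrees for the 60-degree
#' nominal pulse and converted to a transmit scale at simulation time).
#' Entries with `t2 > t1` are unphysical and excluded. Entry ordering is
#' deterministic: T1-major, then T2, then B1.
#'
#' @param t1_values,t2_values Geometric ladders in ms.
#' @param b1_values Achieved flip angles in degrees.
#' @param nominal_flip Nominal flip angle the B1 axis is referenced to.
#' @return A list of class `parameter_grid` with the axis ladders and the
#'   `entries` tibble (`t1`, `t2`, `b1`, `b1_scale`).
#' @export
parameter_grid <- function(t1_values, t2_values, b1_values = 60,
                           nominal_flip = 60) {
  check_ratio <- function(v, lab) {
    if (length(v) > 2) {
      r <- v[-1] / v[-length(v)]
      if (max(abs(r - r[1])) > 1e-12 * r[1])
        stop(lab, " ladder must be geometric")
    }
  }
  check_ratio(t1_values, "t1")
  check_ratio(t2_values, "t2")
  if (length(b1_values) > 2 &&
      max(abs(diff(diff(b1_values)))) > 1e-9)
    stop("b1 ladder must be linearly spaced")
  entries <- expand.grid(b1 = b1_values, t2 = t2_values, t1 = t1_values,
                         KEEP.OUT.ATTRS = FALSE)[, c("t1", "t2", "b1")]
  entries <- entries[entries$t2 <= entries$t1, , drop = FALSE]
  entries$b1_scale <- entries$b1 / nominal_flip
  rownames(entries) <- NULL
  structure(list(t1_values = t1_values, t2_values = t2_values,
                 b1_values = b1_values, nominal_flip = nominal_flip,
                 entries = tibble::as_tibble(entries)),
            class = "parameter_grid")
}

#' Full-protocol parameter grid
#'
#' The published dictionary axes: 140 T1 entries from 140 ms and 160 T2
#' entries from 10 ms, both at 2.5 percent incremental steps, and achieved
#' flips from 1 to 89 degrees in 1-degree increments. Note the printed T1
#' upper bound (4642 ms) is not consistent with this (start, n, step)
#' triple, which ends near 4333 ms; the printed triple is kept.
#'
#' @param t1_n,t2_n,step_percent Axis sizes and step.
#' @param b1_values Achieved-flip ladder in degrees.
#' @return A [parameter_grid()].
#' @export
mrf_parameter_grid <- function(t1_n = 140, t2_n = 160, step_percent = 2.5,
                               b1_values = 1:89) {
  parameter_grid(build_geometric_grid(140, t1_n, step_percent),
                 build_geometric_grid(10, t2_n, step_percent),
                 b1_values)
}

#' Slice-profile bins
#'
#' Discretises the small-tip excitation profile of a Hann-apodised sinc
#' pulse into transverse-scale bins across the nominal slab. The profile is
#' the Fourier transform of the apodised pulse evaluated at the bin-centre
#' off-resonance frequencies; each bin contributes with equal weight and its
#' flip-scale multiplies the nominal train.
#'
#' @param time_bandwidth Time-bandwidth product of the pulse (protocol: 3).
#' @param n_bins Number of bins across the slab (protocol: 32).
#' @param pulse_shape Only `"sinc_hann"` is supported.
#' @param n_quad Quadrature points for the numerical Fourier evaluation.
#' @return A list of class `slice_profile` with `n_bins`, `bin_scales` and
#'   uniform `bin_weights`.
#' @export
slice_profile_bins <- function(time_bandwidth = 3, n_bins = 32L,
                               pulse_shape = c("sinc_hann"),
                               n_quad = 512L) {
  pulse_shape <- match.arg(pulse_shape)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1) stop("n_bins must be at least 1")
  if (n_bins == 1L)
    return(structure(list(n_bins = 1L, bin_scales = 1, bin_weights = 1,
                          time_bandwidth = time_bandwidth),
                     class = "slice_profile"))
  # unit pulse duration; bandwidth = time_bandwidth in these units
  tt <- seq(-0.5, 0.5, length.out = n_quad)
  b <- sinc(time_bandwidth * tt) * (0.5 + 0.5 * cos(2 * pi * tt))
  # bin centres across the nominal slab (full nominal bandwidth)
  f <- (seq_len(n_bins) - 0.5) / n_bins - 0.5
  f <- f * time_bandwidth
  prof <- vapply(f, function(fr) {
    sum(b * cos(2 * pi * fr * tt)) / sum(b)
  }, numeric(1))
  structure(list(n_bins = n_bins, bin_scales = prof,
                 bin_weights = rep(1 / n_bins, n_bins),
                 time_bandwidth = time_bandwidth),
            class = "slice_profile")
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Simulate a fingerprint dictionary
#'
#' Simulates one fingerprint per grid entry: the slice-profile-weighted sum
#' over profile bins of the EPG signal evolution with flip angles scaled by
#' `bin_scale * b1_scale`. Entry ordering follows the grid (T1-major, then
#' T2, then B1) and the computation is fully deterministic.
#'
#' @param program A `sequence_program`.
#' @param grid A [parameter_grid()].
#' @param profile A `slice_profile` or `NULL` for an ideal profile.
#' @param t1_for_t2_cap Unused placeholder for future fat handling.
#' @param max_order EPG truncation order.
#' @param rho Common complex signal scale of the simulated entries.
#' @return A list of class `mrf_dictionary` with elements `grid`,
#'   `fingerprints` (entries x readouts complex matrix), `program_name`,
#'   `tr`, `te`, and empty compression slots (see [compress_svd()]).
#' @export
simulate_dictionary <- function(program, grid, profile = NULL,
                                max_order = 64L, rho = 1 + 0i,
                                t1_for_t2_cap = NULL) {
  entries <- grid$entries
  if (!nrow(entries)) stop("parameter grid has no entries")
  if (is.null(profile))
    profile <- slice_profile_bins(n_bins = 1L)
  events <- compile_events(program, axes = "slice")
  n_ro <- program$n_readouts
  fp <- matrix(0 + 0i, nrow = nrow(entries), ncol = n_ro)
  for (e in seq_len(nrow(entries))) {
    acc <- complex(n_ro)
    for (b in seq_len(profile$n_bins)) {
      scale <- profile$bin_scales[b] * entries$b1_scale[e]
      res <- epg_run_cpp(events, entries$t1[e], entries$t2[e], scale,
                         as.complex(rho), 0, as.integer(max_order))
      acc <- acc + profile$bin_weights[b] * res$signal
    }
    fp[e, ] <- acc
  }
  structure(list(grid = grid, fingerprints = fp, svd_basis = NULL,
                 compressed = NULL, rank = NULL,
                 program_name = program$name, tr = program$tr,
                 te = program$te, profile = profile),
            class = "mrf_dictionary")
}

#' @export
print.mrf_dictionary <- function(x, ...) {
  cat(sprintf("<mrf_dictionary> %s: %d entries x %d readouts%s\n",
              x$program_name, nrow(x$fingerprints), ncol(x$fingerprints),
              if (is.null(x$rank)) "" else
                sprintf(", SVD rank %d", x$rank)))
  invisible(x)
}

#' SVD time-domain compression of a dictionary
#'
#' Computes the top right singular vectors of the complex fingerprint
#' matrix in the time domain and stores the rank-limited temporal basis and
#' the projected (compressed) entries, together with the relative residual
#' energy left outside the subspace.
#'
#' @param dict An `mrf_dictionary`.
#' @param rank Subspace rank (protocol: 8); at most the readout count.
#' @return The dictionary with `svd_basis` (readouts x rank, orthonormal
#'   columns), `compressed` (entries x rank; `fingerprints ~=
#'   compressed %*% Conj(t(svd_basis))`), `rank` and `residual_energy`.
#' @export
compress_svd <- function(dict, rank = 8L) {
  fp <- dict$fingerprints
  if (rank > ncol(fp) || rank > nrow(fp))
    stop("rank exceeds the fingerprint matrix dimensions")
  sv <- svd(fp, nu = 0, nv = rank)
  basis <- sv$v[, seq_len(rank), drop = FALSE]
  dict$svd_basis <- basis
  dict$compressed <- fp %*% basis
  dict$rank <- as.integer(rank)
  tot <- sum(sv$d^2)
  dict$residual_energy <-
    if (tot > 0) sum(sv$d[-seq_len(rank)]^2) / tot else 0
  dict
}

#' Persist and restore dictionaries
#'
#' Dictionaries are stored as a single RDS container holding the grid
#' ladders, fingerprints, SVD basis and metadata; the payload is
#' deterministic for a fixed configuration, so repeated builds are
#' byte-identical.
#'
#' @param dict An `mrf_dictionary`.
#' @param path File path.
#' @return `write_dictionary` the path invisibly; `read_dictionary` the
#'   dictionary.
#' @export
write_dictionary <- function(dict, path) {
  saveRDS(dict, path, version = 3, compress = FALSE)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) readRDS(path)
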