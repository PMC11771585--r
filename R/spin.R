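#' Tissue / voxel spin system
#'
#' Bundles the physical parameters of one spin population: the relaxation
#' times, the transmit-field scale, a complex signal scale and a constant
#' off-resonance frequency (field inhomogeneity or chemical shift).
#'
#' @param t1 Longitudinal relaxation time in ms. Must be positive.
#' @param t2 Transverse relaxation time in ms. Must be positive and not
#'   exceed `t1`.
#' @param b1_scale Transmit-field scale; 1 means all nominal flip angles are
#'   achieved exactly. Must be non-negative.
#' @param rho Complex signal scale (proton density times receive
#'   sensitivity), arbitrary units.
#' @param delta_f Off-resonance in Hz, constant over the sequence.
#' @param population Bookkeeping label, one of `"water"`, `"fat"`, `"flow"`
#'   or `"saturated_band"`.
#' @return An object of class `spin_system`.
#' @examples
#' spin_system(t1 = 1400, t2 = 60)
#' @export
spin_system <- function(t1, t2, b1_scale = 1, rho = 1 + 0i, delta_f = 0,
                        population = c("water", "fat", "flow",
                                       "saturated_band")) {
  population <- match.arg(population)
  stopifnot(is.numeric(t1), length(t1) == 1, is.numeric(t2), length(t2) == 1)
  if (t1 <= 0) stop("t1 must be positive")
  if (t2 <= 0) stop("t2 must be positive")
  if (t2 > t1) stop("t2 must not exceed t1")
  if (b1_scale < 0) stop("b1_scale must be non-negative")
  structure(
    list(t1 = t1, t2 = t2, b1_scale = b1_scale, rho = as.complex(rho),
         delta_f = delta_f, population = population),
    class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf(
    "<spin_system> %s: T1 %.4g ms, T2 %.4g ms, B1 %.3g, |rho| %.3g, df %.4g Hz\n",
    x$population, x$t1, x$t2, x$b1_scale, Mod(x$rho), x$delta_f))
  invisible(x)
}
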