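#' RF rotation of an EPG state
#'
#' Applies the standard EPG rotation mixing to every configuration triplet
#' (F+(k), F-(-k), Z(k)). With `a = flip` and `p = phase` (radians),
#' \deqn{F'(k) = \cos^2(a/2) F(k) + e^{2ip}\sin^2(a/2)\,\overline{F(-k)}
#'   - i e^{ip}\sin a\, Z(k)}
#' \deqn{Z'(k) = -\tfrac{i}{2} e^{-ip}\sin a\, F(k)
#'   + \tfrac{i}{2} e^{ip}\sin a\, \overline{F(-k)} + \cos a\, Z(k)}
#' The total magnetisation norm ([epg_norm()]) is conserved. Transmit-scale
#' (B1) weighting of the nominal flip is applied by the caller.
#'
#' @param state An `epg_state`.
#' @param flip Flip angle in degrees (any real value).
#' @param phase RF phase in degrees.
#' @return The rotated `epg_state`.
#' @examples
#' st <- rf_rotation(equilibrium_state("slice", 4), 90)
#' Mod(acquire(st))  # full excitation
#' @export
rf_rotation <- function(state, flip, phase = 0) {
  a <- flip * pi / 180
  p <- phase * pi / 180
  c2 <- cos(a / 2)^2
  s2 <- sin(a / 2)^2
  sa <- sin(a)
  ca <- cos(a)
  eip <- exp(1i * p)
  Fc <- rev_all(Conj(state$F))                 # Fc(k) = conj(F(-k))
  Fn <- c2 * state$F + s2 * eip^2 * Fc - 1i * eip * sa * state$Z
  Zn <- -0.5i * Conj(eip) * sa * state$F + 0.5i * eip * sa * Fc +
    ca * state$Z
  state$F <- Fn
  state$Z <- Zn
  state
}

#' Gradient shift of an EPG state
#'
#' Shifts the transverse configuration orders on one tracked axis:
#' F+ orders increment by `steps` (and the implicit conjugate counterpart
#' F- decrements), longitudinal states are unaffected. One step corresponds
#' to the per-TR unbalanced slice spoiler (here the 8-pi intra-voxel phase
#' twist); all other gradient moments are expressed as integer multiples of
#' it. Amplitudes shifted beyond `max_order` are dropped and their squared
#' magnitude is accumulated in the `dropped` counter.
#'
#' @param state An `epg_state`.
#' @param axis Axis label; must be tracked by the state.
#' @param steps Integer number of configuration steps (may be negative).
#' @return The shifted `epg_state`.
#' @export
gradient_shift <- function(state, axis, steps) {
  ax <- match(axis, state$axes)
  if (is.na(ax)) stop("axis '", axis, "' is not tracked by this state")
  steps <- as.integer(steps)
  if (steps == 0L) return(state)
  d <- dim(state$F)
  n <- d[ax]
  src <- seq_len(n) - steps                    # new[k] = old[k - steps]
  keep <- src >= 1L & src <= n
  idx <- lapply(d, seq_len)
  lost <- idx
  dst <- seq_len(n) + steps
  lost[[ax]] <- which(dst < 1L | dst > n)
  if (length(lost[[ax]]))
    state$dropped <- state$dropped +
      sum(Mod(do.call(`[`, c(list(state$F), lost, list(drop = FALSE))))^2)
  Fn <- array(0 + 0i, dim = d)
  to <- idx; to[[ax]] <- which(keep)
  from <- idx; from[[ax]] <- src[keep]
  Fn <- do.call(`[<-`, c(list(Fn), to,
                         list(do.call(`[`, c(list(state$F), from,
                                             list(drop = FALSE))))))
  state$F <- Fn
  state
}

#' Relaxation, recovery and off-resonance precession
#'
#' Scales transverse orders by `exp(-dt/T2)` with an off-resonance phase
#' `exp(-2i pi delta_f dt)`, scales longitudinal orders by `exp(-dt/T1)`,
#' and regrows the zero-order longitudinal state toward equilibrium by
#' `1 - exp(-dt/T1)`.
#'
#' @param state An `epg_state`.
#' @param spin A [spin_system()].
#' @param dt Interval in ms; must be non-negative.
#' @param regrowth Logical; disable to propagate a pure difference state
#'   (used for pathway-contribution analyses, where the affine equilibrium
#'   term cancels).
#' @return The relaxed `epg_state`.
#' @export
relax <- function(state, spin, dt, regrowth = TRUE) {
  if (dt < 0) stop("dt must be non-negative")
  if (dt == 0) return(state)
  e1 <- exp(-dt / spin$t1)
  e2 <- exp(-dt / spin$t2)
  ph <- exp(-1i * 2 * pi * spin$delta_f * dt * 1e-3)
  state$F <- state$F * (e2 * ph)
  state$Z <- state$Z * e1
  if (regrowth) {
    zi <- zero_index(state)
    z0 <- do.call(`[`, c(list(state$Z), zi))
    state$Z <- do.call(`[<-`, c(list(state$Z), zi, list(z0 + (1 - e1))))
  }
  state
}

#' Apply a saturation module to an EPG state
#'
#' A saturation module is an RF pulse (nominally 90 degrees) placed between
#' a pair of balanced spoiling gradients on the read/phase axes, followed by
#' an unbalanced slice spoiler whose moment matches an integer number of
#' imaging TR cycles. For a spin inside the saturation band (or on the
#' saturated chemical frequency), the pulse is applied between the balancing
#' gradients, so freshly saturated magnetisation acquires a phase-axis
#' configuration it can never shed and is excluded from every later readout.
#' For all other spins the pulse is transparent: only the gradient moments
#' and the relaxation interval are applied, so the imaged magnetisation sees
#' the same net moment and timing as an imaging block of equal duration.
#'
#' @param state An `epg_state`.
#' @param flip Saturation flip angle in degrees.
#' @param duration Block duration in ms; must be positive.
#' @param spoil_steps_per_axis Named integer vector of unbalanced spoiler
#'   moments in configuration steps (must cover the slice spoiler).
#' @param balanced_axes Axes carrying the balanced gradient pair.
#' @param spin A [spin_system()].
#' @param affects_spin Logical; whether the spin lies in the saturation band
#'   or on the saturated chemical frequency (see [band_affects_spin()]).
#' @param balanced Logical; set `FALSE` to drop the post-pulse balancing
#'   shift and reproduce the unspoiled failure mode in which pathways from
#'   the saturation pulse leak back into the acquired signal.
#' @return The `epg_state` after the module.
#' @export
apply_saturation_module <- function(state, flip = 90, duration,
                                    spoil_steps_per_axis = c(slice = 1L),
                                    balanced_axes = "phase", spin,
                                    affects_spin, balanced = TRUE) {
  if (duration <= 0) stop("duration must be positive")
  if (!"slice" %in% names(spoil_steps_per_axis))
    stop("spoil_steps_per_axis must cover the unbalanced slice spoiler")
  state <- relax(state, spin, duration / 2)
  balanced_axes <- intersect(balanced_axes, state$axes)
  if (affects_spin) {
    for (ax in balanced_axes) state <- gradient_shift(state, ax, 1L)
    state <- rf_rotation(state, flip * spin$b1_scale, 0)
    if (balanced)
      for (ax in balanced_axes) state <- gradient_shift(state, ax, -1L)
  }
  for (ax in intersect(names(spoil_steps_per_axis), state$axes))
    state <- gradient_shift(state, ax, spoil_steps_per_axis[[ax]])
  relax(state, spin, duration / 2)
}
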