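# Primitive-event codes shared by the R and compiled runners
EV_RF <- 1; EV_GRAD <- 2; EV_RELAX <- 3; EV_ACQ <- 4; EV_CRUSH <- 5

#' Lower a sequence program to primitive engine events
#'
#' Compiles the declarative event table of a `sequence_program` into the
#' flat primitive list consumed by the propagation engines: RF rotations,
#' integer gradient shifts, relaxation intervals, readouts (with the
#' demodulation phase of the exciting pulse) and break crushers. The
#' lowering is spin-class specific: saturation pulses are included only for
#' spins the schedule affects, and gradient moments on axes that are not
#' tracked are dropped after verifying that they cancel over the program.
#'
#' @param program A `sequence_program`.
#' @param axes Tracked gradient axes.
#' @param affects_spatial Logical; the spin lies inside a spatial band (the
#'   covering band's pulse is applied).
#' @param affects_chemical Logical; the spin lies inside the chemical
#'   suppression window.
#' @param sat_balanced Logical; set `FALSE` to drop the post-saturation
#'   balancing/spoiling gradient (the failure mode without spoiling after
#'   the saturation pulse).
#' @param ideal_spoiling Logical; replace the literal quadratic FLASH RF
#'   spoiling by an ideal crusher before each FLASH excitation.
#' @return A numeric matrix with columns `kind, p1, p2, p3, p4` (see the
#'   engine documentation); RF rows flag saturation pulses in `p4`.
#' @keywords internal
compile_events <- function(program, axes = "slice",
                           affects_spatial = FALSE,
                           affects_chemical = FALSE,
                           sat_balanced = TRUE, ideal_spoiling = FALSE) {
  ev <- program$events
  mom_cols <- c(slice = "m_slice", phase = "m_phase", read = "m_read")
  untracked <- setdiff(names(mom_cols), axes)
  for (ax in untracked) {
    if (sum(ev[[mom_cols[ax]]]) != 0)
      stop("net moment on untracked axis '", ax, "' is nonzero")
  }
  if ((affects_spatial || affects_chemical) &&
      any(ev$kind %in% c("saturation_spatial", "saturation_chemical")) &&
      !"phase" %in% axes)
    stop("saturated spins require the phase axis to be tracked")

  out <- matrix(0, nrow = 4L * nrow(ev) + 8L, ncol = 5L)
  n <- 0L
  push <- function(kind, p1 = 0, p2 = 0, p3 = 0, p4 = 0) {
    n <<- n + 1L
    out[n, ] <<- c(kind, p1, p2, p3, p4)
  }
  tcur <- ev$time[1]
  skip_sat_grad <- FALSE
  for (i in seq_len(nrow(ev))) {
    if (ev$time[i] > tcur + 1e-9) {
      push(EV_RELAX, ev$time[i] - tcur)
      tcur <- ev$time[i]
    }
    kind <- ev$kind[i]
    if (kind == "inversion") {
      push(EV_RF, ev$flip[i], ev$rf_phase[i], 0)        # adiabatic: B1-proof
    } else if (kind == "excite") {
      if (ideal_spoiling && identical(ev$segment[i], "FLASH")) push(EV_CRUSH)
      push(EV_RF, ev$flip[i], ev$rf_phase[i], 1)
    } else if (kind == "readout") {
      push(EV_ACQ, ev$rf_phase[i])
    } else if (kind == "gradient") {
      post_sat <- !is.na(ev$m_phase[i]) && ev$m_phase[i] < 0
      if (!(skip_sat_grad && post_sat)) {
        for (ax in axes) {
          steps <- ev[[mom_cols[ax]]][i]
          if (steps != 0) push(EV_GRAD, steps, p4 = match(ax, axes))
        }
      }
      if (post_sat) skip_sat_grad <- FALSE
    } else if (kind == "saturation_spatial") {
      if (affects_spatial && identical(ev$band[i], 1L)) {
        push(EV_RF, ev$flip[i], ev$rf_phase[i], 1, p4 = 1)
        if (!sat_balanced) skip_sat_grad <- TRUE
      }
    } else if (kind == "saturation_chemical") {
      if (affects_chemical) {
        push(EV_RF, ev$flip[i], ev$rf_phase[i], 1, p4 = 1)
        if (!sat_balanced) skip_sat_grad <- TRUE
      }
    } else if (kind == "delay") {
      if (isTRUE(ev$crush[i])) push(EV_CRUSH)
    } else stop("unknown event kind: ", kind)
  }
  out[seq_len(n), , drop = FALSE]
}

# Reference R runner over the primitive event list (any number of axes).
run_epg_events <- function(events, spin, state, regrowth = TRUE) {
  signal <- complex(0)
  for (i in seq_len(nrow(events))) {
    kind <- events[i, 1]
    if (kind == EV_RF) {
      flip <- events[i, 2]
      if (events[i, 4] > 0.5) flip <- flip * spin$b1_scale
      state <- rf_rotation(state, flip, events[i, 3])
    } else if (kind == EV_GRAD) {
      state <- gradient_shift(state, state$axes[events[i, 5]], events[i, 2])
    } else if (kind == EV_RELAX) {
      state <- relax(state, spin, events[i, 2], regrowth = regrowth)
    } else if (kind == EV_ACQ) {
      signal <- c(signal, acquire(state, spin, events[i, 2]))
    } else if (kind == EV_CRUSH) {
      state$F[] <- 0 + 0i
    }
  }
  list(signal = signal, state = state)
}

#' Simulate a fingerprint signal evolution
#'
#' Propagates a spin system through a sequence program with the EPG engine
#' and returns one complex sample per readout event, demodulated at the
#' transmitter phase of the exciting pulse. Single-axis programs run through
#' the compiled engine; saturated spins (which need the phase axis) run
#' through the reference R engine.
#'
#' @param program A `sequence_program`.
#' @param spin A [spin_system()].
#' @param max_order EPG truncation order per tracked axis. A scalar given
#'   with multiple axes applies to the slice axis; further axes default to
#'   order 8 (phase-axis orders stay within a few steps here).
#' @param axes Tracked axes; defaults to `"slice"`, or `c("slice","phase")`
#'   when the spin is affected by a saturation mechanism.
#' @param engine `"auto"` (default), `"cpp"` or `"R"`.
#' @param affects_spatial,affects_chemical Whether the saturation pulses act
#'   on this spin (see [band_affects_spin()]).
#' @param sat_balanced,ideal_spoiling Passed to the lowering step; see
#'   `compile_events`.
#' @return Complex vector of length `program$n_readouts` with attribute
#'   `"dropped"`, the squared-magnitude truncation loss.
#' @examples
#' prog <- assemble_program(build_flip_angle_train(
#'   train_config(lengths = rep(10, 4))))
#' fp <- simulate_fingerprint(prog, spin_system(1400, 60))
#' length(fp)
#' @export
simulate_fingerprint <- function(program, spin, max_order = 64L,
                                 axes = NULL, engine = c("auto", "cpp", "R"),
                                 affects_spatial = FALSE,
                                 affects_chemical = FALSE,
                                 sat_balanced = TRUE,
                                 ideal_spoiling = FALSE) {
  engine <- match.arg(engine)
  if (is.null(axes))
    axes <- if (affects_spatial || affects_chemical)
      c("slice", "phase") else "slice"
  if (length(axes) > 1L && length(max_order) == 1L)
    max_order <- c(max_order, rep(8L, length(axes) - 1L))
  events <- compile_events(program, axes = axes,
                           affects_spatial = affects_spatial,
                           affects_chemical = affects_chemical,
                           sat_balanced = sat_balanced,
                           ideal_spoiling = ideal_spoiling)
  if (engine == "auto")
    engine <- if (identical(axes, "slice")) "cpp" else "R"
  if (engine == "cpp") {
    if (!identical(axes, "slice"))
      stop("the compiled engine tracks the slice axis only")
    res <- epg_run_cpp(events, spin$t1, spin$t2, spin$b1_scale, spin$rho,
                       spin$delta_f, as.integer(max_order[1]))
    sig <- res$signal
    if (length(sig) < program$n_readouts)
      sig <- c(sig, complex(program$n_readouts - length(sig)))
    attr(sig, "dropped") <- res$dropped
    return(sig)
  }
  state <- equilibrium_state(axes, max_order)
  res <- run_epg_events(events, spin, state)
  sig <- res$signal
  attr(sig, "dropped") <- res$state$dropped
  sig
}

#' Readout contribution of saturation-generated pathways
#'
#' Isolates, by linearity of the EPG evolution, the transverse magnetisation
#' created by the first saturation pulse (the longitudinal magnetisation it
#' tips into the transverse plane) and propagates that component alone
#' through the remainder of the sequence in a two-axis (slice, phase)
#' simulation. With the balanced phase-axis gradient pair around the pulse,
#' these pathways can reach configuration-state zero on the slice axis but
#' never on the phase axis, so their contribution to every acquired sample
#' is exactly zero; without the post-pulse spoiling the pathways leak into
#' the acquired signal.
#'
#' @param program A `sequence_program` containing saturation events.
#' @param spin A [spin_system()] (treated as lying inside the band or
#'   chemical window).
#' @param max_order Truncation orders for the slice and phase axes.
#' @param balanced Logical; `FALSE` removes the post-saturation balancing
#'   gradient.
#' @return Complex vector of the pathway contribution at each readout that
#'   follows the first saturation pulse.
#' @export
saturation_pathway_signal <- function(program, spin,
                                      max_order = c(32L, 16L),
                                      balanced = TRUE) {
  has_spatial <- any(program$events$kind == "saturation_spatial")
  has_chemical <- any(program$events$kind == "saturation_chemical")
  if (!has_spatial && !has_chemical)
    stop("program contains no saturation events")
  axes <- c("slice", "phase")
  events <- compile_events(program, axes = axes,
                           affects_spatial = has_spatial,
                           affects_chemical = !has_spatial && has_chemical,
                           sat_balanced = balanced)
  sat_rf <- which(events[, 1] == EV_RF & events[, 5] == 1)
  if (!length(sat_rf)) stop("no saturation pulse reached in the lowering")
  i <- sat_rf[1]
  state <- equilibrium_state(axes, max_order)
  if (i > 1)
    state <- run_epg_events(events[seq_len(i - 1), , drop = FALSE], spin,
                            state)$state
  probe <- state
  probe$F[] <- 0 + 0i                       # keep only longitudinal input
  probe <- rf_rotation(probe, events[i, 2] * spin$b1_scale, events[i, 3])
  probe$Z[] <- 0 + 0i                       # keep only the freshly tipped F
  if (i == nrow(events)) return(complex(0))
  run_epg_events(events[(i + 1):nrow(events), , drop = FALSE], spin, probe,
                 regrowth = FALSE)$signal
}
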