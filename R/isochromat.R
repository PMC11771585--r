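# 3x3 rotation about an axis in the transverse plane at azimuth `phase`,
# built from elementary rotations: Rz(phase) Rx(flip) Rz(-phase).
bloch_rf_matrix <- function(flip_deg, phase_deg) {
  a <- flip_deg * pi / 180
  p <- phase_deg * pi / 180
  rz <- function(t) matrix(c(cos(t), sin(t), 0,
                             -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  rx <- matrix(c(1, 0, 0,
                 0, cos(a), sin(a),
                 0, -sin(a), cos(a)), 3, 3)
  rz(p) %*% rx %*% rz(-p)
}

#' Isochromat-ensemble fingerprint (reference oracle)
#'
#' Simulates the same lowered event program as [simulate_fingerprint()]
#' with a uniform ensemble of intra-voxel isochromats propagated by
#' explicit 3x3 Bloch rotation matrices, entirely independently of the
#' configuration-state engine. One gradient configuration step twists the
#' ensemble by one full cycle across the voxel, so for sequences whose
#' gradient moments are integer numbers of steps the ensemble mean
#' transverse magnetisation equals the EPG zero-order signal (up to EPG
#' truncation), which makes this the cross-validation oracle for the
#' engine.
#'
#' @param program A `sequence_program` (single tracked axis).
#' @param spin A [spin_system()].
#' @param n_isochromats Ensemble size; at least four times the EPG
#'   truncation order being validated.
#' @param ideal_spoiling Passed to the lowering step.
#' @return Complex vector of one sample per readout.
#' @export
isochromat_fingerprint <- function(program, spin, n_isochromats = 256L,
                                   ideal_spoiling = FALSE) {
  events <- compile_events(program, axes = "slice",
                           ideal_spoiling = ideal_spoiling)
  N <- as.integer(n_isochromats)
  pos <- (seq_len(N) - 1) / N              # fraction of one twist cycle
  M <- rbind(0, 0, rep(1, N))              # rows Mx, My, Mz
  signal <- complex(0)
  zrot <- function(M, psi) {               # per-isochromat z rotation
    c_ <- cos(psi); s_ <- sin(psi)
    rbind(M[1, ] * c_ - M[2, ] * s_,
          M[1, ] * s_ + M[2, ] * c_,
          M[3, ])
  }
  for (i in seq_len(nrow(events))) {
    kind <- events[i, 1]
    if (kind == EV_RF) {
      flip <- events[i, 2]
      if (events[i, 4] > 0.5) flip <- flip * spin$b1_scale
      M <- bloch_rf_matrix(flip, events[i, 3]) %*% M
    } else if (kind == EV_GRAD) {
      M <- zrot(M, 2 * pi * pos * events[i, 2])
    } else if (kind == EV_RELAX) {
      dt <- events[i, 2]
      e1 <- exp(-dt / spin$t1)
      e2 <- exp(-dt / spin$t2)
      M <- zrot(M, -2 * pi * spin$delta_f * dt * 1e-3)
      M[1:2, ] <- M[1:2, ] * e2
      M[3, ] <- M[3, ] * e1 + (1 - e1)
    } else if (kind == EV_ACQ) {
      mplus <- mean(M[1, ] + 1i * M[2, ])
      signal <- c(signal,
                  spin$rho * mplus * exp(-1i * events[i, 2] * pi / 180))
    } else if (kind == EV_CRUSH) {
      M[1:2, ] <- 0
    }
  }
  signal
}
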