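#' Circular mask on the image grid
#'
#' Pixel-centre coordinates follow the reconstruction convention: column
#' `j` maps to `x = (j - 1 - n/2) * pixel_mm`, row `i` to
#' `y = (i - 1 - n/2) * pixel_mm`.
#'
#' @param n Matrix size.
#' @param fov_mm Field of view in mm.
#' @param center_mm Centre `c(x, y)` in mm.
#' @param radius_mm Radius in mm.
#' @return Logical `n x n` matrix.
#' @export
circular_mask <- function(n, fov_mm, center_mm, radius_mm) {
  px <- fov_mm / n
  x <- ((seq_len(n) - 1) - n / 2) * px
  xg <- matrix(x, n, n, byrow = TRUE)
  yg <- matrix(x, n, n)
  (xg - center_mm[1])^2 + (yg - center_mm[2])^2 <= radius_mm^2
}

new_phantom <- function(shape, fov_mm, regions, band_axis = "x") {
  structure(list(shape = shape, fov_mm = fov_mm,
                 pixel_mm = fov_mm / shape, regions = regions,
                 band_axis = band_axis),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat(sprintf("<digital_phantom> %dx%d px, %.3g mm FOV, %d regions (%s)\n",
              x$shape, x$shape, x$fov_mm, length(x$regions),
              paste(vapply(x$regions, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}

phantom_region <- function(name, mask, spin, position, flow = NULL) {
  list(name = name, mask = mask, spin = spin, position = position,
       flow = flow)
}

#' Flow-phantom configuration and construction
#'
#' A cylindrical agar body with two adjacent tubes of pulsatile flowing
#' water: the tubes carry a bright signal whose amplitude pulsates at the
#' pump frequency and whose phase fluctuates from readout to readout, the
#' mechanism behind radial streak artefacts. With zero `phase_instability`
#' and `amplitude_pulsation` the tubes reduce to static bright regions.
#'
#' @param matrix Image matrix size.
#' @param fov_mm Field of view in mm (protocol: 240).
#' @param body_t1,body_t2 Agar relaxation times in ms.
#' @param tube_offset_mm Tube-centre x offset from isocentre.
#' @param tube_sep_mm Vertical separation between the two tubes.
#' @param tube_radius_mm Tube radius.
#' @param flow_rho Complex proton-density scale of the flowing water (the
#'   vessel brightness itself arises from inflow refreshment, see
#'   [phantom_fingerprints()]).
#' @param pulsation_hz Pump frequency (protocol: 1 Hz).
#' @param amplitude_pulsation Fractional amplitude modulation depth.
#' @param phase_pulsation Velocity-induced phase swing in radians, tracking
#'   the pump waveform (flow phase follows the instantaneous velocity).
#' @param phase_instability Additional per-readout random phase RMS in
#'   radians (beat-to-beat irregularity).
#' @return A `digital_phantom` with three regions (body plus two tubes).
#' @export
make_flow_phantom <- function(matrix = 64L, fov_mm = 240,
                              body_t1 = 1400, body_t2 = 60,
                              tube_offset_mm = 78, tube_sep_mm = 56,
                              tube_radius_mm = 10,
                              flow_rho = 1 + 0i, pulsation_hz = 1,
                              amplitude_pulsation = 0.3,
                              phase_pulsation = 1.5,
                              phase_instability = 0.6) {
  n <- as.integer(matrix)
  half <- fov_mm / 2
  if (abs(tube_offset_mm) + tube_radius_mm > half)
    stop("tubes lie outside the field of view")
  body <- circular_mask(n, fov_mm, c(-12, 0), 72)
  t1 <- circular_mask(n, fov_mm, c(tube_offset_mm, tube_sep_mm / 2),
                      tube_radius_mm)
  t2 <- circular_mask(n, fov_mm, c(tube_offset_mm, -tube_sep_mm / 2),
                      tube_radius_mm)
  body <- body & !t1 & !t2
  flow <- list(pulsation_hz = pulsation_hz,
               amplitude_pulsation = amplitude_pulsation,
               phase_pulsation = phase_pulsation,
               phase_instability = phase_instability)
  water <- function() spin_system(3000, 250, rho = flow_rho,
                                  population = "flow")
  regions <- list(
    phantom_region("body", body, spin_system(body_t1, body_t2), -12),
    phantom_region("tube_upper", t1, water(), tube_offset_mm, flow),
    phantom_region("tube_lower", t2, water(), tube_offset_mm, flow))
  new_phantom(n, fov_mm, regions)
}

#' Multicompartment phantom
#'
#' Ten cylinders spanning a wide range of T1 and T2 (two compartments above
#' 200 ms T2 to probe the long-T2 accuracy regime), two oil containers
#' represented as fat spins at the chemical-shift offset, and a saline
#' background.
#'
#' @param matrix Image matrix size.
#' @param fov_mm Field of view in mm.
#' @param fat_offset_hz Fat chemical-shift frequency at 3 T.
#' @return A `digital_phantom` with 13 regions (background + 10 + 2).
#' @export
make_multicompartment_phantom <- function(matrix = 64L, fov_mm = 240,
                                          fat_offset_hz = -440) {
  n <- as.integer(matrix)
  t1s <- c(320, 420, 560, 740, 960, 1250, 1600, 2000, 2400, 2800)
  t2s <- c(25, 34, 46, 62, 84, 113, 152, 190, 230, 310)
  ang <- 2 * pi * (seq_len(10) - 1) / 10
  ring <- 62
  bg <- circular_mask(n, fov_mm, c(0, 0), 100)
  regions <- list(NULL)
  occupied <- matrix(FALSE, n, n)
  for (i in seq_len(10)) {
    ctr <- c(ring * cos(ang[i]), ring * sin(ang[i]))
    m <- circular_mask(n, fov_mm, ctr, 12.6)
    if (any(m & occupied)) stop("compartment disks overlap")
    occupied <- occupied | m
    regions[[i + 1]] <- phantom_region(
      sprintf("mncl2_%02d", i), m, spin_system(t1s[i], t2s[i]), ctr[1])
  }
  fat_ctrs <- list(c(0, 0), c(0, 88))
  for (k in 1:2) {
    m <- circular_mask(n, fov_mm, fat_ctrs[[k]], 6.9)
    if (any(m & occupied)) stop("compartment disks overlap")
    occupied <- occupied | m
    regions[[11 + k]] <- phantom_region(
      sprintf("oil_%d", k), m,
      spin_system(300, 70, delta_f = fat_offset_hz, population = "fat"),
      fat_ctrs[[k]][1])
  }
  regions[[1]] <- phantom_region("background", bg & !occupied,
                                 spin_system(2900, 1800), 0)
  new_phantom(n, fov_mm, regions)
}

#' Per-region fingerprints of a phantom
#'
#' Simulates the signal evolution of every region. Static regions the
#' saturation schedule affects (spatial band membership via the region's
#' band-normal position, chemical via its off-resonance) run through the
#' two-axis engine so saturated pathways are excluded exactly. Flow regions
#' are modelled as fully inflow-refreshed: the through-plane flow replaces
#' the slice content every TR, so each excitation sees fresh longitudinal
#' magnetisation and the vessel is far brighter than the driven transient
#' of static tissue, `s_n = -i rho sin(flip_n) exp(-TE/T2) m_z(n)`. With a
#' spatial band over the vessel the inflowing spins were saturated at the
#' last saturation block, so `m_z` is only the T1 regrowth since that
#' block; without a band `m_z = 1`.
#'
#' @param phantom A `digital_phantom`.
#' @param program A `sequence_program` (its schedule decides saturation).
#' @param max_order Slice-axis EPG truncation order.
#' @return Complex matrix, regions x readouts.
#' @export
phantom_fingerprints <- function(phantom, program, max_order = 64L) {
  sig <- matrix(0 + 0i, length(phantom$regions), program$n_readouts)
  ev <- program$events
  ro <- ev[ev$kind == "readout", ]
  ex <- ev[ev$kind == "excite", ]
  sat_times <- ev$time[ev$kind %in% c("saturation_spatial",
                                      "saturation_chemical")]
  for (r in seq_along(phantom$regions)) {
    reg <- phantom$regions[[r]]
    hits <- saturation_hits(program$schedule, reg$spin, reg$position)
    if (is.null(reg$flow)) {
      sig[r, ] <- simulate_fingerprint(program, reg$spin,
                                       max_order = max_order,
                                       affects_spatial = hits[["spatial"]],
                                       affects_chemical = hits[["chemical"]])
    } else {
      sp <- reg$spin
      flips <- ex$flip * sp$b1_scale * pi / 180
      mz <- rep(1, nrow(ex))
      if (any(hits) && length(sat_times)) {
        last_sat <- vapply(ex$time, function(t) {
          prev <- sat_times[sat_times < t]
          if (length(prev)) max(prev) else -Inf
        }, numeric(1))
        mz <- ifelse(is.finite(last_sat),
                     1 - exp(-(ex$time - last_sat) / sp$t1), 1)
      }
      sig[r, ] <- -1i * sp$rho * sin(flips) * mz * exp(-program$te / sp$t2)
    }
  }
  rownames(sig) <- vapply(phantom$regions, `[[`, "", "name")
  sig
}

#' Simulate a golden-angle radial acquisition
#'
#' Synthesises one k-space spoke per readout event by exact non-uniform
#' DFT of the piecewise-constant phantom: each region contributes its
#' instantaneous fingerprint sample (flow regions modulated by their
#' pulsation envelope and seeded per-readout random phase) times the static
#' spatial spectrum of its mask along the spoke.
#'
#' @param phantom A `digital_phantom`.
#' @param program A `sequence_program`; readout angles and times are taken
#'   from its events.
#' @param seed Integer seed for the flow phase track and measurement noise.
#' @param noise_sd Complex Gaussian noise SD per sample and channel (0 for
#'   a noiseless acquisition).
#' @param n_samples Samples per spoke (default: matrix size, Nyquist).
#' @param max_order EPG truncation order for the region fingerprints.
#' @return A `radial_kspace` object: `spokes` (readouts x samples), spoke
#'   `angles` and `times`, sample positions `tvals` (rad/pixel), matrix and
#'   field-of-view metadata.
#' @export
simulate_radial_acquisition <- function(phantom, program, seed = 1L,
                                        noise_sd = 0, n_samples = NULL,
                                        max_order = 64L) {
  if (program$n_readouts < 1) stop("program has no readouts")
  n <- phantom$shape
  if (is.null(n_samples)) n_samples <- n
  ev <- program$events
  ro <- ev[ev$kind == "readout", ]
  angles <- ro$readout_angle
  times <- ro$time
  tvals <- ((seq_len(n_samples) - 1) - n_samples / 2) * 2 * pi / n_samples
  fps <- phantom_fingerprints(phantom, program, max_order = max_order)
  set.seed(as.integer(seed))
  spokes <- matrix(0 + 0i, length(angles), n_samples)
  for (r in seq_along(phantom$regions)) {
    reg <- phantom$regions[[r]]
    if (!any(reg$mask)) next
    idx <- which(reg$mask, arr.ind = TRUE)
    xy <- cbind((idx[, 2] - 1) - n / 2, (idx[, 1] - 1) - n / 2)
    G <- spoke_dft_cpp(xy, rep(1 + 0i, nrow(xy)), angles, tvals)
    s <- fps[r, ]
    if (!is.null(reg$flow)) {
      fl <- reg$flow
      cyc <- 2 * pi * fl$pulsation_hz * times * 1e-3
      env <- 1 + fl$amplitude_pulsation * sin(cyc)
      pp <- if (is.null(fl$phase_pulsation)) 0 else fl$phase_pulsation
      ph <- exp(1i * (pp * sin(cyc) +
                      stats::rnorm(length(s), 0, fl$phase_instability)))
      s <- s * env * ph
    }
    spokes <- spokes + s * G
  }
  if (noise_sd > 0)
    spokes <- spokes +
      noise_sd * (matrix(stats::rnorm(length(spokes)), nrow(spokes)) +
                  1i * matrix(stats::rnorm(length(spokes)), nrow(spokes)))
  structure(list(spokes = spokes, angles = angles, times = times,
                 readout_index = seq_along(angles), tvals = tvals,
                 matrix = n, fov_mm = phantom$fov_mm,
                 pixel_mm = phantom$pixel_mm, seed = as.integer(seed)),
            class = "radial_kspace")
}
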