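#' Flip-angle train configuration
#'
#' The acquisition plays a long train of RF excitations split into segments
#' of FISP (gradient-spoiled, coherence-retaining) and FLASH (additionally
#' RF-spoiled) character. The published train is only available graphically,
#' so the default generator draws one smooth sinusoidal half-lobe per
#' segment between the protocol's flip-angle bounds; a fully custom train
#' can be supplied through `custom`.
#'
#' @param lengths Integer vector of segment lengths (default four segments
#'   of 250 excitations).
#' @param segments Character vector of segment types, `"FISP"` or `"FLASH"`.
#' @param peaks Peak nominal flip per segment in degrees.
#' @param min_flip,max_flip Nominal flip-angle bounds in degrees (the
#'   protocol range is 3.2 to 60).
#' @param flash_phase_increment Quadratic RF-spoiling phase increment for
#'   FLASH segments, degrees.
#' @param custom Optional numeric vector overriding the generated flips
#'   (segment labels are still taken from `lengths`/`segments`).
#' @return A list of class `train_config`.
#' @export
train_config <- function(lengths = rep(250L, 4),
                         segments = c("FISP", "FLASH", "FISP", "FLASH"),
                         peaks = c(60, 36, 48, 24),
                         min_flip = 3.2, max_flip = 60,
                         flash_phase_increment = 50,
                         custom = NULL) {
  stopifnot(length(lengths) == length(segments))
  segments <- match.arg(segments, c("FISP", "FLASH"), several.ok = TRUE)
  peaks <- rep(peaks, length.out = length(lengths))
  structure(list(lengths = as.integer(lengths), segments = segments,
                 peaks = peaks, min_flip = min_flip, max_flip = max_flip,
                 flash_phase_increment = flash_phase_increment,
                 custom = custom),
            class = "train_config")
}

#' Build the nominal flip-angle train
#'
#' Generates one nominal flip angle per excitation, clipped to the
#' configured bounds, with the FISP/FLASH segment label attached to each
#' entry as the `"segment"` attribute.
#'
#' @param config A [train_config()].
#' @return Numeric vector of nominal flips in degrees with attribute
#'   `segment` (character, per entry).
#' @examples
#' train <- build_flip_angle_train(train_config())
#' range(train)
#' @export
build_flip_angle_train <- function(config = train_config()) {
  n <- sum(config$lengths)
  if (!is.null(config$custom)) {
    flips <- as.numeric(config$custom)
    if (length(flips) != n)
      stop("custom train length must equal the summed segment lengths")
    if (any(flips < config$min_flip - 1e-9) ||
        any(flips > config$max_flip + 1e-9))
      stop("custom flips lie outside [", config$min_flip, ", ",
           config$max_flip, "] degrees")
  } else {
    flips <- unlist(lapply(seq_along(config$lengths), function(j) {
      m <- config$lengths[j]
      lobe <- sin(pi * seq_len(m) / (m + 1))
      config$min_flip + (config$peaks[j] - config$min_flip) * lobe
    }))
    flips <- pmin(pmax(flips, config$min_flip), config$max_flip)
  }
  attr(flips, "segment") <- rep(config$segments, config$lengths)
  attr(flips, "flash_phase_increment") <- config$flash_phase_increment
  flips
}

#' Saturation schedule
#'
#' Describes how saturation modules are interleaved with the imaging train:
#' a block of `block_tr` TR-equivalents is inserted after every `period_tr`
#' imaging TRs. A block may carry two spatial (slab-selective) saturation
#' pulses, one chemical (frequency-selective) pulse, or both. Block gradient
#' moments always match `block_tr` imaging TR cycles per axis: balanced
#' read/phase pairs around the pulse plus an unbalanced slice spoiler.
#'
#' @param period_tr Imaging TRs between saturation blocks (must exceed
#'   `block_tr`).
#' @param block_tr Block duration in TR units, 2 (spatial only) or 4
#'   (whenever chemical saturation is played).
#' @param spatial Logical; play the pair of spatial saturation bands.
#' @param chemical Logical; play the frequency-selective (fat) pulse.
#' @param band_thickness Saturation-band thickness in mm (at most 150).
#' @param band_positions List of bands, each `c(center = , thickness = )` in
#'   mm along the band normal. Defaults to two 50-mm bands at +/-95 mm.
#' @param chemical_offset Centre frequency of the chemical pulse in Hz
#'   (3 T fat default, -440 Hz).
#' @param chemical_bandwidth Width of the suppressed frequency window in Hz.
#' @return A list of class `saturation_schedule`.
#' @export
saturation_schedule <- function(period_tr, block_tr, spatial = TRUE,
                                chemical = FALSE, band_thickness = 50,
                                band_positions = NULL,
                                chemical_offset = -440,
                                chemical_bandwidth = 300) {
  if (!block_tr %in% c(2L, 4L)) stop("block_tr must be 2 or 4")
  if (period_tr <= block_tr) stop("period_tr must exceed block_tr")
  if (band_thickness > 150) stop("band_thickness must not exceed 150 mm")
  if (is.null(band_positions))
    band_positions <- list(c(center = -95, thickness = band_thickness),
                           c(center = 95, thickness = band_thickness))
  structure(list(period_tr = as.integer(period_tr),
                 block_tr = as.integer(block_tr),
                 spatial = isTRUE(spatial), chemical = isTRUE(chemical),
                 band_thickness = band_thickness,
                 band_positions = band_positions,
                 chemical_offset = chemical_offset,
                 chemical_bandwidth = chemical_bandwidth),
            class = "saturation_schedule")
}

#' Saturation schedules of the protocol variants
#'
#' Returns the saturation schedule for a named sequence variant: `"MRF"`
#' (none), `"SpaSatMRF_25"` (2-TR spatial blocks every 25th TR),
#' `"SpaSatMRF_10"` (2-TR spatial blocks every 10th TR), `"FatSatMRF_10"`
#' (4-TR chemical blocks every 10th TR) and `"AllSatMRF_10"` (4-TR blocks
#' with both, every 10th TR).
#'
#' @param name Variant name.
#' @param ... Passed on to [saturation_schedule()] (band geometry etc.).
#' @return A `saturation_schedule`, or `NULL` for `"MRF"`.
#' @export
mrf_schedule <- function(name = c("MRF", "SpaSatMRF_25", "SpaSatMRF_10",
                                  "FatSatMRF_10", "AllSatMRF_10"), ...) {
  name <- match.arg(name)
  switch(name,
         MRF = NULL,
         SpaSatMRF_25 = saturation_schedule(25, 2, TRUE, FALSE, ...),
         SpaSatMRF_10 = saturation_schedule(10, 2, TRUE, FALSE, ...),
         FatSatMRF_10 = saturation_schedule(10, 4, FALSE, TRUE, ...),
         AllSatMRF_10 = saturation_schedule(10, 4, TRUE, TRUE, ...))
}

#' Golden-angle radial readout angle
#'
#' Readout angle for readout index `s` of shot `l` with `n_shots`
#' interleaved shots: the golden-angle increment advances with the global
#' spoke counter `s * n_shots + l`, and alternate readouts receive an extra
#' half-turn, \eqn{\alpha = (\theta (s n_l + l) + \pi \delta_{0, s \bmod 2})
#' \bmod 2\pi} with the golden angle \eqn{\theta = 111.25^\circ}.
#'
#' @param s Readout index (0-based), non-negative.
#' @param l Shot index, `0 <= l < n_shots`.
#' @param n_shots Number of shots.
#' @param golden_angle Increment in degrees.
#' @return Angle(s) in radians wrapped to `[0, 2 pi)`.
#' @export
radial_angle <- function(s, l, n_shots, golden_angle = 111.25) {
  stopifnot(all(s >= 0), all(l >= 0), all(l < n_shots))
  th <- golden_angle * pi / 180
  (th * (s * n_shots + l) + pi * (s %% 2 == 0)) %% (2 * pi)
}

#' Does a saturation schedule affect a spin?
#'
#' A spin is affected when its position lies inside one of the spatial
#' saturation bands (if spatial saturation is on) or its off-resonance lies
#' inside the chemical suppression window (if chemical saturation is on).
#'
#' @param schedule A [saturation_schedule()] or `NULL`.
#' @param spin A [spin_system()].
#' @param position Position along the band normal in mm (ignored unless
#'   spatial saturation is enabled).
#' @return Logical scalar. `saturation_hits()` returns the per-mechanism
#'   breakdown `c(spatial = , chemical = )`.
#' @export
band_affects_spin <- function(schedule, spin, position = NULL) {
  any(saturation_hits(schedule, spin, position))
}

#' @rdname band_affects_spin
#' @export
saturation_hits <- function(schedule, spin, position = NULL) {
  if (is.null(schedule)) return(c(spatial = FALSE, chemical = FALSE))
  spatial <- FALSE
  if (schedule$spatial && !is.null(position))
    spatial <- any(vapply(schedule$band_positions, function(b) {
      abs(position - b[["center"]]) <= b[["thickness"]] / 2
    }, logical(1)))
  chemical <- schedule$chemical &&
    abs(spin$delta_f - schedule$chemical_offset) <=
      schedule$chemical_bandwidth / 2
  c(spatial = spatial, chemical = chemical)
}

new_event <- function(kind, time, flip = NA_real_, rf_phase = NA_real_,
                      duration = 0, m_slice = 0L, m_phase = 0L, m_read = 0L,
                      readout_angle = NA_real_, segment = NA_character_,
                      crush = FALSE, band = NA_integer_) {
  list(kind = kind, time = time, flip = flip, rf_phase = rf_phase,
       duration = duration, m_slice = m_slice, m_phase = m_phase,
       m_read = m_read, readout_angle = readout_angle,
       segment = segment, crush = crush, band = band)
}

#' Low-level sequence-program constructor
#'
#' Wraps an ordered event table into a `sequence_program`. Most users should
#' call [assemble_program()]; this constructor exists for hand-built toy
#' sequences (single-echo, inversion-recovery ladders and the like).
#'
#' @param events Data frame of events as produced by `new_event` rows
#'   (columns `kind`, `time`, `flip`, `rf_phase`, `duration`, `m_slice`,
#'   `m_phase`, `m_read`, `readout_angle`, `segment`, `crush`).
#' @param tr,te Repetition and echo time in ms.
#' @param name Text label.
#' @param schedule Optional [saturation_schedule()] carried for band tests.
#' @param validate Check the program invariants (event times non-decreasing,
#'   `te < tr`, every readout preceded by an excitation in the same TR).
#' @return A `sequence_program`.
#' @export
sequence_program <- function(events, tr, te, name = "custom",
                             schedule = NULL, validate = TRUE) {
  n_readouts <- sum(events$kind == "readout")
  prog <- structure(list(events = events, tr = tr, te = te,
                         n_readouts = n_readouts, name = name,
                         schedule = schedule),
                    class = "sequence_program")
  if (validate) {
    if (te >= tr) stop("te must be smaller than tr")
    if (is.unsorted(events$time)) stop("event times must be non-decreasing")
    ro <- which(events$kind == "readout")
    ex <- which(events$kind == "excite")
    for (i in ro) {
      prev <- ex[ex < i]
      if (!length(prev) ||
          events$time[i] - events$time[max(prev)] > tr + 1e-9)
        stop("every readout must be preceded by an excitation in its TR")
    }
  }
  prog
}

#' @export
print.sequence_program <- function(x, ...) {
  cat(sprintf("<sequence_program> %s: %d events, %d readouts, TR/TE %.3g/%.3g ms\n",
              x$name, nrow(x$events), x$n_readouts, x$tr, x$te))
  invisible(x)
}

#' Assemble a fingerprinting sequence program
#'
#' Builds the timed event program: an adiabatic inversion, then the
#' flip-angle train with one excitation, readout and unbalanced slice
#' spoiler (one configuration step) per TR. FLASH segments additionally
#' carry a quadratic RF-spoiling phase schedule, restarted per segment, and
#' the acquired samples are demodulated at the transmitter phase. After
#' every `period_tr` imaging TRs a saturation block of `block_tr`
#' TR-equivalents is inserted (two spatial band pulses and/or one chemical
#' pulse between balanced phase-axis gradients, plus a slice spoiler of
#' `block_tr` steps). Between segments a `break_tr`-TR relaxation delay is
#' inserted, entered through a crusher so no transverse coherence crosses a
#' break.
#'
#' @param train Flip-angle train from [build_flip_angle_train()].
#' @param schedule A [saturation_schedule()] or `NULL` for the plain
#'   sequence.
#' @param tr,te Repetition and echo time in ms (protocol: 7.5/3.5).
#' @param break_tr Inter-segment break length in TR units.
#' @param shot,n_shots Shot index and shot count for the radial-angle
#'   ordering.
#' @param inv_delay Delay between the inversion pulse and the first
#'   excitation, ms.
#' @param sat_block_stretch Diagnostic factor multiplying the saturation
#'   block duration only (gradient moments are not rescaled); values other
#'   than 1 deliberately break the moment-per-duration matching.
#' @param name Program label.
#' @return A `sequence_program`.
#' @examples
#' prog <- assemble_program(build_flip_angle_train(
#'   train_config(lengths = rep(25, 4))), mrf_schedule("SpaSatMRF_25"))
#' prog$n_readouts
#' @export
assemble_program <- function(train, schedule = NULL, tr = 7.5, te = 3.5,
                             break_tr = 50L, shot = 0L, n_shots = 1L,
                             inv_delay = tr, sat_block_stretch = 1,
                             name = NULL) {
  if (te >= tr) stop("te must be smaller than tr")
  if (!is.null(schedule) && schedule$period_tr <= schedule$block_tr)
    stop("saturation period must exceed the block duration")
  segs <- attr(train, "segment")
  if (is.null(segs)) segs <- rep("FISP", length(train))
  dphi <- attr(train, "flash_phase_increment")
  if (is.null(dphi)) dphi <- 50
  n <- length(train)
  seg_end <- cumsum(rle(segs)$lengths)
  period <- if (is.null(schedule)) n else schedule$period_tr
  cap <- 4L * n + 8L * (n %/% max(1L, period)) + 32L
  col <- list(kind = character(cap), time = numeric(cap),
              flip = rep(NA_real_, cap), rf_phase = rep(NA_real_, cap),
              duration = numeric(cap), m_slice = integer(cap),
              m_phase = integer(cap), m_read = integer(cap),
              readout_angle = rep(NA_real_, cap),
              segment = rep(NA_character_, cap), crush = logical(cap),
              band = rep(NA_integer_, cap))
  nr <- 0L
  add <- function(ev) {
    nr <<- nr + 1L
    for (nm in names(col)) col[[nm]][nr] <<- ev[[nm]]
  }

  add(new_event("inversion", 0, flip = 180, rf_phase = 0))
  t <- inv_delay
  flash_j <- 0L
  prev_seg <- segs[1]
  for (i in seq_len(n)) {
    if (segs[i] != prev_seg) flash_j <- 0L
    prev_seg <- segs[i]
    if (segs[i] == "FLASH") {
      phase <- (dphi * flash_j * (flash_j + 1) / 2) %% 360
      flash_j <- flash_j + 1L
    } else phase <- 0
    add(new_event("excite", t, flip = train[i], rf_phase = phase,
                  segment = segs[i]))
    add(new_event("readout", t + te, rf_phase = phase,
                  readout_angle = radial_angle(i - 1L, shot, n_shots),
                  segment = segs[i]))
    add(new_event("gradient", t + tr, m_slice = 1L))
    t <- t + tr
    if (!is.null(schedule) && i %% schedule$period_tr == 0L) {
      d <- schedule$block_tr * tr * sat_block_stretch
      add(new_event("delay", t, duration = d / 2))
      add(new_event("gradient", t + d / 2, m_phase = 1L))
      if (schedule$spatial) {
        add(new_event("saturation_spatial", t + d / 2, flip = 90,
                      rf_phase = 0, band = 1L))
        add(new_event("saturation_spatial", t + d / 2, flip = 90,
                      rf_phase = 0, band = 2L))
      }
      if (schedule$chemical)
        add(new_event("saturation_chemical", t + d / 2, flip = 90,
                      rf_phase = 0))
      add(new_event("gradient", t + d / 2, m_phase = -1L,
                    m_slice = schedule$block_tr))
      add(new_event("delay", t + d / 2, duration = d / 2))
      t <- t + d
    }
    if (i %in% seg_end && i < n) {
      add(new_event("delay", t, duration = break_tr * tr, crush = TRUE))
      t <- t + break_tr * tr
    }
  }
  events <- as.data.frame(lapply(col, `[`, seq_len(nr)),
                          stringsAsFactors = FALSE)
  if (is.null(name))
    name <- if (is.null(schedule)) "MRF" else
      sprintf("SatMRF_%d_%d", schedule$period_tr, schedule$block_tr)
  sequence_program(events, tr, te, name = name, schedule = schedule)
}

#' Build a named protocol variant
#'
#' Convenience wrapper combining [build_flip_angle_train()],
#' [mrf_schedule()] and [assemble_program()].
#'
#' @param name Variant name (see [mrf_schedule()]).
#' @param config A [train_config()].
#' @param ... Passed to [assemble_program()].
#' @return A `sequence_program`.
#' @export
build_sequence <- function(name = "MRF", config = train_config(), ...) {
  sched <- mrf_schedule(name)
  assemble_program(build_flip_angle_train(config), sched, name = name, ...)
}

#' Sequence duration in TR units
#'
#' Total duration of the imaging train (first excitation to the end of the
#' last event) divided by TR. The inversion preparation is excluded so the
#' plain sequence with three 50-TR breaks measures `n_readouts + 150` TR.
#'
#' @param program A `sequence_program`.
#' @return Duration in TR units (0 for an empty program).
#' @export
sequence_duration_tr <- function(program) {
  ev <- program$events
  if (!nrow(ev)) return(0)
  ex <- ev$time[ev$kind == "excite"]
  if (!length(ex)) return(0)
  (max(ev$time + ifelse(is.na(ev$duration), 0, ev$duration)) - min(ex)) /
    program$tr
}

#' Tabular event listing
#'
#' @param program A `sequence_program`.
#' @return A tibble of the program's events.
#' @export
program_event_table <- function(program) tibble::as_tibble(program$events)

#' Write the event listing to CSV
#'
#' @param program A `sequence_program`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_program_csv <- function(program, path) {
  utils::write.csv(program$events, path, row.names = FALSE)
  invisible(path)
}
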