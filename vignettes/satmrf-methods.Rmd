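---
title: "Saturation-enabled MR fingerprinting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saturation-enabled MR fingerprinting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satmrf)
```

# The problem

MR fingerprinting (MRF) acquires a long transient signal evolution — a
*fingerprint* — by varying the flip angle over ~1000 excitations, and maps
tissue parameters (T1, T2, the transmit-field scale B1, and a nuisance
amplitude rho) by matching each voxel's evolution against a simulated
dictionary. In abdominal applications with golden-angle radial sampling,
pulsatile blood in large vessels produces bright signals with an unstable
phase, which radiate streak artefacts across the maps. A classical remedy in
qualitative imaging is the *saturation module*: a 90-degree RF pulse plus
spoiling gradients that nulls magnetisation in a spatial slab or in a
chemical-shift band (fat). This package models what happens when such
modules are interleaved with an MRF flip-angle train: how the saturated
magnetisation must be kept out of the acquired signal, what the interruption
costs in T1/T2 encoding power, and how much streak and fat artefact
suppression the modules buy on synthetic digital phantoms.

# The extended-phase-graph engine

The engine propagates magnetisation as configuration states: a transverse
spectrum `F(k)` (complex amplitude of the intra-voxel phase winding of order
`k`) and a longitudinal spectrum `Z(k)`, per tracked gradient axis. One
configuration step is defined as the per-TR unbalanced slice spoiler (the
8-pi intra-voxel twist); all gradient moments are expressed as integer
multiples of it, so every moment in the sequence is an exact integer shift
of the configuration index. RF pulses mix `(F(k), conj(F(-k)), Z(k))` with
the standard rotation coefficients; relaxation applies `exp(-dt/T2)` with an
off-resonance phase to `F`, `exp(-dt/T1)` to `Z`, and regrows `Z(0)`.
Signal is read from `F(0)` only, demodulated at the transmitter phase of
the exciting pulse (the complex convention is `F = Mx + i My`).

Two propagation routes exist deliberately. A compiled single-axis engine
(C++) runs the dictionary-scale work; a reference R engine supports any
number of axes and is used for saturated spins, where the phase axis must be
tracked. An independent check is provided by an isochromat simulator that
propagates an ensemble of `N` uniformly spaced intra-voxel spins with
explicit 3x3 Bloch rotation matrices: for integer-step gradient moments the
ensemble mean equals the EPG zero-order signal, and the test suite holds the
two routes to a relative `1e-6` over all five protocol variants.

**Truncation.** The default truncation order is 64 per axis, with a counter
accumulating the squared magnitude pushed past the boundary. Within the
tissue range that the protocol targets (T2 up to roughly 100 ms) doubling
the order changes no sample by more than `1e-9`. At the long end of the T2
ladder (507 ms) pathways decay so slowly that the truncation error at order
64 grows to ~1e-3 of the peak signal; the exact spread is bounded by the
segment length (a break crusher zeroes transverse states every 250 TRs), so
order ~350 would be exact. We keep 64 as the default — the error is far
below the matching discrimination at these grid steps — and expose both the
order and the dropped-energy diagnostic.

**RF spoiling.** FLASH segments carry the literal quadratic phase schedule
(50-degree increment, restarted per segment) in the rotations, with readout
demodulation at the transmitter phase; an ideal-spoiling toggle (crush
transverse states each FLASH TR) exists for speed and for isolating
coherence effects. FISP segments use a constant RF phase. The adiabatic
inversion is modelled as an exact 180-degree rotation independent of B1,
reflecting the B1-insensitivity of adiabatic pulses.

# Sequence model

The protocol plays 1000 excitations in four segments (FISP, FLASH, FISP,
FLASH) at TR/TE = 7.5/3.5 ms with nominal flips in [3.2, 60] degrees,
separated by 50-TR breaks, after a single adiabatic inversion. The published
flip-angle train exists only as a figure, so the default generator draws one
sinusoidal half-lobe per segment (peaks 60, 36, 48, 24 degrees) between the
published bounds; any custom train can be injected, so users who possess the
true train can reproduce it exactly. Breaks are modelled as pure relaxation
delays entered through a crusher — their stated purpose is additional T1
recovery and T2 decay, and carrying coherence across a 375 ms gap would make
the simulation hostage to sub-hertz off-resonance detail.

Saturation blocks of 2 TR (spatial) or 4 TR (any chemical) interrupt the
train after every 25th or 10th imaging TR, per the five named variants
(`MRF`, `SpaSatMRF_25`, `SpaSatMRF_10`, `FatSatMRF_10`, `AllSatMRF_10`).
Within a block the saturation pulses sit at the block centre between a
balanced gradient pair on the phase axis, followed by an unbalanced slice
spoiler whose moment equals the block duration in TR units — the block is
therefore indistinguishable, for unsaturated spins, from the same duration
of idle imaging TRs (same timing, same net moment per axis). Blocks are
scheduled on the imaging-TR counter only and do not run inside segment
breaks. The two spatial band pulses are played back to back with a shared
spoiler; a given spin is covered by at most one band.

**Why the moments matter.** A constant background field offset acts like a
small always-on gradient. With block duration and per-axis moments equal to
an integer number of imaging TRs, the magnitude evolution of an unsaturated
spin is *exactly* independent of a constant off-resonance (the test suite
measures a mean magnitude deviation at machine precision); stretching the
block duration without rescaling the moments breaks the commensurability
and produces a clear off-resonance sensitivity (~5e-3 of the signal scale
at 30 Hz). This is the package's quantitative version of the
coherence-loss failure mode that motivates integer-scaled spoilers.

**Saturated-pathway exclusion.** For a spin the pulse affects, the freshly
tipped transverse magnetisation is created at phase-axis order zero and then
shifted off it by the post-pulse balancing gradient; every later RF can only
mirror the order's sign, so the pathway can reach slice-order zero but never
phase-order zero, and its contribution to each acquired sample is exactly 0
(machine zero, not merely small). The package verifies this by linearity: it
splits the state at the pulse, propagates the saturation-generated component
alone, and records its readout contribution. One genuine caveat, measured
and documented here: with *periodic* re-saturation, the next saturation
pulse can park part of the saturated magnetisation back at phase-order zero
in `Z` (a stimulated-pathway re-entry), after which imaging pulses excite
it. The exact-zero statement therefore holds for the pathways of a given
pulse up to the next block — and unconditionally for a single-block
sequence, which is the configuration the exclusion argument describes. The
re-entered fraction in a periodic two-axis run is of order 1e-2 of the
signal scale.

**Radial angles.** The golden-angle ordering is implemented as
`alpha(s, l) = mod(theta (s n_l + l) + pi [s even], 2 pi)` with
`theta = 111.25` degrees (readout `s`, shot `l` of `n_l`): a golden-angle
increment on the global spoke counter with a half-turn on alternate
readouts. The printed formula is typographically damaged and this is our
reading of its stated semantics. Note that 111.25 degrees is rational
(445/4), so the 4 x 250 spoke set folds onto exactly 288 distinct angles
(computable in integer quarter-degrees); only the irrational golden angle
would make all 1000 distinct. This is a property of the printed constant,
not of the implementation.

# Dictionary

The published axes are kept verbatim: 140 T1 entries from 140 ms and 160 T2
entries from 10 ms, both at 2.5% incremental steps, and achieved flips 1-89
degrees in 1-degree steps (stored in degrees for the 60-degree nominal
pulse, converted to a transmit scale at simulation time). Two remarks:

* The printed T1 upper bound of 4642 ms is inconsistent with its own
  (start, n, step) triple, which ends at `140 * 1.025^139 = 4333` ms. The
  package keeps the printed triple and reports the computed endpoint rather
  than silently altering a parameter.
* Entries with T2 > T1 are unphysical and excluded; ordering is
  deterministic (T1-major, then T2, then B1), which makes dictionary
  payloads byte-identical across runs.

Slice-profile correction discretises the small-tip excitation profile of a
Hann-apodised sinc (time-bandwidth product 3) into 32 equal-weight bins
across the nominal slab; each bin rescales the flip train. Dictionaries are
compressed in the time domain by SVD at rank 8 on the complex fingerprint
matrix (phase retained for matching); the residual energy outside the
subspace is recorded, and a noiseless self-match of every entry is preserved
at rank 8.

The chemical and combined variants share one dictionary: the saturation
pulses are assumed to leave water-spin dynamics untouched, and the package's
simulations make that exact (the water spin sees only the block's delay and
moments, which are identical for the 4-TR variants).

# Cramér–Rao analysis

Encoding power is compared through the Fisher information of the complex
signal with respect to `theta = (T1, T2, B1, rho)` under white Gaussian
noise, `I = sigma^-2 sum_n Re(J_n^H J_n)` with `sigma = 1` (it only scales
the result). Jacobians come from central finite differences (relative step
`1e-3`) through the same simulation code that builds the dictionary; the
rho column is exact by linearity. The complex-aware accumulation
(`Re(J^H J)`, sigma per real/imaginary channel) is the default; a
real-signal convention is available behind a flag. Bounds are normalised as
`nCRLB = CRLB / theta` — the printed form, which divides a variance by a
value; because the intended units are ambiguous, a `sqrt_mode`
(`sqrt(CRLB)/theta`, a relative standard deviation) is provided but not the
default. A singular information matrix (an unencoded parameter) yields a
pseudo-inverse result with the affected parameters flagged non-identifiable
instead of an error.

With the default train, the saturation-equipped variants have a higher
normalised T2 bound than the plain sequence at T1 = 1500 ms, B1 = 60
degrees, for T2 in {30, 60, 120} ms — the direction the protocol's
comparison reports. Absolute values depend on the flip-angle train, which is
not published numerically, so magnitudes are not comparable and are not
asserted anywhere.

One spec-level invariant was corrected during implementation: scaling rho
alone does *not* leave the T1/T2/B1 bounds unchanged at fixed noise (a
brighter signal tightens every bound by the square of the scale); the true
reparameterisation sanity is joint invariance under
`(rho, sigma) -> (k rho, k sigma)`, which is what the tests assert.

# Digital phantoms and reconstruction

The flow phantom is an agar-like disk (T1/T2 = 1400/60 ms) with two 10-mm
tubes of flowing water beside it. Flow is modelled at the signal level, not
by spin transport: through-plane flow at vessel velocities replaces the
slice content every TR, so the tubes emit the fresh-magnetisation signal
`-i rho sin(flip_n) exp(-TE/T2) m_z`, several times brighter than the
driven transient of static tissue; their phase carries a 1.5-rad swing
tracking the 1-Hz pump waveform (velocity-induced phase) plus 0.6-rad RMS
white jitter (beat-to-beat irregularity), and their amplitude pulsates by
30%. With a saturation band over the tubes, the inflowing spins were
saturated at the last block, so `m_z` is only the T1 regrowth since then.
The white phase component produces streaks whose intensity decays with
distance from the tubes; the periodic component produces broader swirl-like
artefacts; both are strongly suppressed by the band. The multicompartment
phantom holds ten cylinders spanning T2 ~25-310 ms (two above 200 ms, the
regime where interrupted trains lose accuracy), two oil disks at -440 Hz,
and a saline background.

Acquisition synthesises one spoke per readout by exact non-uniform DFT of
the piecewise-constant phantom: each region's static spatial spectrum is
computed once per spoke geometry and scaled by its instantaneous signal.
Reconstruction projects the spoke data onto the rank-8 temporal basis in
k-space and grids each coefficient channel by adjoint NUDFT with ramp
(`|k|`) density compensation (DC cell regularised to a quarter step;
spokes-as-diameters angular weighting). This adjoint-with-DCF route is the
documented default; no iterative reconstruction is attempted. On a complete
Cartesian sampling the same adjoint is the exact inverse DFT; on radial
samplings it leaves percent-level background ripple, which sets the noise
floor of the matched maps at matrix 64. Matching maximises the magnitude of
the normalised complex inner product over the compressed dictionary per
voxel; rho is the projection amplitude, and zero-signal voxels are flagged
unmatched. Matched-filter coil combination is implemented for synthetic
multi-coil runs and is the identity for the default single uniform coil.

Multi-shot protocols are modelled as seeded repeat-and-average of spoke
sets, each shot starting from equilibrium.

# Problem sizes used in the tests

Unit tests run on 40-120 readout trains and truncation orders 24-32, where
every closed form is still exact. The end-to-end checks use the full
1000-readout variants with: 15 EPG-vs-isochromat runs at order 64 and 256
isochromats; scaled dictionaries of 20 x 20 x 5 (2.5% steps around tissue
values: T1 from 800 ms, T2 from 40 ms, flips 36-84 degrees) for the SNR-30
recovery experiment (1000 trials; SNR 30 is defined per query, noise SD =
that fingerprint's peak magnitude / 30); a 20 x 24 x 3
grid (6% T1 steps from 700 ms for artifact headroom, 2.5% T2 steps from 45
ms) for the matrix-64 flow-phantom experiment; and 500 Monte-Carlo
realisations for the estimator-efficiency check. Distance-banded ROIs
(nearest-tube distance < 75 mm vs > 110 mm, both restricted to the body
interior to stay clear of edge ringing) quantify the streak gradient.

# What the synthetic experiments do and do not show

The generator reproduces the *mechanisms* — inflow brightness with unstable
phase, radial streak formation, band and fat suppression, encoding-power
loss from interrupting the train — under exactly known ground truth. It
does not reproduce scanner magnitudes: no coil-array geometry, no B0/B1
field maps, no magnetisation transfer (relevant for in vivo T1 drops under
saturation), no diffusion sensitivity of strong spoilers, no bulk spin
transport, and matrix 64 instead of 240. Passing the directional artefact
tests therefore says the physics and the pipeline are wired correctly, not
that quantitative artefact amplitudes transfer to any particular scanner.

# Known limitations

* Saturation pulses are frequency/slab-window tests, not shaped-pulse Bloch
  simulations; band edges are ideal.
* The exact published flip-angle train is not available; all
  train-dependent magnitudes (CRLB values in particular) are
  representative, not reproductions.
* Long-T2 dictionary entries carry ~1e-3 relative truncation error at the
  default order (see above).
* The periodic re-saturation re-entry pathway described earlier is a real
  second-order effect that the single-pulse exclusion argument does not
  cover.
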