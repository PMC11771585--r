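# satmrf

Simulation and analysis toolkit for **saturation-enabled MR fingerprinting
(SatMRF)** — magnetic resonance fingerprinting sequences in which spatial
saturation bands and chemical (fat) saturation pulses are interleaved with
the variable flip-angle train to suppress flow- and fat-related streak
artefacts in golden-angle radial acquisitions.

It is written for MR physicists and methods developers who want to study,
in silico, what saturation modules do to a fingerprinting acquisition:

* an **extended phase graph (EPG) engine** (compiled single-axis core plus a
  general multi-axis reference implementation and an independent isochromat
  Bloch oracle) that simulates FISP/FLASH fingerprint evolutions with
  inversion, 8&pi; gradient spoiling, 50&deg; quadratic RF spoiling, and
  saturation modules whose balanced read/phase gradients and integer-scaled
  slice spoilers keep saturated magnetisation out of every readout;
* declarative **sequence construction** of the five protocol variants
  (`MRF`, `SpaSatMRF_25`, `SpaSatMRF_10`, `FatSatMRF_10`, `AllSatMRF_10`:
  2- or 4-TR saturation blocks every 25th or 10th TR), with the golden-angle
  (111.25&deg;) radial readout ordering;
* **dictionary building** on the published geometric grids (T1/T2 at 2.5%
  steps, B1 in 1&deg; steps), slice-profile binning of a Hann-apodised sinc
  pulse, and rank-8 SVD time-domain compression;
* **Cramér–Rao lower bound** analysis: finite-difference Jacobians of the
  complex signal, Fisher information `I = sigma^-2 sum_n Re(J_n^H J_n)`,
  and normalised bounds `nCRLB = CRLB(theta_i)/theta_i` for
  `theta = (T1, T2, B1, rho)`;
* **digital phantoms** (pulsatile-flow tubes with inflow brightness and
  unstable phase; a multicompartment T1/T2/fat phantom), exact NUDFT radial
  acquisition, SVD-subspace adjoint gridding reconstruction, voxel-wise
  dictionary matching, and ROI statistics for streak-suppression
  experiments.

## Worked example

Build the 2-TR-block/25-TR-period spatial-saturation variant, simulate a
prostate-like spin, and compare encoding power against plain MRF:

```r
library(satmrf)

prog <- build_sequence("SpaSatMRF_25")
prog
#> <sequence_program> SpaSatMRF_25: 3244 events, 1000 readouts, TR/TE 7.5/3.5 ms
sequence_duration_tr(prog)
#> [1] 1230      # 1000 imaging TRs + 150 break TRs + 40 blocks x 2 TR

fp <- simulate_fingerprint(prog, spin_system(t1 = 1400, t2 = 60))
round(Mod(fp[1:5]), 4)
#> [1] 0.0637 0.0742 0.0843 0.0938 0.1027   # post-inversion transient

rep <- compare_sequences(list(build_sequence("MRF"), prog),
                         list(c(1500, 60, 60, 1)))
rep[, c("sequence", "t2", "ncrlb_t1", "ncrlb_t2", "ncrlb_b1")]
#>       sequence t2 ncrlb_t1 ncrlb_t2 ncrlb_b1
#> 1          MRF 60     1775    308.9    67.21
#> 2 SpaSatMRF_25 60     2105    581.0    68.71
```

The fingerprint is the complex signal at each of the 1000 readouts,
demodulated at the transmitter phase; the normalised bounds show the cost of
interrupting the train: the saturation-equipped sequence has a markedly
higher T2 bound (lower T2 encoding power) at the same T1/B1, the same
direction the in-vivo protocol observes. Absolute bound values depend on the
flip-angle train, which is configurable (`train_config()`); the default is a
representative sinusoidal-lobe train within the published 3.2–60&deg;
bounds.

A full phantom experiment (dictionary, radial acquisition, subspace
reconstruction, matching, ROI statistics, NIfTI export) runs from one YAML
configuration:

```r
cfg <- load_config("my_run.yaml")   # or load_config() for pure defaults
manifest <- run_pipeline(cfg)
```

A thin command-line interface over the same functions is installed at
`inst/cli/satmrf.R` (`dict`, `crlb`, `phantom` subcommands).

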