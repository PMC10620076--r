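# tistim

Desk-scale modeling of **transcranial temporal interference stimulation
(tTIS)** in R.

tTIS applies two high-frequency alternating currents (carriers
*f*₁ and *f*₁ + Δ*f* in the kHz range) through two independent electrode
pairs. Neither carrier alone is thought to drive neurons, but where the
fields overlap, their superposition is amplitude-modulated at the beat
frequency Δ*f*, and that low-frequency envelope can modulate neural
activity. Because the envelope depends on *both* fields, its peak can be
steered toward deep structures such as the striatum — the depth–focality
tradeoff that limits conventional transcranial electrical stimulation
does not apply in the same way. `tistim` is for researchers who want to
study the dosimetry and protocol design of this technique with fully
synthetic, reproducible inputs: every stage runs on a built-in layered
head phantom, with no external head model, solver, or data download.

The package covers, end to end:

* **Phantom** — a voxelized concentric-sphere head (scalp / skull / CSF /
  gray / white, plus a bilateral deep target), 10-10 electrode placement,
  and ROI masks (`build_phantom()`, `electrode_positions()`,
  `make_roi_set()`, `sphere_under_electrode()`).
* **Solver** — the ohmic quasistatic potential ∇·(σ∇φ) = 0 with Dirichlet
  electrode patches and current normalization, via a compiled
  finite-difference conjugate-gradient core (`solve_channel()`,
  `solve_potential()`, `normalize_current()`).
* **TI exposure** — the maximum modulation envelope magnitude per voxel,

  |E₂ₘ| = max₍|n|=1₎ 2 min(|n·E₁|, |n·E₂|)

  evaluated in closed form and pinned down by two independent oracles: a
  Fibonacci-sphere direction scan and a full time-domain beat simulation
  (`ti_envelope_map()`, `directional_modulation_oracle()`,
  `timedomain_envelope_oracle()`, plus the static `tdcs_magnitude_map()`
  comparator).
* **Montage sweep** — symmetric four-electrode montages scored by target
  exposure, focality and activation ratios against the 98% volumetric
  iso-percentile threshold, with Pareto-front extraction
  (`run_sweep()`, `exposure_metrics()`, `pareto_front()`).
* **Waveform** — the pulsed theta-burst TI protocol (frequency-shift
  keying: 3 envelope pulses at 100 Hz per 30-ms burst, bursts every
  200 ms within 2-s trains every 10 s) and its HF control, with
  envelope-based validation measured back from the signals
  (`synthesize()`, `burst_train_statistics()`, `session_schedule()`).
* **Reporting & pipeline** — ROI histograms and summary statistics,
  condition comparisons, NIfTI-1 I/O, YAML-configured end-to-end runs
  with hash-stable manifests (`roi_report()`, `run_pipeline()`).

## Worked example

```r
library(tistim)

# envelope of two interfering fields at one location (V/m)
E1 <- c(0.30, 0.10, 0.05)   # channel 1 field vector
E2 <- c(0.05, 0.25, 0.10)   # channel 2 field vector
ti_envelope_point(E1, E2)                      # closed form
#> [1] 0.5087801
directional_modulation_oracle(E1, E2, 1e6)     # independent direction scan
#> [1] 0.5087407

# a coarse phantom and the three symmetric montages over F3/F4 + TP7/TP8
phantom <- build_phantom(phantom_config(spacing_mm = 4))
rois    <- make_roi_set(phantom)
els     <- electrode_positions(c("F3", "F4", "TP7", "TP8"), phantom)
run_sweep(phantom, rois, els, currents_mA = c(2, 2))
#>    pair1   pair2    geometry_class threshold_V_per_m target_median focality_pct
#> 1  F3-F4 TP7-TP8  parallel-coronal             1.324         0.588            0
#> 2 F3-TP7  F4-TP8 parallel-sagittal             0.598         0.263            0
#> 3 F3-TP8  F4-TP7          crossing             1.469         0.745            0
#>   activation_pct pareto
#> 1              0  FALSE
#> 2              0  FALSE
#> 3              0   TRUE

# theta-burst waveform, measured back from the synthesized signals
env <- extract_envelope(synthesize(waveform_protocol()))
unlist(burst_train_statistics(env))
#>    burst_rate_Hz   train_period_s pulses_per_burst  am_frequency_Hz
#>         5.000014        10.000000         3.000000       100.000000
```

Reading the output: the two envelope evaluations agree to ~4 × 10⁻⁵ V/m,
the kind of cross-check the test suite performs on a thousand random
pairs. In the sweep, each row is one montage; `threshold_V_per_m` is the
98th-percentile exposure over the brain, `target_median` the median
envelope inside the deep bilateral target (V/m at 2 mA per channel), and
the crossing montage dominates on target exposure so it alone carries the
Pareto flag. Focality and activation are 0% here because on a smooth
spherical phantom the deep target does not reach the top-2% exposure set
— see the methods vignette (`vignettes/tistim-methods.Rmd`) for why that
is expected and what the phantom does and does not emulate. The waveform
statistics are measured from the synthesized two-channel signal and land
on the protocol's nominal values: 3 envelope pulses per burst at 100 Hz,
5 bursts per second, trains every 10 s.

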