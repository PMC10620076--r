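---
title: "Temporal interference dosimetry on a layered head phantom: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal interference dosimetry on a layered head phantom: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tistim)
```

## The problem

Transcranial temporal interference stimulation (tTIS) applies two
high-frequency alternating currents (carriers $f_1$ and $f_1 + \Delta f$,
both in the kHz range) through two independent electrode pairs. Neither
carrier alone is thought to drive neurons, but where the two fields
overlap their superposition is amplitude-modulated at the difference
frequency $\Delta f$, and that low-frequency envelope can modulate neural
activity. Because the envelope amplitude depends on *both* fields, its
peak can be steered into deep structures (striatum, hippocampus) that
conventional transcranial electrical stimulation cannot reach without
co-stimulating the overlying cortex.

`tistim` implements the computational chain needed to study this at desk
scale: a synthetic voxelized head phantom, a quasistatic forward solver,
the envelope-modulation dosimetric map, montage scoring and Pareto
selection, theta-burst waveform synthesis, and ROI reporting. Every stage
is testable without external data.

## The head phantom

Anatomically detailed head models and commercial finite-element solvers
are deliberately out of scope. The phantom is a set of strictly nested
spheres — scalp, skull, CSF, brain — with a gray-matter shell, a
white-matter core, and a bilateral deep spherical target embedded in the
white matter as a striatum stand-in. Defaults (all configurable through
`phantom_config()`):

| parameter | default | note |
|---|---|---|
| outer radii | 92 / 86 / 80 / 78 mm | adult-head scale, scalp/skull/CSF/brain |
| white-matter core radius | 68 mm | leaves a 10 mm gray shell |
| deep target | radius 12 mm at (±20, 5, 5) mm | bilateral, inside the white core |
| voxel edge | 2 mm (1–4 allowed) | isotropic, RAS axes, voxel-center convention |
| conductivities (S/m) | scalp 0.4, skull 0.01, CSF 1.79, gray 0.28, white 0.13, deep 0.28 | low-frequency tissue values typical of the quasistatic tES literature; air exactly 0 |

A voxel belongs to the innermost shell containing its center; with strict
inequalities no ties can occur. The grid always has an odd voxel count
per axis with the head center on a voxel center, which makes the label
volume *voxel-exactly* mirror symmetric about the mid-sagittal plane —
the property that guarantees exactly mirror-equal left/right electrode
patches and target masks.

Electrode positions come from a built-in 10-10 table. This is a
placement *convention*, not an anatomical reconstruction: a label's row
(Fp, AF, F, FC, C, CP, P, PO, O) maps to a sagittal angle in 18°
steps from the vertex, its column number to a lateral angle in 18° steps
(odd left, even right), and the direction is
$d = (\sin b,\ \cos b \sin a,\ \cos b \cos a)$. This puts Cz at
$(0,0,1)$ and makes homologs (F3/F4, TP7/TP8) exactly mirror symmetric.

## The quasistatic solver

Ohmic currents dominate displacement currents in tissue at kHz
frequencies, so the potential obeys $\nabla\!\cdot\!(\sigma\nabla\varphi)
= 0$. The solver discretizes this with a 7-point finite-difference
stencil; face conductivities are harmonic means of the two adjacent
voxels, which is the exact series conductance of two half-voxels and
stays well behaved at the ~200:1 CSF/skull contrast. Electrode contact is
ideal: the scalp patch voxels under each electrode are fixed at ±0.5 V
(Dirichlet), everything else is insulating (air has $\sigma = 0$, so
tissue/air faces carry no current). The symmetric positive-definite
system is solved by Jacobi-preconditioned conjugate gradients in compiled
code, to a relative residual of $10^{-8}$ by default (cap
$20 N^{1/3} \cdot 100$ iterations).

Because the problem is linear, the Dirichlet solution is rescaled to the
desired injected current ("current normalization"): the injected current
is measured as the sum of ohmic face currents leaving the anode patch,
and $\varphi$, $E$ are multiplied by the target/injected ratio. Anode and
cathode patch currents agree to ~$10^{-9}$ relative at the default
tolerance, which is the discrete conservation check. The electric field
is $E = -\nabla\varphi$ by central differences, one-sided into tissue at
tissue/air boundaries, zero in air. Carrier frequency does not enter the
solve: tissue dispersion is negligible across the low-kHz range, so one
solve per electrode pair serves both carriers.

Three independent oracles pin the solver down in the tests: the
parallel-plate slab ($|E| = V/d$, exact to $10^{-6}$), charge balance,
and the truncated Legendre series for antipodal point electrodes on a
homogeneous sphere. For the series comparison the discrete sphere is
represented by its *effective* radius $R - h/2$ (surface voxel centers
sit half a voxel inside the nominal boundary) and electrodes are single
voxels; agreement is within 2% on the axis up to $0.7R$ at 2 mm spacing.

## The TI exposure map

The dosimetric quantity is the maximum modulation envelope magnitude: at
each location, the amplitude of the envelope oscillation of the summed
two-channel field, maximized over field direction,

$$\left|E_{AM}^{max}\right| = \max_{|n|=1} \; 2\,\min\!\big(|n\cdot E_1|,\ |n\cdot E_2|\big).$$

The closed form evaluated voxelwise: after flipping the sign of $E_2$
when $E_1\!\cdot\!E_2 < 0$ (the envelope is phase-sign invariant) and
relabeling so $|E_1| \ge |E_2|$,

$$\left|E_{AM}^{max}\right| =
\begin{cases}
2|E_2| & |E_2| \le |E_1|\cos\alpha\\[2pt]
\dfrac{2\,|E_2 \times (E_1 - E_2)|}{|E_1 - E_2|} & \text{otherwise,}
\end{cases}$$

with $\alpha$ the angle between the sign-adjusted vectors. Correctness is
defined by oracle equivalence, not by the formula itself: the package
ships a deterministic Fibonacci-sphere direction scan
(`directional_modulation_oracle()`) and a full time-domain beat
simulation (`timedomain_envelope_oracle()`, analytic-signal envelope over
whole beat cycles), and the test suite holds the closed form to the scan
within $10^{-3}$ relative (at $2\times10^5$ directions) and to the
time-domain oracle within 1% on a thousand seeded random vector pairs
with magnitudes log-uniform in $[10^{-3}, 1]$.

The static comparator for direct-current montages is `tdcs_magnitude_map()`
($|E| \cdot I$), linked to the TI map by the collinear identity
`ti_envelope_map(f, f)/2`.

## Montage metrics and the Pareto front

A montage is scored against the deep target with three quantities, all
derived from the 98% volumetric iso-percentile threshold of the exposure
over brain voxels:

* **target exposure strength** — the *median* exposure inside the target
  (a deliberate choice: the exposure distribution is skewed, so the
  median is robust; the mean is reported alongside);
* **focality ratio** — percentage of suprathreshold brain volume that
  lies inside the target;
* **activation ratio** — percentage of the target volume that is
  suprathreshold.

Two conventions matter at small voxel counts and are fixed explicitly:
percentiles interpolate linearly between order statistics
(`quantile(..., type = 7)`), and "suprathreshold" is a *strict*
inequality. With an empty suprathreshold set focality is undefined and
reported as `NA`, activation as 0.

`enumerate_montages()` generates mirror-symmetric four-electrode
montages: every unordered pair of left/right homolog electrode pairs, in
all three pairings of the four electrodes — within-row homolog channels
(`parallel-coronal`), within-hemisphere channels (`parallel-sagittal`),
and cross-hemisphere cross-row channels (`crossing`) — giving
$3\binom{P}{2}$ montages for $P$ homolog pairs, a count asserted in
closed form by the tests. Larger sweeps reported for anatomical head
models use enumeration rules of their own; this package makes no claim
to reproduce any particular external count. Pareto flags
are standard non-domination over the three maximized objectives; equal
rows are all flagged, failed solves mark their rows and never abort a
sweep. Scaling both channel currents rescales thresholds and exposures
but provably leaves focality, activation and the Pareto set unchanged,
which the tests assert exactly.

## The pulsed theta-burst waveform

The protocol switches one carrier instead of gating amplitude: channel 1
runs continuously at $f_1 = 2$ kHz; channel 2 runs at $f_1$ and is
switched to $f_1 + \Delta f = 2.1$ kHz for 30 ms every 200 ms (5 Hz,
theta) within 2-s trains repeating every 10 s. Each 30-ms shift window
holds $\Delta f \times 0.03 = 3$ whole beat cycles — three envelope
pulses at 100 Hz per burst. Interburst and intertrain intervals carry
*unmodulated* high-frequency current, not silence. The HF control mode
never shifts: identical high-frequency exposure, flat envelope. Defaults:
2 mA per channel, 5-s linear ramps, 100 kHz sampling (integer samples per
beat and burst cycle), and a 25-s synthesized session (ramp plus two full
train periods) for the envelope validation.

Switching is phase-continuous: channel 2 integrates its instantaneous
frequency, so the accumulated phase is preserved at every switch and the
sample-to-sample slew never exceeds the one-sample carrier bound. Because
each shift window holds whole beat cycles, channel 2 returns *in phase*
with channel 1 at the end of every burst. Two design consequences follow
and are worth stating because they shape the envelope analysis:

* The summed-signal envelope equals its maximum ($2A$) on the
  unmodulated plateaus, and each burst's boundary maxima merge into those
  plateaus. A modulation pulse is therefore counted at its *trough*: a
  prominent excursion below 50% of the global envelope maximum (depth
  prominence ≥ 25% of the maximum, minimum separation half a beat
  period). Each beat cycle carries exactly one deep trough, so the count
  equals the number of amplitude-modulation cycles — 3 per default burst,
  measured from the signal, and 0 for the HF control.
* The dominant envelope frequency inside bursts is estimated from the
  mean trough-to-trough modulation period. A periodogram peak is biased
  by about 2% here — each burst holds only 2–3 modulation cycles, so the
  fundamental's main lobe overlaps the DC-removal leakage and the 200-Hz
  harmonic of the rectified-cosine envelope — whereas the period
  estimator recovers 100.0 Hz.

Remaining waveform conventions chosen where the protocol description was
open: the first shift window is aligned to the train onset, the ramp
precedes the first train, and both channels start at phase 0.

`session_schedule()` encodes the two experiment templates — six blocks of
ten 30-s task repetitions alternated with 30-s rests (stimulation during
task only; 30 min total), and seven 90-s task blocks with 90-s breaks
(10 min 30 s total) — and the totals are summed from the emitted
intervals, not hard-coded.

## ROI reporting

`roi_report()` produces the per-ROI record used for condition
comparisons: voxel count, mean, sd ($n-1$ denominator), median, 99th
percentile, and a histogram with 50 uniform bins on [0, 1] V/m by
default. Bins are left-closed/right-open with the final bin right-closed;
values above the clip are excluded from binning and reported as an
omitted-above-range count, so counts plus omissions always equal the ROI
size. Comparisons between conditions (e.g. tTIS vs tDCS) are purely
descriptive — voxels are not independent samples, so no inferential
statistics are attached. Report writers use sorted ROI order and fixed
float formatting, so identical inputs give byte-identical files.

## What the phantom does and does not show

The generator emulates the *geometry* of the problem — nested
conductivity shells, a deep bilateral target, superficial controls,
10-10 electrode placement — and that is enough to exercise every
algorithmic property: conservation, symmetry, linearity, threshold
bookkeeping, Pareto logic, envelope physics. It does not emulate
anatomy: no gyrification, no CSF channeling along sulci, no skull
inhomogeneity, no tissue anisotropy. Consequences worth knowing:

* Absolute exposure values and the published focality/activation numbers
  from the anatomical reference model are not reproducible here and are
  not targets; on the spherical phantom the deep target rarely reaches
  the top-2% exposure set, so focality/activation for realistic montages
  are typically near zero at the 98% threshold.
* The depth advantage of the TI arg-max is montage-dependent on a
  sphere. For the within-hemisphere (parallel-sagittal) pairing each
  cortex sees only its own channel, superficial envelope hotspots are
  suppressed, and the TI arg-max lands on the mid-sagittal surface,
  farther from the scalp than either single-channel arg-max. For the
  crossing pairing (F3–TP8 with F4–TP7) one electrode of each channel
  overlies the same fronto-temporal cortex, both fields are strong
  there simultaneously, and the envelope arg-max sits at that
  superficial patch — a tenth of a millimetre *shallower* than the
  single-channel arg-max, i.e. the depth property fails for that montage
  on this phantom. The anatomical detail that breaks this degeneracy in
  realistic head models is exactly what the phantom omits.

## Problem sizes and runtimes

The default phantom is $97^3$ voxels at 2 mm (~4 × 10⁵ conductive
unknowns; a channel solve takes ~700 CG iterations). Unit tests run most
solver work on a 4 mm phantom (~49³) where a solve takes about a second;
the acceptance-level physics checks (slab, charge balance, Legendre
sphere, arg-max depths) run at the 2 mm default. Waveform validation
synthesizes 2.5 × 10⁶ samples per channel (25 s at 100 kHz); envelope
extraction is one FFT of that length.
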