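---
title: "Comparative middle-ear mechanics: model, kinematics and delay estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative middle-ear mechanics: model, kinematics and delay estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earmech)
library(dplyr)
```

## The problem

Sound entering the ear canal drives the tympanic membrane (TM); the umbo —
the TM's most depressed point — moves the malleus, which drives the incus
and the stapes, whose piston-like motion pumps the cochlea. Laser-Doppler
vibrometry (LDV) measures the velocity of targets on these ossicles as
complex frequency responses normalised by ear-canal pressure:
`V_U/P_EC` at the umbo, `V_I/P_EC` at the incus tip, `V_ST/P_EC` at the
stapes head, each a magnitude in (mm/s)/Pa plus an unwrapped phase in
cycles. Comparative questions — how does a very large middle ear transmit
sound relative to a human one? — then reduce to arithmetic on these
spectra: transfer-function ratios across the ossicular chain, group delays
from phase slopes, and size ratios from micro-CT morphometry.

This package implements that computational chain as composable functions on
tidy tibbles, together with a lumped-element simulator that generates
physically structured spectra with known ground truth, so every downstream
stage can be verified by parameter recovery rather than against data that
cannot be redistributed.

## The lumped-element simulator

The umbo response is modelled as a series stiffness--resistance--mass
resonator driven by the force of ear-canal pressure acting over the TM
area:

$$\frac{V_U}{P_{EC}}(f) = \frac{A_{tm}\, i\omega}
  {K_{me} + i\omega R_{me} - \omega^2 m_{me}}\; e^{-i\omega \tau_{tm}},
  \qquad \omega = 2\pi f .$$

Below the resonance $f_{me} = \sqrt{K_{me}/m_{me}}/2\pi$ the response is
stiffness-dominated: magnitude rises at +6 dB/oct with phase near +0.25
cycles. Above it the mass dominates: −6 dB/oct and −0.25 cycles. At
resonance the reactances cancel, the magnitude peaks at $A_{tm}/R_{me}$ and
the (delay-free) phase crosses zero. The factor $e^{-i\omega\tau_{tm}}$ is
the travelling-wave delay across the TM surface.

The ossicular stage maps umbo to stapes velocity as

$$\frac{V_{ST}}{P_{EC}} = \frac{V_U}{P_{EC}}\cdot
  \frac{1}{l_M/l_I}\cdot H_{isj}(f)\cdot e^{-i\omega\tau_{oss}},$$

where $l_M/l_I$ is the anatomical lever ratio (malleus over incus lever
arm; low-frequency $|V_{ST}/V_U|$ is approximately its reciprocal),
$H_{isj}$ is a unit-DC-gain second-order resonance
$1/(1 - (f/f_0)^2 + i f/(f_0 Q))$ standing for the incudostapedial-joint /
incus-pedicle resonance (identity when absent), and $\tau_{oss}$ is the
ossicular transmission delay. An incus-tip response is generated so the
umbo-to-stapes transfer function factors exactly:
`TF_US = TF_UI * TF_IS`. The split is a modelling choice of this package:
the lever attenuation and half of $\tau_{oss}$ sit between umbo and incus
tip, the ISJ resonance and the other half between incus tip and stapes. No
published circuit constrains this; only the product is observable in the
quantities the pipeline reports.

### Presets

`species_preset()` stores the two study conditions in one registry:

| parameter | elephant | human | meaning |
|---|---|---|---|
| $f_{me}$ | 300 Hz | 1000 Hz | middle-ear resonance |
| $m_{me}$ | 600 mg | 60 mg | effective mass (TM + ossicles) |
| $K_{me}$ | $m(2\pi f_{me})^2$ | same | both species share one stiffness |
| $Q$ | 1.5 | 1.5 | resonance sharpness ($R = m\omega_0/Q$) |
| $A_{tm}$ | 504.9 mm² | 67.3 mm² | eardrum area |
| $l_M/l_I$ | 2.8 | 1.4 | lever ratio |
| $\tau_{tm}$ | 60 µs | 14 µs | eardrum delay |
| $\tau_{oss}$ | 77 µs | 42 µs | ossicular delay |
| ISJ | 9 kHz, Q = 4 | none | high-frequency transmission boost |

The masses, areas, lever ratios and delays are the comparative study's own
estimates; sharing one stiffness and attributing the resonance shift
entirely to the ten-fold mass difference follows the interpretation those
measurements support. The resonance quality Q = 1.5 is this package's
choice — the published responses show a broad, shallow peak and no fitted
damping value exists; it was fixed once and is not tuned. The ISJ quality
Q = 4 realises the reported ~4x high-frequency boost of incus-to-stapes
transmission (a second-order peak of quality Q has gain ≈ Q).

The default frequency grid is log-spaced at 100 points/decade over
7 Hz–13 kHz, the measured range. Noise, when requested, is independent
Gaussian on log-magnitude (dB) and on phase (cycles), seeded; the
published inter-specimen spread of roughly ±10 dB motivates the dB domain,
but no empirical noise model exists, so the defaults (3 dB, 0.02 cycles)
are nominal.

### What the simulator does not emulate

Real spectra include the sub-20 Hz resistive plateau, TM breakup modes,
measurement-system artefacts and frequency-dependent coherence loss. None
of these are modelled (the resistive shunt was considered and left out: no
parametric form is available). Passing recovery tests on simulated data
therefore demonstrates the correctness of the *analysis* chain — rotation
algebra, projection, unwrapping, fitting — not the adequacy of the
two-stage circuit as a middle-ear model.

## Kinematics: from three beams to one piston velocity

A 3D LDV measures three orthogonal velocity components in its own frame.
The anatomically relevant motion is 1D: along the stapes piston direction
(perpendicular to the footplate) or the TM-plane normal for the umbo.
Orientations are recorded as three intrinsic rotations in degrees, in
either of two explicit conventions (`measured_order`: azimuth about z,
elevation about the new x, rotation about the new y; or `zyx`), composed
by right-multiplication into proper rotation matrices. Frames are
right-handed and positive angles counter-clockwise looking down the axis;
this convention is pinned by the published demonstration that the two
angle sequences for one human temporal bone (+20° z, +40° x, −150° y
measured; about −139° z, −22° y, +135° x re-expressed) produce the same
matrix. Note the re-expressed angles are printed rounded to whole degrees,
so the printed pair agrees only to ~1.3e−2 entrywise; `as_zyx()`
recomputes the z-y-x set at full precision, where agreement is at machine
precision.

`project_to_piston()` is the complex scalar product of the three
components with a unit direction — linear, exact, and insensitive to any
motion orthogonal to the direction. `synthesize_ldv_3d()` inverts it:
it embeds a known piston spectrum at an arbitrary orientation plus
deliberate orthogonal contamination, giving round-trip fixtures whose
recovery error is at numerical precision. `legacy_cos_correction()`
implements the older single-beam practice (divide magnitude by
cos θ), valid only for pure piston motion — the round-trip fixtures make
that limitation testable.

## Spectra arithmetic

Phase unwrapping adds integer cycle offsets so adjacent differences lie in
(−0.5, +0.5]; above a configurable enforcement frequency (default 5 kHz,
applied to elephant ears only, where delay accumulates fast enough that
the raw wrap is ambiguous) offsets additionally forbid rises larger than a
tolerance, keeping the phase monotonically decreasing. Every applied
offset is reported, because a manual-unwrap step must be auditable.
Unwrapping is idempotent.

`transfer_function()` divides magnitudes and subtracts unwrapped phases.
Spectra on different grids are reconciled by linear interpolation of
log-magnitude and phase onto the coarser grid over the overlapping range —
a documented choice; ratios of independently sampled measurements need
*some* alignment rule and none is prescribed. Points where the denominator
falls below 1e−6 of its peak are masked, not fatal.

Group averaging works in the presentation domains — dB for magnitude
(a geometric mean on the linear scale) and cycles for phase — matching how
mean ± SD bands are drawn on log axes; complex averaging would instead
penalise phase dispersion, and which of the two the published mean curves
used is not stated. `prepare_stats_table()` produces the analysis-ready
long table for mixed-effects modelling (log magnitude, log(phase + 4),
17 Hz–11 kHz, low/high split at 1 kHz); the models themselves are
deliberately out of scope.

## Group delays

`fit_group_delay()` fits an ordinary least-squares line to unwrapped phase
(cycles) against frequency (Hz, linear axis) over a band, inclusive at
both edges; the group delay is the negative slope, in µs. The fit is
unweighted over the points present, so a log-spaced grid concentrates
weight at the low end of the band — the stated procedure says no more, and
this is the plainest reading. Bands sit above each species' resonance:
elephant NR 600–1200 Hz, HF 1.2–11 kHz; human NR 2–4 kHz, HF 4–11 kHz;
WB is the union.

The ear-canal acoustic path from probe tube to umbo adds `distance/c`
(c = 344 m/s) of delay; `estimate_group_delays()` subtracts it after
fitting. Fitting corrected phase or correcting the fitted delay are
identical by linearity of OLS, and that equivalence is asserted in the
tests. Corrected delays may be negative and are reported as-is. Group
summaries use the population SD (divisor n): the specimen sets are
summarised as the complete measured group, which is the form the
published per-group SDs follow. Report tables round to one decimal in µs,
and transmission delays (stapes minus umbo group delay) are differenced
from those rounded means, reproducing the published values exactly.

One numerical subtlety: a fitted band-average group delay of a *simulated*
spectrum is the injected delay plus the circuit's own dispersive delay
(for the resonator, $R/(4\pi^2 m f^2)$, about 2 µs averaged over the
elephant HF band; more for the stapes branch near the ISJ resonance).
That term is physics, not estimator bias. Recovery tests therefore verify
the *injected* delay as the difference between fits with and without the
injected delays — exact by OLS linearity — alongside exact recovery on
pure delay lines and unbiasedness under seeded phase noise (200
replicates, mean within 3 SE of truth).

## Morphometry

Primary stored quantities are measured inputs only: two TM diameters,
thickness, segmented ossicle volumes, densities (water for the TM, 2.31
mg/mm³ malleus, 2.14 incus and stapes), lever arms. Everything else is
always derived: TM area $\pi(d_1/2)(d_2/2)$, masses as volume × density,
chain mass as the sum of three ossicle masses, lever ratio $l_M/l_I$, and
elephant/human size ratios as elephant means over the human value, one
decimal with an "x" suffix. The second TM diameter is not published and is
carried as an input solved once from the printed area. The human TM
thickness is flagged as likely inflated ~2–3x by the imaging method
(soft-tissue contrast); the flag is metadata, no correction is applied.
Derived scalars include the resonance law $\sqrt{K/m}/2\pi$ and the TM
surface-wave speed (radius/delay: 13.6 mm / 60 µs ≈ 227 m/s for elephant;
the human inputs 5.0 mm / 12 µs give 417 m/s against a published 425 m/s,
whose exact inputs are ambiguous — the computed value is reported and the
discrepancy noted, not forced).

## Problem sizes and determinism

The test-suite simulations use 40 points/decade grids (≈130 points over
7 Hz–13 kHz) and the acceptance script 100 points/decade (≈330 points);
property checks loop over a few dozen seeded random orientations and 200
noisy replicates for the delay-bias check. These sizes make every
quantity's Monte-Carlo error far smaller than the tolerances asserted
while keeping the whole suite fast. All randomness is seeded; the
pipeline is deterministic given (inputs, seed).

## A worked example

```{r example, fig.width = 6, fig.height = 4}
cfg <- tibble::tibble(
  specimen_id = c("E1", "H1"),
  group = c("elephant", "human"),
  probe_distance_mm = c(41, 5)
)
spectra <- bind_rows(
  simulate_specimen_bundle(species_preset("elephant"), "E1",
    probe_distance_mm = 41
  )$spectra,
  simulate_specimen_bundle(species_preset("human"), "H1",
    probe_distance_mm = 5
  )$spectra
)
res <- run_pipeline(spectra, cfg)
res$gd_summary
res$transmission
```

The human transmission delay equals the injected 42 µs ossicular delay
(no ISJ stage); the elephant value exceeds its injected 77 µs by roughly
30 µs of dispersive delay contributed by the 9 kHz ISJ resonance inside
the fitted band, as discussed above.

## Known limitations

* The two-stage circuit is the minimal structure consistent with the
  observed asymptotes; it is not a validated anatomical network, and its
  parameters are interpretable only in that minimal sense.
* Grid reconciliation and dB/cycles averaging are documented choices among
  reasonable alternatives; results for strongly disparate grids depend
  mildly on them.
* The TM-plane landmark choice for the umbo normal is configuration, not
  anatomy: `normal_from_three_points()` is the mechanism, the landmarks
  are inputs.
* Angles are inputs throughout; nothing estimates them from images.
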