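# earmech

Tools for comparative middle-ear biomechanics from laser-Doppler
vibrometry (LDV) data, built for researchers analysing how the ossicular
chain — malleus, incus, stapes — transmits sound from the eardrum to the
cochlea, and how that transmission scales between species as different in
size as elephant and human.

Middle-ear measurements arrive as complex frequency responses: umbo,
incus-tip and stapes velocities normalised by ear-canal pressure
(`V_U/P_EC`, `V_I/P_EC`, `V_ST/P_EC`; magnitude in (mm/s)/Pa, unwrapped
phase in cycles). The package implements the full analysis chain on tidy
tibbles:

* **Simulator** — a lumped-element model
  `V_U/P_EC = A_tm · iω / (K_me + iωR_me − ω²m_me) · e^{−iωτ_tm}`, with an
  ossicular stage `(1/(l_M/l_I)) · H_isj(f) · e^{−iωτ_oss}`, generating
  physically structured spectra with known ground truth (resonance
  `f_me = √(K_me/m_me)/2π`, +6/−6 dB/oct asymptotes, lever attenuation,
  a 9 kHz incudostapedial-joint boost for elephant, 10–200 µs delays).
  Elephant and human presets live in `species_preset()`.
* **Kinematics** — intrinsic Euler-angle rotation composition in two
  explicit conventions, full-precision conversion between them
  (`as_zyx()`), projection of 3-component LDV velocities onto anatomical
  piston directions, TM-plane normals from landmarks, and the legacy
  `1/cos θ` single-beam correction.
* **Spectra arithmetic** — auditable phase unwrapping (with a
  monotone-decrease rule above 5 kHz for elephant ears), transfer
  functions `TF_US = V_ST/V_U = TF_UI · TF_IS`, dB conversion, group
  mean ± SD in dB/cycles, and the analysis-ready table for mixed-effects
  modelling.
* **Group delays** — banded least-squares line fits to phase versus linear
  frequency (GD = −slope), ear-canal propagation corrections
  (`distance / 344 m/s`), per-group summaries and umbo→stapes
  transmission delays.
* **Morphometry** — micro-CT arithmetic: elliptical TM area from two
  diameters, mass = volume × density, ossicular chain mass, lever ratios
  `l_M/l_I`, elephant/human size ratios, resonance scaling and TM
  surface-wave speed.

## Worked example

Simulate one virtual specimen per species, run the pipeline, and read off
group delays and transmission delays:

```r
library(earmech)
library(dplyr)

cfg <- tibble::tibble(
  specimen_id = c("E1", "H1"),
  group = c("elephant", "human"),
  probe_distance_mm = c(41, 5)
)
spectra <- bind_rows(
  simulate_specimen_bundle(species_preset("elephant"), "E1", probe_distance_mm = 41)$spectra,
  simulate_specimen_bundle(species_preset("human"), "H1", probe_distance_mm = 5)$spectra
)
res <- run_pipeline(spectra, cfg)
res$transmission
#> # A tibble: 4 × 5
#>   group    band  umbo_gd_us stapes_gd_us transmission_us
#>   <chr>    <chr>      <dbl>        <dbl>           <dbl>
#> 1 elephant HF          62.2        171.             109.
#> 2 elephant WB          64.3        168.             104.
#> 3 human    HF          16.5         58.5             42
#> 4 human    WB          19.4         61.4             42
```

The human umbo→stapes transmission delay recovers the injected 42 µs
ossicular delay exactly; the elephant estimate exceeds its injected 77 µs
because the 9 kHz joint resonance adds dispersive delay inside the fitted
band (see the vignette). The umbo delays carry the eardrum delay plus the
resonator's own small dispersion.

Morphometric size ratios regenerate from primary micro-CT measurements:

```r
comparative_table()$ratios[c(2, 5, 9), ]
#> # A tibble: 3 × 5
#>   quantity      elephant_mean human ratio ratio_label
#>   <chr>                 <dbl> <dbl> <dbl> <chr>
#> 1 tm_area_mm2            505.  67.3  7.50 7.5x
#> 2 tm_mass_mg             183.  12.7 14.4  14.4x
#> 3 chain_mass_mg          529.  56.5  9.37 9.4x
```

— the elephant eardrum is 7.5× the area and 14.4× the mass of the human
one, and its ossicular chain 9.4× heavier, which is what drops its
middle-ear resonance from ~1 kHz to ~300 Hz at comparable stiffness.

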