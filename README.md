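# mpsflow

Reduced-order design and analysis models for two-channel membrane
microphysiological systems (organs-on-chips): devices in which an apical
and a basal microfluidic channel, driven by pneumatic pressure pumps, are
separated by a porous culture membrane carrying a cellular barrier — an
alveolar air–liquid interface, or a glomerular filtration barrier (GFB)
with podocytes and endothelial cells on opposite membrane faces.

The package is for device designers and experimentalists who need
quantitative answers without a finite-element model:

* **Hydraulics** — by the hydraulic–electric analogy, every channel
  segment, membrane pore and port bore is a resistor. Elementary
  resistances (`pore_resistance()`, `membrane_resistance()`,
  `channel_resistance()`), Darcy permeability `k = φR²/8`, wall shear
  stress `τ = 6μQ/(bh²)`, and a coupled network solver
  (`solve_coupled_network()`) that predicts steady transmembrane
  ultrafiltration. Inverse fits recover system resistance from
  pressure–flow sweeps (`fit_pq_line()`) and membrane permeability from
  observed ultrafiltration (`fit_membrane_permeability()`).
* **Mechanics** — bi-axial membrane strain from measured center
  deflection, via a semi-ellipsoid surface-area model
  `SA = 2π[((ab)^p + (ac)^p + (bc)^p)/3]^{1/p} + πbc` (p = 1.6075),
  `ε_SA = (SA_f − SA_0)/SA_0`.
* **Waveforms** — pump pressure programs (constant perfusion,
  breathing-cycle sinusoids, e.g. 345 mbar at 0.33 Hz = 20 breaths/min)
  with exact CSV round-trips, plus mbar/mmHg/Pa and bpm/Hz conversions.
* **Assays** — TEER by the Ohm's-law method
  `TEER = (R_meas − R_blank)·M_area`, clearance-based filtration
  `F = [A]·AV/[B]`, blank normalization, linear signal calibration, and a
  tidy batch analysis (`batch_assay()`).
* **Synthetic data** — seeded generators (`synthetic_scenario()`,
  `gen_*()`) emulate every instrument readout the analyses consume, so the
  whole pipeline runs and is tested with no external data.

See `vignettes/mpsflow-methods.Rmd` for the models, assumptions, defaults
and their provenance.

## Worked example

Predict the ultrafiltration of the default glomerular-configuration chip
(apical/basal well widths 6/4.5 mm, height 0.5 mm, 35 mm channels, 3 µm-pore
track-etched membrane over the 27 mm² well overlap, water) with both inlets
perfused at 100 µL/min:

```r
library(mpsflow)
chip <- default_chip()
run_design(chip, apical_flow_ul_min = 100, basal_flow_ul_min = 100)
#> <design_report>
#>   transmembrane flow: 2.139 uL/min
#>   shear: apical 0.006667 Pa, basal 0.008889 Pa
```

The narrower basal channel and its deeper port bores run at a slightly
higher pressure than the apical channel, so about 2% of the perfusion
(2.14 µL/min) ultrafilters across the membrane in the basal → apical
("urinary") direction; the membrane surfaces see milli-pascal-scale shear.
With an output directory, `run_design()` also writes the full node-pressure
solution, a summary with every parameter used, and a manifest.

Barrier-function analysis of a synthetic filtration experiment (albumin
and freely-filtered inulin; healthy barrier vs sphingolipid-injured
podocytes, n = 3):

```r
sc <- synthetic_scenario(seed = 42)
run_assay(gen_filtration_readouts(sc))
#>    solute condition n filtration_ul filtration_sd normalized_filtration
#> 1 albumin     blank 3         110.6          9.48                 1.000
#> 2 albumin   control 3          30.6          5.02                 0.276
#> 3 albumin       S1P 3          60.5          5.50                 0.547
#> 4  inulin     blank 3         111.0         11.51                 1.000
#> 5  inulin   control 3         111.0         21.36                 1.000
#> 6  inulin       S1P 3         111.3          8.22                 1.003
```

A healthy podocyte barrier passes ~28% of the albumin a blank membrane
passes; after S1P injury that roughly doubles, while inulin — freely
filtered — stays at 1 in every condition. TEER from a volt-ohm-meter
reading: `teer(150, 100, 0.336)` gives 16.8 Ω·cm²; and
`deflection_for_strain(0.04, default_planform())` locates the 0.469 mm
center deflection at which membrane stretch reaches 4% bi-axial strain.

A thin command-line wrapper over the same functions ships in
`inst/cli/mps.R` (subcommands `design`, `strain`, `waveform`, `assay`,
`fixtures`).

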