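---
title: "Reduced-order modeling of a two-channel membrane chip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order modeling of a two-channel membrane chip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpsflow)
```

## The device and the modeling problem

`mpsflow` models a class of microphysiological systems ("organs-on-chips")
in which two shallow microfluidic channels — an *apical* and a *basal*
channel — are separated by a porous culture membrane over a culture-well
region. Cells grown on the two faces of the membrane form biological
barriers (an alveolar air–liquid interface, or a glomerular filtration
barrier with podocytes above and endothelial cells below), and the chip is
perfused by pneumatic pressure pumps. Four questions recur when designing
and analyzing such devices, and the package answers each with a small,
testable model:

1. **Hydraulics.** What pressures, flows, wall shear stresses and
   transmembrane ultrafiltration develop for a given geometry and pump
   setting?
2. **Mechanics.** How much bi-axial stretch does a pressure-deflected
   membrane experience?
3. **Waveforms.** What pressure commands implement a protocol (steady
   perfusion, breathing-like cyclic stretch)?
4. **Assays.** How are barrier-function readouts — TEER and clearance-based
   filtration — computed from instrument measurements?

## The lumped hydraulic network

Laminar pressure-driven flow maps onto Ohm's law (the hydraulic–electric
analogy): pressure is voltage, volumetric flow is current, and every
channel segment, pore and access bore is a resistor.

**Channel segments.** A shallow rectangular channel of width $b$, height
$h \le b$ and length $L$ carries plane-Poiseuille resistance
$R = 12\mu L/(b h^3)$. This closure is consistent with the wall-shear
formula below; the leading rectangular-duct correction
$1/(1-0.63\,h/b)$ (about 5–8% for these aspect ratios) is available behind
`channel_resistance(..., exact = TRUE)` and `solve_coupled_network(...,
exact_duct = TRUE)`.

**Membrane.** Each pore is a circular pipe of radius $R$ and length equal
to the membrane thickness $L_m$, with Poiseuille resistance
$R_{pore} = 8\mu L_m/(\pi R^4)$. A track-etched membrane is a parallel
array of $A\,n$ such pores ($n$ = pore density, related to the open-area
fraction $\phi$ by $\phi = n \pi R^2$), so

$$R_{memb} = \frac{R_{pore}}{A\,n} = \frac{8 \mu L_m}{R^2 A \phi},
\qquad k = \frac{\pi n R^4}{8} = \frac{\phi R^2}{8},$$

where $k$ is the Darcy permeability (m²) of the pore array. The two forms
are algebraically identical — $R_{memb} = \mu L_m/(k A)$ holds to machine
precision, and the test suite asserts it. We state this because a common
slip is to read the pore "density" symbol as the dimensionless porosity;
doing so inflates the membrane resistance by a factor $1/(\pi R^2) \sim
10^{11}$ and makes any observable ultrafiltration impossible.

**Wall shear stress.** At the membrane surface,
$\tau = 6\mu Q/(b h^2)$ — the plane-Poiseuille wall value.

**The coupled solver.** `solve_coupled_network()` discretizes each channel
into axial resistors with `n_segments` coupling segments across the well
region; the membrane conductance $1/R_{memb}$ is apportioned over the well
nodes with trapezoidal weights. Kirchhoff's current law at every node gives
a small symmetric linear system, solved densely (a few hundred unknowns at
most — no iterative tolerance is needed or exposed). Each inlet takes
either an imposed pressure or an imposed flow; outlets are held at gauge
pressure 0 because the chip drains to open reservoirs. Transmembrane flux
is summed per segment, with the positive direction basal → apical (the
"urinary" direction in the glomerular configuration).

Numerical properties the tests enforce: interior mass conservation below
$10^{-9}$ relative; solutions linear in the boundary values; the
one-segment solution equal to a hand-solved star circuit; transmembrane
flow changing by well under 1% from 64 to 128 segments (64 is the default
for reported runs).

## The default chip and its provenance

```{r}
chip <- default_chip()
chip$membrane
run_design(chip)
```

Printed dimensions: culture-well widths 6 mm (apical) and 4.5 mm (basal),
well height 0.5 mm, water as working fluid, pore radius 1.5 µm (a 3 µm-pore
insert). The remaining parameters are not printed anywhere for the physical
device, so the defaults document this package's own choices, all
user-overridable through `read_chip_config()`:

* **Membrane thickness 10 µm, porosity 0.14.** Typical of commercial 3
  µm-pore track-etched inserts (nominal pore density around
  $2\times10^6\,\mathrm{cm^{-2}}$ gives $\phi = n\pi R^2 \approx 0.14$).
  Manufacturers differ: some 3 µm inserts are nearer
  $0.6\times10^6\,\mathrm{cm^{-2}}$ ($\phi \approx 0.04$), which would
  scale the predicted ultrafiltration down about threefold. Every run
  prints the membrane parameters used, precisely because this is the least
  certain part of the model.
* **Channel length 35 mm, well centered.** A chip clamped in a standard
  45 × 15 mm holder format.
* **Port access vias.** The chip is a two-part milled stack: the apical
  channel lives in the top piece and is reached through one 0.125-inch
  (3.175 mm) acrylic layer; the basal channel is milled into the bottom
  piece and sealed underneath by a film, so its fluid access bores pass
  through both layers (6.35 mm). These bores are genuine series
  resistances, and because they are *asymmetric* between the channels they
  contribute most of the basal-side overpressure that drives
  ultrafiltration at equal inlet flows. Bore radius defaults to 0.5 mm (a
  standard 1 mm port drill); note the $r^{-4}$ sensitivity — a chip with
  different port bores should override `via_radius`. Width asymmetry alone
  (6 vs 4.5 mm) produces roughly half the ultrafiltration that the vias
  and widths produce together.

With these defaults, both inlets at 100 µL/min yield a transmembrane flow
of about 2.1 µL/min — about 2% of the perfusion, in line with a
pressure-driven filtration barrier operating at sub-pascal transmembrane
pressure differences.

**Open heights.** Only the culture-well height (0.5 mm) is printed; both
channel heights are therefore explicit configuration with that default. A
reported order-of-magnitude shear contrast between the channels cannot be
reproduced from the printed widths alone (they give only $6/4.5 = 1.33$)
and is not asserted by this package.

## Membrane strain from deflection

A membrane deflected by pressure over an elliptical well (semi-axes
$b \ge c$) is treated as a half-ellipsoid of cap height $a$ (the measured
center deflection, from focal-distance tracking) on the base ellipse:

$$SA = 2\pi\left[\frac{(ab)^p + (ac)^p + (bc)^p}{3}\right]^{1/p} +
\pi b c, \qquad p = 1.6075,$$

the Thomsen approximation (exact for the sphere: $a=b=c=r$ gives
$3\pi r^2$, asserted in the tests; $p$ is fixed, not configurable). The
bi-axial surface strain is $\varepsilon_{SA} = (SA_f - SA_0)/SA_0$.

One subtlety is deliberate: the $a \to 0$ limit of the cap term is
$2\pi b c (1/3)^{1/p} \approx 1.01\,\pi bc$, *not* the flat ellipse
$\pi b c$. `biaxial_strain()` therefore evaluates $SA_0$ with the same
formula at $a = 0$ rather than using $\pi b c$: this guarantees
$\varepsilon_{SA}(0) = 0$ exactly and cancels the formula's ~1% degenerate
bias. Whether the original analysis used this convention is unknown; it is
this package's documented choice. The planform defaults to half the
printed well widths ($b = 3$, $c = 2.25$ mm) and is overridable, since the
values actually used are not stated.

No pressure→deflection plate model is implemented — deflection is always
measured input. The inverse question ("what deflection gives 4% strain?")
is answered by `deflection_for_strain()` via root bracketing:

```{r}
deflection_for_strain(0.04, default_planform()) # mm
```

## Pump programs

`sine_program()` and `constant_program()` produce idealized commanded
waveforms — e.g. a breathing cycle at 345 mbar amplitude and 0.33 Hz (20
breaths/min) over a constant basal perfusion pressure. Pump actuation
dynamics are *not* modeled (no transfer function is available), so the
realized pressure in hardware will deviate from the command. Pressures are
non-negative by contract (the pumps cannot pull vacuum); a sinusoid whose
trough would dip below zero is rejected unless clipping is explicitly
enabled. The sine baseline to pair with a 345 mbar amplitude is not
prescribed by any protocol; the CLI's breathing preset uses offset =
amplitude, the smallest non-clipping choice. Default sampling is 10 Hz
with an inclusive endpoint; CSV export uses fixed 6-decimal formatting so
that export → import → export is byte-identical.

## Barrier-function assays

**TEER** (Ohm's-law method): $TEER = (R_{meas} - R_{blank}) \times
M_{area}$ in Ω·cm². The area is a *required* argument (0.336 cm² for the
24-well transwell format, but insert formats differ, so there is no silent
default). Negative cell-layer resistance — cells measuring below the blank
— is a common instrument artifact; it is returned with a warning rather
than raised, so batch processing never crashes on it.

**Filtration** (renal-clearance form): $F = [A] \cdot AV / [B]$, a cleared
volume, where $[A]$, $[B]$ are apical/basal outflow concentrations and
$AV$ the apical volume collected. Free filtration clears exactly $AV$;
perfect retention gives 0. `normalized_filtration()` divides by the blank
membrane's filtration, and `batch_assay()` applies both over a tidy
readout table, normalizing each solute against the mean of its blank rows
(so blank rows report exactly 1 by construction) and averaging replicates.
Raw plate-reader signals can be converted first with a linear
blank-subtracting calibration (`signal_to_concentration()`; negative
concentrations clamp to 0 with a flag). Nonlinear calibration (4PL) and
group-comparison statistics (t-tests, ANOVA) are deliberately out of
scope: the outputs are tidy tables for any statistics environment.

## What the synthetic generators emulate — and what they do not

All analyses are exercised end-to-end on seeded synthetic data
(`synthetic_scenario()` plus `gen_*()`); identical seeds give byte-identical
tables, and each generator consumes its own RNG stream without touching
the caller's RNG state. Choices, made once and documented here:

* **Flow sweeps**: true flow $P/R_{true}$ on a 0–150 mbar grid (11 levels,
  60 s at 10 Hz) with additive Gaussian sensor noise scaled to instrument
  full scale (default 2% of 1000 µL/min, a typical thermal flow-meter
  class). $R_{true}$ defaults to $3\times10^{12}$ Pa·s/m³ — the *system*
  resistance seen by a pressure sweep (chip plus tubing and sensor), an
  order of magnitude above the bare chip.
* **Deflection sweeps**: a power law $a(P) = c_1 P^{c_2}$, $c_2 = 1/3$ by
  default, chosen only because it is monotone through the origin (the
  large-deflection membrane regime scales like $P^{1/3}$); it carries no
  claim about this membrane's physics. $c_1$ is anchored so the 315 mbar
  endpoint reaches exactly 4% bi-axial strain on the default planform,
  mirroring the observed maximum. Focal-distance noise is additive
  Gaussian (default 2 µm).
* **TEER time courses**: logistic coverage growth over 5 days mapped to
  resistance, with final-day ordering co-culture ≥ endothelial-only ≥
  podocyte-only (podocytes terminally differentiate; endothelia proliferate
  to confluence; the co-culture ends only slightly — ≤1.3× — above
  endothelial-only). Ohmmeter noise is additive Gaussian (default 2 Ω).
* **Filtration readouts**: basal outflow at the feed concentration
  (2 mg/mL albumin, 100 µg/mL inulin), apical outflow at sieving × feed,
  both under unit-mean log-normal noise (default CV 10%). Default sieving
  truths: inulin 0.95 in every condition (freely filtered); albumin 0.9 on
  blank membranes, 0.25 across a healthy podocyte barrier, and 0.5 after
  sphingolipid (S1P) injury — a 2× increase, a configurable effect size
  since no magnitude is printed. Replicates default to $n = 3$.

Passing tests on these generators demonstrate *internal consistency* —
parameter recovery, conservation, correct plumbing — under the stated
noise models. They do not validate the noise models themselves against
real instruments, nor cell biology (differentiation, mucin production,
drug response) beyond the effect-direction structure above, nor the
unprinted membrane/port parameters of any physical chip.

## Problem sizes and numerical choices

Reported design runs use 64 segments (mesh-converged to well under 1%).
Monte-Carlo test sizes: 200 replicates for resistance recovery (expecting
≥95% within 5% at 2% sensor noise), 100 seeds for permeability recovery
(median within 10% at 5% noise, 8-segment forward model inside the
optimizer), 200 seeds for the injury-detection power check (expecting
≥90% detection at CV 10%, $n = 3$). The permeability fit optimizes over
$\log k$ in a $10^{\pm3}$ bracket around the template membrane's value;
non-identifiable inputs (no driving gradient, or all-zero observed flows
under a gradient) are flagged rather than returning a spurious optimum.
Degenerate pressure–flow sweeps (flat lines) likewise flag the resistance
as undefined instead of returning an infinite value.

## Known limitations

* The network model is one-dimensional per channel: no lateral pressure
  variation across the 6 mm well width, no entrance effects, no Brinkman
  coupling inside the membrane. Against a full 3-D finite-element solution
  of the same device class, transmembrane flow agreement should be
  expected at the tens-of-percent level, dominated by the unprinted
  membrane and port parameters rather than by discretization.
* Two-phase (air–liquid) flow in the channels is not modeled; the
  breathing protocol's air column is treated only as a pressure command.
* Bi-axial surface strain is not convertible to the linear strains often
  quoted for tissue stretch without an assumed deformation mode; no such
  conversion is provided.
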