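---
title: "Reduced-order design analysis of a hepatic-cord liver-on-chip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order design analysis of a hepatic-cord liver-on-chip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepchip)
```

## Scope and philosophy

`hepchip` models a multiplexed liver-on-chip in which two series of 20
culture chambers (38 µm wide, 25 or 40 µm high) flank a perfused medium
channel, communicating through arrays of 2×2 or 5×3.5 µm slits. The
package replaces a 3D finite-element treatment with two deliberately
reduced models — a lumped resistor network for the flow and a
depth-averaged 2.5D finite-volume model for oxygen — because every design
question the chip poses (shear ceiling, hypoxia floor, resistor sizing,
slit gating, stack height) is a question about integrated quantities that
these reductions capture, while remaining cheap enough to test
exhaustively and to embed in Monte-Carlo sensitivity loops.

## Hydraulic model

At the chip's scales (velocities ≲ mm/s, features of tens of µm) the
Reynolds number is far below one. Creeping flow is linear, so every duct
is fully characterised by its hydraulic resistance and the chip by a
resistor graph: per chamber series, medium and cell channels are
discretised into per-chamber segments, and each chamber contributes the
series path *slit array → chamber duct → slit array* between the two
channels. Four port nodes carry the boundary conditions; the standard
perfusion condition imposes a flow at the medium inlet and 0 Pa gauge at
the three other ports. Nodal analysis yields a sparse symmetric system
solved directly; conservation at interior nodes holds to ~1e-15 of the
inlet flow, and the suite cross-checks the solver against an
independently assembled dense solve on random graphs.

Rectangular-duct resistances use the exact Fourier-series solution. The
common one-term closed form `12 µL/(w h³ (1 − 0.63 h/w))` is kept as an
option: it is within 0.3% of the series for aspect ratios `h/w ≤ 0.5` but
overestimates a square duct by ~14%, which matters here because the slits
are square. Slit arrays are lumped as identical parallel ducts with no
entrance/exit losses (justified at Re ≪ 1); the discontinuous 90°
anti-migration slit is three rectangular ducts in series, the central
3×2 µm channel taking one third of the path length — at creeping flow
only the resistances matter, not the corners.

**Shear at cell positions.** Shear is reported per chamber at two
candidate locations: the chamber floor (parallel-plate estimate
`6 µQ/(w h²)` on the chamber cross-section) and the slit mouths (same
estimate per slit). In every physically plausible layout the slit-mouth
value dominates by orders of magnitude — the chamber through-flow is
micro-litre-scale pressure leakage spread over a 38×40 µm duct, while the
same flow squeezes through eight 2×2 µm slits. The binding constraint
`tau_cell = max(chamber, slit)` therefore sits at the slit mouths, where
cells press against the array; with the shipped 40-2 layout the 0.5 Pa
hepatocyte ceiling is reached at ≈ 9.56 µl/min. The free-channel shear at
that flow is ≈ 4 Pa, which is exactly why the chamber-and-slit
architecture exists: the cells never see it.

**Layout calibration.** The published device description fixes chamber
width/height, slit cross-sections and one slit length, but not the
channel widths, the chamber pitch, the chamber length or the slit count.
These are configuration fields with defaults; the medium-channel width
(260 µm) and per-chamber pitch (100 µm) were chosen once, by a scan over
round values within fabrication-plausible bounds
(`scripts/calibrate_preset.R`), so that the 40-2 preset's shear-limited
maximum flow lands at the device's design value of 9.5 µl/min (it lands
at 9.56, +0.65%). The calibration is frozen in the preset and auditable
by re-running the script; it is not adjusted anywhere else.

## Oxygen model

The steady, depth-averaged balance on a structured grid covering one
chamber series (medium channel, slit strip, chambers) is

> ∇·(h D ∇c) − ∇·(h **u** c) − ρ q c/(K_m + c) + k (c_amb − c) = 0

with `h` the local conveyance height, `ρ` the hepatocyte surface density,
`q = 5e-17 mol/s/cell` the per-cell consumption, and
`k = K D_pdms / t_pdms` the PDMS ceiling transfer coefficient. The
partition coefficient `K` scales the membrane *permeability*; writing the
driving force as `K·c_amb − c` instead would equilibrate above
saturation, which is unphysical. Defaults: `D_medium = 3e-9 m²/s`,
`D_pdms = 3.4e-9 m²/s`, `K = 10`, `t_pdms = 5 mm`, `c_sat = c_amb =
0.2 mol/m³`. `K_m` is not printed in the device description; the default
0.005 mol/m³ is the order of literature values for hepatocytes, and the
design conclusions are insensitive across a 10× range (the PDMS-supplied
steady state sits at 0.07–0.09 mol/m³, an order of magnitude above any
plausible `K_m`).

Numerics: cell-centred finite volumes; harmonic-mean interface
diffusivities (so the high-contrast medium/slit/chamber junctions are
resolved exactly in the 1D limit); first-order upwind convection on a
face-flux field copied conservatively from the network solution (per-cell
divergence ~1e-16); partially walled mouth columns treated as porous with
their exact open fraction, which makes the chamber footprint, ceiling
area and seeded-cell total resolution-independent — grid refinement from
8 µm to 1 µm moves the chamber minimum by < 0.3%. The saturable uptake is
solved by Newton iteration with its diagonal Jacobian
`ρ q K_m/(K_m + c)²`, damped to the physical range; four iterations reach
a 1e-8 relative update at the 2 µm acceptance resolution, and the
converged field closes the global mass balance to ~1e-12. The monotone
discretisation keeps `0 ≤ c ≤ c_sat` with no upwinding overshoot.
Validation is against closed forms: the parabolic zero-order slab
(`c ≫ K_m`) and the cosh first-order slab (`c ≪ K_m`), both matched to
well under the 2% target.

**Budget versus field.** `oxygen_budget()` is the whole-device
supply/demand ratio `(Q c_sat + A k c_amb)/(N q)`; at the 375 nl/min
operating point with 4000 cells the convective term alone gives 6.25.
`min_flow_for_oxygen()` defaults to inverting this budget because the
spatially resolved model shows the chambers are fed almost exclusively by
PDMS permeation and slit diffusion — their convective through-flow is
~10⁻⁴ of the inlet flow — so the chamber minimum is nearly independent of
perfusion rate, and a flow threshold is only meaningful in the well-mixed
budget sense. With permeation on, the budget (and the solver) give
`q_min = 0`: the chip keeps its cells oxygenated at arbitrarily low flow,
the finding that motivated choosing a gas-permeable chip body. The solver
path remains available (`method = "solver"`) and is exercised in the
suite.

## Design rules

Two cell-scale estimators close the geometry questions. Stack height is
`floor(h_chamber/(k·d))` with `d = 17 µm` the cell diameter; the
compaction factor `k = 0.7` is a fitted design constant — the single
value consistent with both observed configurations (2-cell stacks at
25 µm, 3-cell stacks at 40 µm). Slit gating uses the nuclear-deformation
rule: migration is blocked when the slit cross-section is below 10% of
the nuclear cross-section; with an 80 µm² nucleus the 2×2 µm slit (ratio
0.05) blocks and the 5×3.5 µm slit (0.219) does not.

## Capillary resistor

Pressure disturbances from handling (modelled quasi-statically as a
hydrostatic step `ρ g Δh` at the syringe, default 10 cm ≈ 974 Pa) drive
flow through the chambers and strip the cells. The external capillary
tube adds `128 µL/(π d⁴)` in series; the four catalogue options are
strictly ordered, (50 µm, 10 cm) < (50, 20) < (25, 10) < (25, 20), the
stiffest exceeding 1.4e16 Pa·s/m³. `select_capillary()` takes the least
resistive tube meeting the disturbance budget, which defaults to the
chamber through-flow at normal 375 nl/min operation — a disturbance
should not exceed nominal perfusion. With the (25 µm, 20 cm) tube the
induced chamber flow falls more than four orders of magnitude below the
bare-chip value.

## Synthetic data

`draw_occupancy()` emulates per-chamber live-cell counts from the only
published summaries, mean ± SD of 69 ± 26 (proliferative loading) and
52 ± 23 (differentiated loading), as a zero-truncated Normal rounded to
integers. Truncation is by censoring — negative draws become empty
chambers — because the conditional (rejection) reading biases the
differentiated mean by +0.7 cells, more than the two-standard-error
recovery band the generator is held to; censoring bias is below 0.1
cells, and the closed-form censored-parent mean is exported as the test
oracle. Counts are drawn independently across chambers: loading-order
correlations are unknown and not modelled. The generator reproduces the
summaries, not real data's features — no spatial gradients along the
series, no aggregate morphology, no viability dynamics — so passing tests
establish the pipeline's arithmetic under realistic magnitudes, not
biological fidelity.

`draw_perturbations()` provides seeded log-normal multipliers (median 1)
for viscosity, diffusivity, metabolism and channel width; default
dispersions 0.05 for fabrication/fluid quantities, 0.1 for diffusivity,
0.2 for the biological rates. `run_sensitivity()` re-runs the window per
draw and flags row-level failures without aborting the sweep.

## Degenerate inputs and tie-breaks

Zero imposed flow yields exactly zero shear everywhere; zero cells make
every oxygen criterion trivially satisfied (`q_min = 0`, budget ratio
infinite). Networks with floating subgraphs are rejected naming the
disconnected nodes; a missing capillary edge in the disturbance analysis
is an error, because an unprotected chip is precisely the observed
failure mode. Capillary ties at equal resistance break toward the
shorter tube. The peak chamber shear is the maximum over chambers of
`tau_cell`, reported per chamber for audit.

## Problem sizes

The shipped analyses use the full 2×20-chamber network (164 nodes, 204
edges — solved in milliseconds) and, for the oxygen field, one series
rasterised at 2 µm for the acceptance run (~167,000 unknowns, tens of
seconds) with routine tests on 2–3-chamber sections at 4–8 µm, where grid
convergence is demonstrated.

## Known limitations

The parallel-plate shear estimate ignores the 3D recirculation and corner
flows a full CFD model resolves; accuracy claims are calibrated
accordingly, and the ±20% band on the shear-limited flow reflects both
this reduction and the unprinted layout dimensions. The oxygen model is
steady (no transients, no CO₂/pH coupling, no growth or death feedback),
treats the cell-channel side of each chamber as a pure outflow, and
collapses the PDMS slab to a membrane — the lateral spreading resistance
of the bulk slab is neglected, which overestimates permeation somewhat
for thick slabs. Disturbances are quasi-static: tubing compliance and
inertia are out of scope. None of these affect the ordering of the design
conclusions the package exists to compute.
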