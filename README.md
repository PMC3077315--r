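# cvmr

Control-volume estimation of pressure-differential waveforms from
through-plane phase-contrast MR (PC-MR) velocity images.

## The problem

Pressure differences driving cerebrospinal-fluid flow (for example the
transmantle pressure in hydrocephalus) are of order tens of pascals —
below the resolution of implantable sensors and clinically inaccessible.
PC-MR imaging, however, measures fluid velocity non-invasively. `cvmr`
implements a momentum-conservation route from velocity images to pressure:
for a fixed control volume (CV), Newton's second law for the fluid reads

```
d/dt ∫_CV ρ u dV  +  ∮_CS ρ u (u·n̂) dS  =  F_body + F_pressure + F_viscous
```

For a short conduit CV with pulsatile flow at high Womersley number
(α = (D/2)√(ω/ν) ≫ 2.5), the momentum in/outflow nominally cancels, the
viscous drag is small against the oscillating fluid column's inertia, and
a horizontal static CV has no axial body force — so the pressure force on
the CV reduces to the inertial force,

```
F_P(t) ≈ F_I(t) = ρ L dQ/dt ,
```

with Q(t) the volume-flow waveform obtained by summing through-plane
velocities over a segmented region of interest (ROI): Q^k = Σ_i v_i^k S_pixel.
The package provides every term of the budget (inertial, momentum inflow,
viscous, body, pressure), the Urchuk–Plewes per-pixel Navier–Stokes
comparator (−dp/dz = ρ ∂v/∂t − μ∇²v, averaged over interior ROI pixels),
noise propagation, and the exact Womersley solution for oscillatory pipe
flow as analytic ground truth — so the whole chain is testable without a
scanner: a synthetic phantom generator renders the Womersley flow onto
pixel grids (0.2 cm pixels, V_enc 5–20 cm/s, 11–17 phases, 1 Hz, SNR ≈ 25,
46 mL/min sinusoidal flow in a 1.27 cm passage; Re = 77, α = 15.9) with
calibrated velocity noise (σ_v = √2 V_enc/(π SNR)), phase wrapping, and an
emulated differential-pressure sensor.

Intended users: MR-flow and CSF-dynamics researchers validating
image-derived pressure estimates, and developers of PC-MR post-processing
pipelines who need a controllable in-silico phantom.

## Worked example

The full synthetic pipeline — simulate (SNR 25, seeded), segment at the
0.60 magnitude threshold, analyze, compare against the analytic Womersley
pressure force:

```r
library(cvmr)
p <- run_phantom_pipeline(seed = 7, snr = 25)
p$mask
#> <roi_mask: N = 32 pixels, area 1.28 cm^2, 16 perimeter pixels>
p$budget
#> <momentum_budget (simplified, central):
#>   flow amplitude            45.9 mL/min
#>   inertial force            22.4 dyne
#>   momentum inflow          0.287 dyne
#>   viscous force            0.322 dyne
#>   pressure force (CV)       22.4 dyne
#>   pressure gradient        0.464 Pa/cm>
p$comparison$percent
#> [1] 11.08368
```

Reading the numbers: the corner-aligned 1.27 cm lumen covers 32 pixel
centers on the 0.2 cm grid (area 1.28 cm², vs the true 1.267 cm² cross
section). The sinusoid fit of the pixel-sum flow waveform recovers the
46 mL/min drive to within a few percent. The momentum-term hierarchy is as
the physics dictates at α ≈ 16: momentum inflow and viscous drag are two
orders of magnitude below the inertial force, so the simplified balance
F_P = F_I is justified, and the derived pressure force deviates from the
exact analytic pressure force by 11% rms (normalized by the reference
range) — noise and discretization included. The propagated flow
uncertainty for this acquisition is σ_Q = 0.0815 cm³/s (4.9 mL/min).

A command-line interface wraps the same functions:

```sh
exec/cvmr simulate --out /tmp/phantom --seed 3
exec/cvmr segment  --series /tmp/phantom --out /tmp/phantom
exec/cvmr analyze  --series /tmp/phantom --mask /tmp/phantom_mask.nii --out /tmp/phantom --snr 25
```

Series are exchanged as 4D NIfTI-1 (+ JSON sidecar), masks as 0/1 NIfTI,
waveforms as CSV, budget reports as JSON.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package, the in-lumen pixel counts of the 1.27 cm lumen on the 0.2 cm grid
(corner- and center-aligned renderings segmented at the 0.60 threshold)
and the cycle-averaged relative error of the pixel-summed flow waveform
against the analytic Womersley flow at α = 16 for the centered 37-pixel
ROI, writing them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

See `vignettes/control-volume-pcmr.Rmd` for the model, estimator
conventions, numerical choices and known limitations.
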