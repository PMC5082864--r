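# capflux

Blood flow and oxygen transfer in feto-placental capillaries.

In the placenta, oxygen diffuses from maternal blood through villous
tissue into the capillaries of terminal villi, where fetal hemoglobin
carries it away. `capflux` is an R package for quantifying that transfer
in a single capillary, for physiologists and modellers who have capillary
morphometry (lengths, radii, villous distances, vascular resistances) or
skeleton radius profiles and want transfer rates, regime diagnoses, and
the effect of localized capillary dilations (sinusoids) on oxygen uptake.

## What it computes

**Reduced-order model.** With the oxygen–hemoglobin dissociation curve
linearized through the origin (slope *K* = 0.019 mmHg⁻¹), binding
amplifies advection by a constant factor *B* = 1 + c_max·K·k_hn/ρ_bl ≈ 141,
and the transfer rate *N* through a capillary of length *L*, radius *R₀*
and resistance *R* = 8μL/(πR₀⁴) follows three regimes in the effective
Péclet number Pe_eff = B·u₀·R₀/D:

- boundary-layer (Graetz–Lévêque): *N* ≈ α·c_mat·(D²·B·ΔP·L²/R)^(1/3),
  α = (12π²)^(1/3)/Γ(4/3) ≈ 5.5;
- equilibrated: *N* ≈ c_mat·B·ΔP/R;
- diffusion-limited bound: *N*_max ≈ D·A·c_mat / (R₀·ln(1 + d/R₀)) for a
  villous tissue annulus of thickness *d* and capillary surface area *A*.

A regression formula *N* = K₁K₂ΔP/(K₂ + K₁ΔP^(2/3)) bridges the
flow-limited regimes, and *N* = N_flow/(1 + N_flow/N_max) folds in the
villous correction.

**Axisymmetric simulator.** A finite-element solver (Taylor–Hood Stokes +
SUPG-stabilized advection–diffusion, written in R on `Matrix` sparse
algebra) computes flow and oxygen fields in a capillary whose wall radius
R(z) has a localized dilation described by a constrained Fourier series,
with oxygen supplied along the dilated section at fixed pressure drop.

**Shape optimizer.** Multistart L-BFGS-B with finite-difference gradients
over the nested symmetric shape families finds the dilation maximizing
*N* at fixed ΔP; at physiological conditions the optimal dilation carries
about 15% more oxygen than a straight capillary.

**Profile analysis.** Measures dilation length λ, undilated radius R₀ and
maximum radius R_max from skeleton radius-vs-arclength profiles, by
either of the two endpoint conventions in use (flanking local minima, or
crossings of the branch-average radius).

## Worked example

```r
library(capflux)
tp <- transport_params()      # D = 1700 um^2/s, B = 141, c_mat = 2.24 g/m^3

# transfer predictions for three imaged villous branches at dP = 0.5 Pa
preds <- predict_transfer(table3_fixture(), tp, dP = 0.5)
preds[, c("label", "R0", "N_corrected", "N_ratio", "regime")]
#>     label   R0 N_corrected N_ratio               regime
#> 1 Image 1 4.68    2.30e-07   0.928 flow_limited_leveque
#> 2 Image 2 6.09    3.31e-07   0.950            crossover
#> 3 Image 3 4.73    3.67e-07   0.864            crossover
```

At this low pressure drop the corrected transfer sits close to the
flow-limited value (N_ratio near 1): tissue diffusion barely limits
uptake, and the branch with the least resistance per unit length
(Image 3) receives the most oxygen.

```r
# simulate the measured dilation (R0 = 4.7 um, R_max = 6.8 um, lam = 31 um)
sh <- bump_shape(R0 = 4.7, R_max = 6.8, lam = 31, L = 76)
sol <- simulate_dilation(sh, tp)   # dP calibrated to 300 um/s centreline
sol
#> Axisymmetric field solution
#>   dP = 4.12856 Pa, Q = 12804.4 um^3/s, resistance = 0.000322434 Pa s/um^3
#>   mass balance error 1.28e-15
#>   N = 1.63438e-06 ug/s (flux balance error 0.000241)
```

The dilation lowers the resistance (a straight tube of this radius has
R = 3.3e-4 · 76/45 ≈ 5.5e-4 Pa s/um³ over the same length) and transfers
9.5% more oxygen than the straight capillary at the same pressure drop.
Optimizing the shape (`optimize_dilation()`, `dof_continuation()`) pushes
the gain to about 15%.

```r
# measure a dilation in a noisy skeleton profile
prof <- make_bump_profile(4.7, 6.8, 31, 76, ds = 0.5,
                          noise_sigma = 0.1, seed = 1)
measure_dilation(prof, "average_crossing")
#> Dilation (average_crossing): lam = 21.71 um on [27.01, 48.71] um
#>   R0 = 5.131 um, R_max = 6.824 um (smoothing window 3 um)
```

A command-line interface (`inst/exec/capflux`) exposes the same pipeline
as `predict`, `simulate`, `optimize`, `measure` and `fixtures`
subcommands, persisting each run's effective configuration for
reproducibility.

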