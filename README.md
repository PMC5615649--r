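# vesselgrow

Growth and remodeling of the arterial wall as a constrained mixture, with
selectable volumetric-growth kinematics, applied to the evolution of
abdominal aortic aneurysms (AAA).

## The problem

Vascular tissue continuously turns over its load-bearing constituents and
seems to adapt toward stable homeostatic mechanical conditions; failure to
reach homeostasis underlies pathologies such as aneurysm disease.  Models
of this adaptation must decide (a) how deposited mass changes constituent
volume and (b) how a scalar tissue volume change becomes a growth
*tensor* — and both choices are experimentally unconstrained.  This
package implements a layered, structurally motivated wall model in which
those two choices are explicit switches, so their consequences for
predicted aneurysm evolution can be explored systematically.  It is aimed
at researchers in vascular biomechanics and tissue growth and remodeling.

## The model in brief

* **Constrained mixture.**  Elastin, ground matrix and two helical
  collagen fiber families coexist at every point and deform together.
  Deposition preserves either constituent density (CCD, volume follows
  mass) or constituent volume (CCV, density follows mass); the normalized
  tissue volume change is
  `v̂ = Σ_CCD m̂ζ φζ(0) + Σ_CCV φζ(0)`.
* **Growth kinematics.**  `F = Fe·Fg` with `det Fg = v̂`; the mapping of
  `v̂` into `Fg` is isotropic (IVG), in-plane (PVG), in-thickness (TVG) or
  isochoric (NVG).
* **Wall constitution.**  Quasi-incompressible hyperelasticity:
  neo-Hookean elastin and ground matrix, exponential collagen fibers that
  engage beyond a recruitment stretch `λ̄r` (clamped invariant
  `Ī4c = max(Ī4/λ̄r², 1)`), weighted by normalized partial densities.
* **Turnover.**  Collagen remodels in response to the stimulus
  `ξ = (Ī4c − Ī4a)/(Ī4a − 1)` about the attachment stretch
  `λ̄a` (`∂λ̄r/∂τ = αξ`, `∂m̂c/∂τ = βm̂cξ`); elastin loss is prescribed,
  localized at the vessel center:
  `m̂e(z,τ) = 1 − (1 − c_min^{τ/T})·exp(−m1(2z/L−1)²)`.
* **Geometry.**  A closed-form equi-biaxial patch (the analytic
  laboratory) and a reduced thick-walled two-layer cylinder of the
  infrarenal aorta: 30 independent axial stations, exact-incompressibility
  inflation solves, two-phase protocol (homeostasis, then aneurysm
  growth).

See `vignettes/growth-kinematics-aaa.Rmd` for the full account, including
numerical choices and known limitations of the reduced geometry.

## Worked example

```r
library(vesselgrow)

cal <- calibrate_fiber_angle()     # fiber angle from the homeostatic diameter
ves <- build_vessel(n_axial = 30, gamma = cal$gamma, kind = "TVG")
ves <- homeostasis_solve(ves)
c(d0 = ves$d0, h0 = ves$h0)
#>     d0      h0
#> 23.000   1.135

rec <- grow(ves, dtau = 0.01, tau_end = 10)   # baseline beta = 1.0/yr
tail(rec$series[, c("tau", "di", "d_hat", "h_mid", "lambda_c_A",
                    "m_hat_c_A", "v_hat_A")], 3)
#>        tau      di  d_hat  h_mid lambda_c_A m_hat_c_A v_hat_A
#> 999   9.98 47.5992 2.0695 0.7106     1.1157    3.0554  1.3083
#> 1000  9.99 47.6504 2.0718 0.7103     1.1157    3.0632  1.3095
#> 1001 10.00 47.7016 2.0740 0.7101     1.1158    3.0711  1.3107
```

The calibration puts the collagen families at 49.3° to the circumferential
direction, which sets the homeostatic loaded inner diameter to 23 mm at a
wall thickness of 1.135 mm.  Over ten years of simulated elastin loss and
collagen turnover the mid-vessel diameter grows to 47.7 mm (normalized
expansion `d_hat` = 2.07), the wall thins to 0.71 mm, collagen mass at the
inner wall triples (`m_hat_c` = 3.07) while its stretch stays close to the
attachment value 1.093, and the local tissue volume grows by 31%.
`measure(rec)` reports a peak growth rate of 5.0 mm/yr and normalized
expansion 1.5 reached after 7.0 years.

Parameter studies (`run_study(study_spec("study1"))`) sweep the collagen
net-growth rate over all four kinematics; the signature result is a sign
flip: raising collagen production *slows* expansion under TVG/NVG but
*accelerates* it under IVG/PVG.

A thin command-line wrapper ships at `inst/cli/vesselgrow`
(`patch`, `homeostasis`, `grow`, `study1`, `study2` subcommands; YAML
config, CSV + JSON-manifest outputs; baseline config at
`inst/extdata/baseline.yaml`).

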