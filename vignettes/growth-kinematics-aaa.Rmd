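---
title: "Growth kinematics and constrained-mixture remodeling of the aneurysmal aorta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth kinematics and constrained-mixture remodeling of the aneurysmal aorta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselgrow)
```

## The model

`vesselgrow` simulates growth and remodeling (G&R) of the arterial wall as a
*constrained mixture*: elastin, ground matrix and two helical collagen fiber
families coexist at every material point and deform affinely with the
tissue.  Two time scales are separated by a multiplicative split of the
deformation gradient,

$$ F(\tau, t) = F_e(t)\, F_g(\tau), \qquad \det F_g = \hat v(\tau), $$

where the growth tensor $F_g$ carries the slow (years) change of stress-free
volume and the elastic part $F_e$ carries the fast, quasi-incompressible
response to pressure and axial pre-stretch.

### Deposition rules and tissue volume change

Mass turnover may preserve a constituent's *density* (CCD: volume follows
mass, $\hat v_\zeta = \hat m_\zeta$) or its *volume* (CCV: density follows
mass, $\hat v_\zeta = 1$).  The normalized tissue volume change is the
initial-fraction-weighted sum

$$ \hat v(\tau) = \sum_{\zeta \in \mathrm{CCD}} \hat m_\zeta(\tau)\,
   \phi_\zeta(0) + \sum_{\zeta \in \mathrm{CCV}} \phi_\zeta(0), $$

and normalized partial densities $\hat\rho_\zeta = \hat m_\zeta / \hat v$
weight the constituent strain energies.  Fractions are per layer and must
sum to one; when a study overrides one initial fraction the ground matrix
absorbs the complement, since it is the residual constituent by
construction.  (The baseline adventitial fractions as published sum to
1.01; the shipped baseline keeps the collagen fractions and sets the
adventitial ground fraction to 0.85.)

### Growth kinematics

How the scalar $\hat v$ maps into the tensor $F_g$ is not experimentally
constrained, so four idealized kinematics are provided, all of the
transversely isotropic family $F_g = \alpha I + \beta\, n \otimes n$ about
the wall normal $n$:

| kind | $F_g$ | reading |
|------|-------|---------|
| IVG | $\hat v^{1/3} I$ | isotropic deposition |
| PVG | $\hat v^{1/2} I + (1 - \hat v^{1/2})\, n \otimes n$ | in-plane (tangential) deposition |
| TVG | $I + (\hat v - 1)\, n \otimes n$ | in-thickness deposition |
| NVG | $I$ | isochoric reference case (requires all-CCV) |

These $(\alpha, \beta)$ growth coefficients are internal to
`growth_tensor()` and deliberately share no namespace with the remodeling
rates $\alpha, \beta$ below.

### Wall constitution

The wall is quasi-incompressible and hyperelastic with a
volumetric/isochoric split,

$$ \Psi = \tfrac{\kappa}{2}(J_e - 1)^2
   + \hat\rho_e \tfrac{\mu_e}{2}(\bar I_1 - 3)
   + \hat\rho_g \tfrac{\mu_g}{2}(\bar I_1 - 3)
   + \sum_{i=1,2} \hat\rho_{ci} \tfrac{k_1}{2 k_2}
     \left[ e^{k_2 (\bar I_4^{ci} - 1)^2} - 1 \right], $$

with neo-Hookean elastin and ground matrix and exponential collagen
fibers.  Collagen is undulated: a fiber engages only beyond its
*recruitment stretch* $\bar\lambda_r$, through the clamped invariant
$\bar I_4^c = \max(\bar I_4 / \bar\lambda_r^2, 1)$, and carries no
compressive or bending load.  The adventitia holds no elastin.  Both an
exact-incompressibility mode (hydrostatic pressure supplied by the
equilibrium solver) and a penalty mode ($p_h = \kappa (J_e - 1)$) are
implemented; the vessel solver defaults to exact incompressibility for
robustness (see *The penalty bulk modulus* below).

### Collagen turnover and elastin loss

Collagen is deposited at an *attachment stretch* $\bar\lambda_a$; the gap
between the current fiber stretch and the attachment stretch drives
turnover through the stimulus

$$ \xi = \frac{\bar I_4^c - \bar I_4^a}{\bar I_4^a - 1},
   \qquad \bar I_4^a = \bar\lambda_a^2, $$

and the rate equations
$\partial \bar\lambda_r / \partial\tau = \alpha\,\xi$,
$\partial \hat m_c / \partial\tau = \beta\, \hat m_c\, \xi$.
A flattened typesetting of the stimulus admits the alternative reading
$\xi = \bar I_4^c / \bar I_4^a - 1$; the difference form above is adopted
(consistent with the normalization of the recruitment literature) and the
ratio form is kept behind `stimulus_form = "ratio"` for sensitivity
checks.  $\xi$ is computed from the clamped $\bar I_4^c$, so a fully slack
fiber atrophies at the maximal rate $\xi = -1$.  The recruitment stretch
is floored at one — a value below one has no physical reading in the
recruitment picture.

Aneurysm onset is driven by prescribed elastin loss, localized at the
vessel center and deepening in time:

$$ \hat m_e(z, \tau) = 1 - \left(1 - c_{min}^{\tau/T}\right)
   e^{-m_1 (2 z / L - 1)^2}, $$

so that $\hat m_e = c_{min}$ at $z = L/2$, $\tau = T$, and decay continues
for $\tau > T$.

## Parameters

Units are mm, kPa and years throughout.  The shipped baseline
(`inst/extdata/baseline.yaml`, also `default_config()`): inner radius
$R_i = 8.4$, media thickness $H_M = 1.18$, adventitia $H_A = 0.59$, length
$L = 147.4$, pressure $p_i = 16$, axial pre-stretch $\lambda_z = 1.2$;
$\mu_e = 133.81$ (media only), $\mu_g = 33.45$, $k_1 = 3.52$, $k_2 = 40$,
$\kappa = 100$; medial fractions $\phi_e = 0.12$, $\phi_g = 0.73$,
$\phi_{ci} = 0.075$ per family; $\alpha = 0.6$, $\beta = 1.0$,
$\bar\lambda_a = 1.093$, $\lambda_{rec,0} = 1.13$, $c_{min} = 0.6$,
$T = 10$, $m_1 = 20$.

**The collagen fiber angle** $\gamma$ (to the circumferential direction)
is absent from the baseline set, yet the homeostatic diameter depends on
it.  `calibrate_fiber_angle()` root-finds the angle at which the phase-1
loaded inner diameter equals its target (23 mm by default); at the
baseline this gives $\gamma \approx 49.3^\circ$ and a loaded thickness of
1.135 mm in exact-incompressibility mode.  The calibrated angle is then
held fixed across all studies.

## The reduced vessel model

The full-field problem this package reduces is a 3-D axisymmetric
finite-element model.  Here the infrarenal aorta is an array of
independent thick-walled two-layer ring sections at axial stations
$z \in [L/2, L]$ (distal–proximal symmetry; 30 stations by default, with
4 Gauss–Legendre points per layer), all at a fixed axial pre-stretch.
With exact incompressibility the radial map is

$$ r(R)^2 = r_i^2 + \frac{2}{\lambda_z} \int_{R_i}^{R} \hat v(\rho)\,
   \rho \, d\rho, $$

and the inner radius follows from radial equilibrium
$\mathrm{d}\sigma_{rr}/\mathrm{d}r = (\sigma_{\theta\theta} -
\sigma_{rr})/r$ with $\sigma_{rr}(r_i) = -p_i$ and $\sigma_{rr}(r_o) = 0$,
solved by a warm-started Newton iteration on $r_i$ (vectorized across
sections, with a bracketed-root fallback).  The cumulative volume integral
uses a piecewise-linear reconstruction of $\hat v(R)$ between the
quadrature nodes, exact in $\rho$.

**Two-phase protocol.**  Phase 1 (homeostasis): masses fixed, the
recruitment stretch develops until the collagen stretch is spatially
uniform and equal to $\bar\lambda_a$.  Because that end state is fully
characterized by $\bar\lambda_c \equiv \bar\lambda_a$, the solver imposes
this closure directly in the stress, finds the equilibrium geometry in a
single root solve, backs out $\bar\lambda_r = \sqrt{\bar I_4} /
\bar\lambda_a$, and verifies the fixed point with a plain equilibrium
re-solve (the recruitment field then reproduces
$|\bar\lambda_c - \bar\lambda_a| < 10^{-6}$).  This is both faster and
more robust than pseudo-time stepping of the recruitment rate equation:
in penalty mode the literal alternation of equilibrium solves and
recruitment updates diverges, because each update chases the dilation of
the volumetrically compliant wall.  Phase 2 (growth): remodeling time is
reset, elastin degrades by the prescribed law, and each step evaluates the
stimulus at the previously equilibrated state, advances
$(\bar\lambda_r, \hat m_c)$ by forward Euler, recomputes $\hat v$ and
$F_g$ (wall normal = radial direction), and re-equilibrates.  If a solve
fails the step is retried with up to four halvings of $\Delta\tau$ before
the run is truncated with an explicit status.

**Numerical choices.**  Default $\Delta\tau = 0.01$ yr (rates are
$O(1)$/yr and trajectories smooth; first-order convergence is tested, not
assumed, with observed order $\ge 0.9$).  Equilibrium tolerance $10^{-9}$
kPa on the outer traction; homeostasis tolerance $10^{-6}$ on the collagen
stretch; quadrature refinement from 4 to 8 points per layer moves the
baseline solved radius by less than $10^{-4}$ mm.  Measurements: "point A"
is the inner-wall quadrature point of the mid-vessel section, the diameter
is twice the mid-vessel inner radius, the growth rate is a centered
1-year finite difference, and the total volume change integrates $\hat v$
over all reference material volume.  Studies terminate at fourfold
diameter expansion, mirroring the termination of the full-field model
once the aneurysm reached about four times its initial diameter.

## The equi-biaxial patch laboratory

For a single-constituent neo-Hookean patch under equi-biaxial stretch
$\lambda$ the first Piola–Kirchhoff stress has closed forms per kinematics
kind,

$$ P_{IVG} = \hat\rho\, \hat v^{1/3} \mu (\lambda - \hat v^2 \lambda^{-5}),
   \quad
   P_{PVG} = \hat\rho\, \mu (\lambda - \hat v^3 \lambda^{-5}),
   \quad
   P_{TVG} = \hat\rho\, \hat v\, \mu (\lambda - \lambda^{-5}), $$

which the test suite verifies against the generic
growth-tensor/constitutive pipeline on random states to $10^{-8}$
relative.  The patch makes the qualitative signatures of the kinematics
visible analytically: PVG moves the stress-free edge length
($P = 0$ at $\lambda = \hat v^{1/2}$), TVG only rescales the stress
(slope $\propto \hat m$), IVG mixes both.

```{r patch}
head(patch_curves(kinds = "TVG", v_hat_list = c(0.5, 1, 1.5),
                  lam_grid = c(1, 1.5, 2)))
```

## What a run looks like

```{r run, eval = FALSE}
cal <- calibrate_fiber_angle()               # gamma ~ 49.3 deg, d = 23 mm
ves <- build_vessel(n_axial = 30, gamma = cal$gamma, kind = "TVG")
ves <- homeostasis_solve(ves)                # d0 = 23.000, h0 = 1.135 mm
rec <- grow(ves, dtau = 0.01, tau_end = 10)
measure(rec)                                 # rates, crossing times, maxima
```

The two shipped studies (`run_study(study_spec("study1"))`, `"study2"`)
sweep the collagen net-growth rate $\beta \in \{0.75, 1.0, 1.25\}$/yr over
all four kinematics, and the initial elastin ($\phi_e \in \{0.12, 0.18\}$,
elastin CCD) and per-family medial collagen
($\phi_{ci} \in \{0.075, 0.15\}$, collagen CCD) fractions.  A collagen
sweep value of 0.75 *per family* would make the fractions exceed one and
is interpreted as 0.075 (the study driver and its manifest flag this).
The qualitative signatures the test suite asserts: TVG and NVG expand
almost identically; raising $\beta$ slows expansion under TVG/NVG but
accelerates it under IVG/PVG; at twofold expansion the collagen stretch
orders PVG > IVG > TVG $\approx$ NVG while the local volume change orders
inversely (TVG largest); NVG conserves total volume to $10^{-8}$.

## Design decisions and known limitations

**Quasi-1D reduction.**  Sections evolve independently under the local
$\hat m_e(z, \tau)$ with $\lambda_z$ fixed at 1.2 everywhere.  Axial
bending and coupling, sac lengthening, and the folding/buckling of the
non-aneurysmal segment are not representable.  The main quantitative
consequence: the full-field model develops large axial stretch at the
aneurysm apex, which thins the wall there; at fixed $\lambda_z$ the
thickness at a given diameter is kinematically bounded below by
$\approx H \hat v / (\lambda_\theta \lambda_z)$, so the reduced model
overestimates the wall thickness at twofold expansion (it reproduces the
ordering — TVG thicker than NVG — and the expansion timing, but not the
printed thickness values).

**The penalty bulk modulus.**  The baseline $\kappa = 100$ kPa is of the
same order as the shear moduli, i.e. far from quasi-incompressible.  In
this reduced model a homeostatic state with that penalty active does not
exist: with collagen pinned at the attachment stretch the wall is too
volumetrically compliant to carry 16 kPa at any radius (the solver
verifies its penalty path against the exact-incompressibility solution,
which it approaches as $\kappa \to \infty$: the homeostatic diameter moves
35.8 → 25.0 → 23.2 → 23.02 mm for $\kappa = 10^2 \ldots 10^5$ kPa, against
23.000 exact).  The penalty-mode thickness is therefore reported at the
exact-mode homeostatic recruitment field, re-equilibrated with the penalty
active, and exceeds the published loaded thickness; whether the published
value reflects a stiffer effective bulk response is not decidable from the
baseline set alone.  Both modes remain available
(`equilibrium_solve(..., mode = "penalty")`).

**Other simplifications.**  No intraluminal thrombus, no smooth-muscle
active stress, no rupture criterion, no fiber dispersion, a single
deterministic recruitment stretch per point, and a stretch-based (not
stress-based) stimulus — all deliberate scope choices of the underlying
model family.  Passing tests on this reduced geometry demonstrate the
constitutive/growth mechanics and their couplings, not predictive accuracy
for patient-specific aneurysms.
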