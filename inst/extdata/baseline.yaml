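# Baseline parameter set for the abdominal-aorta growth model.
# Units: mm, kPa, years.  Missing keys are filled from the package defaults;
# this file states the full baseline explicitly.
geometry:
  Ri: 8.4          # reference inner radius (mm)
  HM: 1.18         # media-intima thickness (mm)
  HA: 0.59         # adventitia thickness (mm)
  L: 147.4         # artery length (mm)
  lambda_z: 1.2    # axial pre-stretch
  p_i: 16.0        # inner pressure (kPa)
material:
  mu_e: 133.81     # elastin shear modulus (kPa), media only
  mu_g: 33.45      # ground-matrix shear modulus (kPa)
  k1: 3.52         # collagen stiffness parameter (kPa)
  k2: 40.0         # collagen exponential parameter (-)
  kappa: 100.0     # fictitious bulk modulus (kPa), penalty mode
composition:
  media:
    phi_e: 0.12    # elastin initial volume fraction
    phi_c: 0.075   # collagen initial volume fraction, per family
  adventitia:
    phi_c: 0.075
  # ground matrix absorbs the complement so per-layer fractions sum to 1
  rules:
    elastin: CCV
    ground: CCV
    collagen: CCD
remodeling:
  alpha: 0.6         # recruitment remodeling rate (1/year)
  beta: 1.0          # collagen net growth rate (1/year)
  lambda_a: 1.093    # collagen attachment stretch
  lambda_rec0: 1.13  # initial collagen recruitment stretch
  c_min: 0.6         # residual elastin at the vessel center after T
  T: 10              # degradation time (years)
  m1: 20             # axial shape parameter
  stimulus_form: offset
fiber:
  angle_deg: null    # null -> calibrate to target_d0
  target_d0: 23.0    # homeostatic loaded inner diameter (mm)
kinematics: TVG
schedule:
  dtau: 0.01         # remodeling time step (years)
  tau_end: 10.0      # simulated duration (years)
solver:
  n_radial: 4        # Gauss points per layer
  n_axial: 30        # axial stations on [L/2, L]
  mode: exact        # exact | penalty (phase-1)
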