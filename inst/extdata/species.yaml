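# Species registry: timing of neurogenesis (embryonic days), deeper-layer
# neuron fraction, adult neocortical neuron counts, demographic adjustment
# fractions, cell-cycle data (hours) and reference division strategies
# (alpha0, alphaS, betaF, tS) for the constant and age-dependent cell-cycle
# models.  Human cell-cycle values and phi are macaque proxies: no in-vivo
# human progenitor measurements are available.
mouse:
  t0: 11.0
  tF: 19.0
  tM: 17.0
  phi: 0.52
  N_adult: 1.369e+07
  P0_literature: 375000.0
  death_fraction: 0.30
  migration_fraction: 0.25
  Tc_constant: 14.3
  Tc_anchors:
    day: [12.0, 16.0]
    hours: [10.2, 18.4]
  reference_strategy:
    constant: [0.4, 0.5, 0.7, 14.0]
    age_dependent: [0.2, 0.7, 1.0, 16.0]
macaque:
  t0: 40.0
  tF: 100.0
  tM: 64.0
  phi: 0.29
  N_adult: 1.71e+09
  P0_literature: ~
  death_fraction: 0.30
  migration_fraction: 0.25
  Tc_constant: 34.67
  Tc_anchors:
    day: [40.0, 60.0, 80.0]
    hours: [23.0, 54.0, 27.0]
  reference_strategy:
    constant: [0.1, 1.0, 0.7, 65.5]
    age_dependent: [0.5, 0.8, 1.0, 63.5]
human:
  t0: 40.0
  tF: 117.0
  tM: 93.0
  phi: 0.29
  N_adult: 1.634e+10
  P0_literature: ~
  death_fraction: 0.30
  migration_fraction: 0.25
  Tc_constant: 34.67
  Tc_anchors:
    day: [40.0, 60.0, 80.0]
    hours: [23.0, 54.0, 27.0]
  reference_strategy:
    constant: [0.3, 1.0, 0.5, 94.0]
    age_dependent: [0.1, 0.9, 0.8, 92.0]
    age_dependent_tc1.5: [0.4, 0.8, 0.7, 84.5]
    age_dependent_tc2: [0.1, 0.4, 0.7, 56.0]
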