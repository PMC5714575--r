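# Default full-study configuration: three synthetic treatment-type cohorts of
# 10 plans each, evaluated for both algorithm-change presets against every
# applicable registry parameter set.
cohorts:
  - treatment_type: Tang
    change: PB-CC
    n_plans: 10
  - treatment_type: LGL
    change: PB-CC
    n_plans: 10
  - treatment_type: Lung
    change: PB-CC
    n_plans: 10
  - treatment_type: Tang
    change: PBC-AAA
    n_plans: 10
  - treatment_type: LGL
    change: PBC-AAA
    n_plans: 10
  - treatment_type: Lung
    change: PBC-AAA
    n_plans: 10
alpha_beta: 3
reference_dose_per_fraction: 2
se_method: jacobian
seed: 1
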