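# Default treatment-archetype templates and dose-calculation-algorithm effect
# presets for the synthetic cohort generator. Templates encode the
# in-field / penumbra / low-dose-bath structure of each treatment type;
# effects encode how a model-based dose engine reshapes a pencil-beam DVH.
# Effect presets are calibrated with calibrate_effect() so cohort mean
# relative MLD reductions land near 10/9/8 % (Tang/LGL/Lung, PB-CC) and
# 4/4/5 % (PBC-AAA).
templates:
  Tang:
    prescription_dose: 50.0
    n_fractions: 25
    in_field_fraction: 0.10
    penumbra_fraction: 0.10
    in_field_dose: 48.0
    penumbra_width: 4.0
    bath_decay: 2.0
    inter_plan_variability: 0.10
    bin_width: 0.5
    lung_volume: paired
  LGL:
    prescription_dose: 50.0
    n_fractions: 25
    in_field_fraction: 0.18
    penumbra_fraction: 0.14
    in_field_dose: 48.0
    penumbra_width: 4.0
    bath_decay: 3.5
    inter_plan_variability: 0.12
    bin_width: 0.5
    lung_volume: paired
  Lung:
    prescription_dose: 60.0
    n_fractions: 30
    in_field_fraction: 0.25
    penumbra_fraction: 0.15
    in_field_dose: 58.0
    penumbra_width: 5.0
    bath_decay: 5.0
    inter_plan_variability: 0.25
    bin_width: 0.5
    lung_volume: paired
effects:
  PB-CC:
    Tang:
      in_field_dose_scale: 0.88
      penumbra_mass_shift: 0.18
      bath_scale: 1.25
    LGL:
      in_field_dose_scale: 0.90
      penumbra_mass_shift: 0.15
      bath_scale: 1.20
    Lung:
      in_field_dose_scale: 0.92
      penumbra_mass_shift: 0.12
      bath_scale: 1.15
  PBC-AAA:
    Tang:
      in_field_dose_scale: 0.95
      penumbra_mass_shift: 0.08
      bath_scale: 1.12
    LGL:
      in_field_dose_scale: 0.955
      penumbra_mass_shift: 0.07
      bath_scale: 1.10
    Lung:
      in_field_dose_scale: 0.95
      penumbra_mass_shift: 0.08
      bath_scale: 1.10
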