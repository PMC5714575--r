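# Published pencil-beam-era NTCP parameter sets for radiation-induced lung
# complications shipped with ntcprefit. Values as printed in the source
# studies; provenance strings identify the study and endpoint.
- name: seppenwoolde_lkb
  model: LKB
  parameters:
    d50: 30.80
    m: 0.37
    "n": 0.99
  lung_volume: paired
  endpoint: "radiation pneumonitis, SWOG grade 2"
  used_on: [Lung, LGL, Tang]
  provenance: "Seppenwoolde et al., LKB fit to paired-lung DVHs (pencil-beam dose calculation)"
- name: seppenwoolde_rs
  model: RS
  parameters:
    d50: 34.0
    gamma: 0.9
    s: 0.06
  lung_volume: paired
  endpoint: "radiation pneumonitis, SWOG grade 2"
  used_on: [Lung, LGL, Tang]
  provenance: "Seppenwoolde et al., relative seriality fit to paired-lung DVHs"
- name: gagliardi_rs
  model: RS
  parameters:
    d50: 30.1
    gamma: 0.966
    s: 0.012
  lung_volume: ipsilateral
  endpoint: "clinical radiation pneumonitis"
  used_on: [LGL, Tang]
  provenance: "Gagliardi et al., relative seriality fit to ipsilateral-lung DVHs"
- name: rancati_lkb
  model: LKB
  parameters:
    d50: 17.0
    m: 0.33
    "n": 0.91
  lung_volume: ipsilateral
  endpoint: "radiation pneumonitis, grade 1 (modified CTC-NCIC)"
  used_on: [LGL, Tang]
  provenance: "Rancati et al., LKB fit to ipsilateral-lung DVHs, mild endpoint"
- name: rancati_rs
  model: RS
  parameters:
    d50: 17.30
    gamma: 1.07
    s: 0.11
  lung_volume: ipsilateral
  endpoint: "radiation pneumonitis, grade 1 (modified CTC-NCIC)"
  used_on: [LGL, Tang]
  provenance: "Rancati et al., relative seriality fit to ipsilateral-lung DVHs"
- name: dejaeger_lkb_epl
  model: LKB
  parameters:
    d50: 34.10
    m: 0.45
    "n": 1.0
  lung_volume: paired
  endpoint: "radiation pneumonitis, SWOG grade 2"
  used_on: [Lung]
  provenance: "De Jaeger et al., LKB fit, octree/edge algorithm with equivalent-path-length inhomogeneity correction"
- name: dejaeger_lkb_cs
  model: LKB
  parameters:
    d50: 29.20
    m: 0.45
    "n": 1.0
  lung_volume: paired
  endpoint: "radiation pneumonitis, SWOG grade 2"
  used_on: [Lung]
  provenance: "De Jaeger et al., LKB fit, convolution/superposition algorithm"
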