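schema_version: 1
metabolites:
  citrate: 6
  alpha_ketoglutarate: 5
  succinate: 4
  malate: 4
reactions:
- id: citrate_synthase
  source: malate
  product: citrate
  branches:
  - probability: 1.0
    mapping:
    - ACETYL_C1
    - ACETYL_C2
    - M2
    - M3
    - M4
    - M1
    lost: []
- id: isocitrate_dehydrogenase
  source: citrate
  product: alpha_ketoglutarate
  branches:
  - probability: 1.0
    mapping:
    - M5
    - M4
    - M3
    - M2
    - M1
    lost:
    - 6
- id: alpha_ketoglutarate_dehydrogenase
  source: alpha_ketoglutarate
  product: succinate
  branches:
  - probability: 1.0
    mapping:
    - M2
    - M3
    - M4
    - M5
    lost:
    - 1
- id: succinate_to_malate
  source: succinate
  product: malate
  branches:
  - probability: 0.5
    mapping:
    - M1
    - M2
    - M3
    - M4
    lost: []
  - probability: 0.5
    mapping:
    - M4
    - M3
    - M2
    - M1
    lost: []
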