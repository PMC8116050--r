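# Canned parameter tables and assay presets used throughout the package.
# Model parameter values are the published tables verbatim; assay presets
# name the paired subsystem amounts of the standard competition scenarios.
models:
  minimal:
    a: 1
    b: 1
    Dm: 0.01
    Dc: 1
  indirect:
    a: 1
    b: 1
    c: 0.01
    d: 1
    Dm: 0.01
    Dc: 1
    Dvi: 1
  mechanistic:
    k1a: 10
    k1b: 10
    k2a: 0.16
    k2b: 1.75
    k3: 0.35
    k4a: 10
    k4b: 10
    k5a: 36
    k5b: 0.65
    k7: 10
    Dm: 0.0025
    Dc: 10
    eta: 0.01
  mechanistic_nfb:
    k1a: 10
    k1b: 10
    k2a: 0.16
    k2b: 0.35
    k3: 0.35
    k4a: 10
    k4b: 10
    k5a: 36
    k5b: 0.65
    k7: 10
    k8max: 0.0063
    k8n: 6
    k8h: 10
    k9max: 0.0044
    k9n: 6
    k9h: 0.003
    Dm: 0.0025
    Dc: 10
    eta: 0.01
presets:
  minimal_competition_low:
    model: minimal
    amounts: [0.6, 1.0]
    expected: competition
  minimal_coexistence_high:
    model: minimal
    amounts: [2.0, 4.0]
    expected: coexistence
  nfb_competition:
    model: mechanistic_nfb
    amounts: [0.5, 1.0]
    expected: competition
  nfb_equalization:
    model: mechanistic_nfb
    amounts: [1.0, 2.0]
    expected: equalization
  indirect_competition:
    model: indirect
    amounts: [0.6, 0.9]
    expected: competition
  indirect_equalization_mid:
    model: indirect
    amounts: [0.8, 1.2]
    expected: equalization
  indirect_equalization_high:
    model: indirect
    amounts: [1.2, 1.8]
    expected: equalization
  phase_diagram_template:
    model: indirect
    split: [0.4, 0.6]
    Dvi_values: [0.01, 0.1, 1, 10]
    amount_values: [0.5, 0.75, 1, 1.25]
    t_max: 2000
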