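schema: agphot/descriptor/v1
name: Ag10(I)
units:
  energy: eV
  socme: cm^-1
  nacme: a.u.
  frequency: cm^-1
  rate: s^-1
contexts:
  S0-opt:
  - label: T1
    energy: 1.95
  - label: S1
    energy: 2.57
    oscillator_strength: 0.79
  S1-opt:
  - label: T1
    energy: 1.78
  - label: S1
    energy: 2.17
    oscillator_strength: 1.21
socme_s1_t1: 3.68
supplied_rates:
  k_r: 247000000.0
  k_isc: 485000000.0
  k_ic: 1000000.0
reference:
  experimental:
    absorption_s1_ev: 2.53
    emission_s1_ev: 2.17
    qyf_percent: 63.0
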