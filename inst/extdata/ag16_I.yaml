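schema: agphot/descriptor/v1
name: Ag16(I)
units:
  energy: eV
  socme: cm^-1
  nacme: a.u.
  frequency: cm^-1
  rate: s^-1
contexts:
  S0-opt:
  - label: T1
    energy: 1.97
  - label: T2
    energy: 2.3
  - label: S1
    energy: 2.37
    oscillator_strength: 0.91
  S1-opt:
  - label: T1
    energy: 1.43
  - label: S1
    energy: 1.66
    oscillator_strength: 1.27
socme_s1_t1: 2.05
supplied_rates:
  k_r: 154000000.0
  k_isc: 825000000.0
  k_ic: 4960000.0
reference:
  experimental:
    absorption_s1_ev: 2.36
    emission_s1_ev: 1.7
    qyf_percent: 36.0
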