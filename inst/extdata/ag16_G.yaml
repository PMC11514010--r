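schema: agphot/descriptor/v1
name: Ag16(G)
units:
  energy: eV
  socme: cm^-1
  nacme: a.u.
  frequency: cm^-1
  rate: s^-1
contexts:
  S0-opt:
  - label: T1
    energy: 1.98
  - label: T2
    energy: 2.31
  - label: S1
    energy: 2.36
    oscillator_strength: 0.87
  S1-opt:
  - label: T1
    energy: 1.44
  - label: S1
    energy: 1.67
    oscillator_strength: 1.33
socme_s1_t1: 3.01
supplied_rates:
  k_r: 161000000.0
  k_isc: 1960000000.0
  k_ic: 4960000.0
reference:
  experimental:
    absorption_s1_ev: 2.36
    emission_s1_ev: 1.68
    qyf_percent: 26.0
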