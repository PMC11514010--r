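schema: agphot/descriptor/v1
name: Ag10(G)
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
    energy: 2.55
    oscillator_strength: 0.79
  S1-opt:
  - label: T1
    energy: 1.84
  - label: S1
    energy: 2.2
    oscillator_strength: 1.19
socme_s1_t1: 4.09
supplied_rates:
  k_r: 249000000.0
  k_isc: 879000000.0
  k_ic: 1000000.0
reference:
  experimental:
    absorption_s1_ev: 2.53
    emission_s1_ev: 2.18
    qyf_percent: 25.0
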