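# Lyman-Kutcher-Burman endpoint parameters (literature fits).
# The symptomatic-pneumonitis row is applied to both the ipsilateral and the
# whole lung.
symptomatic_pneumonitis:
  organ: lung
  n_volume: 1.000
  m: 0.35
  d50: 37.6
  source: Seppenwoolde et al. fit, parallel lung
radiation_pneumonitis_g2:
  organ: lung
  n_volume: 0.990
  m: 0.37
  d50: 30.8
  source: Burman et al. fit, grade >= 2 pneumonitis
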