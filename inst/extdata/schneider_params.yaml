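# Schneider secondary-cancer model organ parameters.
# delta: initial slope [(10,000 PY Gy)^-1]; gamma_e / gamma_a: age-modifier
# coefficients; alpha: linear-quadratic alpha [Gy^-1]; repop: repopulation/
# repair capacity R in [0, 1]. beta is derived as alpha / (alpha/beta ratio).
lung:
  delta: 8.0
  gamma_e: 0.002
  gamma_a: 4.23
  alpha: 0.042
  repop: 0.83
  source: Schneider et al., combined A-bomb and Hodgkin cohorts
breast:
  delta: 8.2
  gamma_e: -0.037
  gamma_a: 1.70
  alpha: 0.044
  repop: 0.15
  source: Schneider et al., combined A-bomb and Hodgkin cohorts
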