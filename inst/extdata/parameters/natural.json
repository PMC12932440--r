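{
  "omega_PC": 0.93,
  "omega_PB": 0.32,
  "omega_B": 0.00064,
  "eta_B": 0.008678,
  "eta_C": 0.0001096,
  "eta_S": 0.00011,
  "lambda_B": 1.29e-06,
  "lambda_C": 3.82e-06,
  "kappa_Sc": 0.05,
  "tau_E": 2.6,
  "e_PC": 0.2556,
  "e_Sc": 10.59,
  "sc_PC": 8600000,
  "sc_PB": 163,
  "sc_Omega": 3040,
  "r_Omega": 1020,
  "nu_Omega": 1080,
  "BMC0": 0.8,
  "t_m": 0,
  "resorption_coupling": "activation"
}
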