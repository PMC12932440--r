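{
  "kappa_E": 6.19957726712001,
  "k_syn": 0.596113198761539,
  "eta_surg": 5,
  "omega_surg": 1.86,
  "tau": 0.0097
}
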