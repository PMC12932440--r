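{
  "kappa_E": 6.19957726712001,
  "k_syn": 0.596113198761539,
  "eta_surg": 0.4174,
  "omega_surg": 0.2155,
  "tau": 0
}
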