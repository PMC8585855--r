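# Demo configuration: two-shift SLIDER acquisition, small in-plane grid.
preset: slider2
simulate:
  n_meas: 10
  seed: 7
  nx: 24
  ny: 24
noise:
  var_thermal: 16
  var_physio: 4
  rho: 0.5
recon:
  lambda: 0.1
quant:
  alpha: 0.85
  blood_t1_ms: 1650
  partition_coefficient: 0.9
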