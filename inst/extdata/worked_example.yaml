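# Worked hot-flash example: severity X ~ N(5, 2^2) on the 0-10 scale,
# surrogate prescreen measure Z with the same marginal, correlation 0.7.
outcome:
  beta0: 0
  beta1: -0.2
  beta2: 1
  beta3: -0.25
  sigma: 2.5
screening:
  mu_x: 5
  sd_x: 2
  mu_z: 5
  sd_z: 2
  rho: 0.7
costs:
  c_trt: 700
  c_placebo: 700
  c_rec: 300
  c_scr: 200
  c_pre: 100
  currency: USD
test:
  alpha: 0.05
  target_power: 0.90
  use_z_critical: true
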