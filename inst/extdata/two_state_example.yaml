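# Minimal two-state voltage-sensor example: resting/active gating with an
# active-state quencher. Units: ms, mV, Angstrom, elementary charges (e0);
# rates 1/ms at 0 mV.
scheme:
  positions: [0.0, 10.0]
  charges: [0.0, 1.0]
  transitions:
    - {from: 1, to: 2, rate0: 0.05, z: 1.0}
    - {from: 2, to: 1, rate0: 0.00214, z: -1.0}
  kT_mV: 25.4
geometry:
  x_w: 10.0
  lambda_half: 6.0
  F0: 1000.0
protocol:
  holding_mV: -120.0
  sample_interval_ms: 0.05
  segments:
    - {duration_ms: 10.0, voltage_mV: -120.0}
    - {duration_ms: 50.0, voltage_mV: 80.0}
    - {duration_ms: 20.0, voltage_mV: -120.0}
noise:
  gaussian_sd: 0.0
  drift_slope: 0.0
  bleach_rate: 0.0
  seed: 1
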