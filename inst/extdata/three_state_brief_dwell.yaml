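# Brief-dwell variant of the three-state trajectory: exit from the
# intermediate state is 20x faster than entry, so the single-pulse
# fluorescence is monotonic but still carries two exponential components
# (two nonzero relaxation eigenvalues). The quencher sits nearer the
# resting end of the path. Synthetic demonstration parameters.
# Units: ms, mV, Angstrom, elementary charges (e0); rates 1/ms at 0 mV.
scheme:
  positions: [0.0, 5.0, 10.0]
  charges: [0.0, 0.5, 1.0]
  transitions:
    - {from: 1, to: 2, rate0: 0.0428, z: 1.0}
    - {from: 2, to: 1, rate0: 0.0100, z: -1.0}
    - {from: 2, to: 3, rate0: 0.8560, z: 1.0}
    - {from: 3, to: 2, rate0: 0.0050, z: -1.0}
  kT_mV: 25.4
geometry:
  x_w: 2.0
  lambda_half: 6.0
  F0: 1.0
protocol:
  holding_mV: -120.0
  sample_interval_ms: 0.02
  segments:
    - {duration_ms: 5.0, voltage_mV: -120.0}
    - {duration_ms: 50.0, voltage_mV: 80.0}
noise:
  gaussian_sd: 0.0
  drift_slope: 0.0
  bleach_rate: 0.0
  seed: 1
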