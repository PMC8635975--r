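# Three-state voltage-sensor trajectory whose single-pulse fluorescence is
# biphasic: the quencher sits next to the intermediate state and the dwell
# time there is comparable to the activation step, so the ensemble
# fluorescence dips while the intermediate is occupied and recovers as the
# final state fills. Synthetic demonstration parameters.
# Units: ms, mV, Angstrom, elementary charges (e0); rates 1/ms at 0 mV.
scheme:
  positions: [0.0, 5.0, 10.0]
  charges: [0.0, 0.5, 1.0]
  transitions:
    - {from: 1, to: 2, rate0: 0.0428, z: 1.0}
    - {from: 2, to: 1, rate0: 0.0100, z: -1.0}
    - {from: 2, to: 3, rate0: 0.0214, z: 1.0}
    - {from: 3, to: 2, rate0: 0.0050, z: -1.0}
  kT_mV: 25.4
geometry:
  x_w: 4.5
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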