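# Default study configuration: the full training design (512 runs, 100
# snapshots, 99.9% POD energy, fourfold cross-validation) with
# quasi-Monte Carlo UQ and Saltelli sensitivity replication.
space:
  names: [endothelium_regen_days, flow_velocity_m_s, threshold_strain, fenestration_pct]
  mins: [10, 0.133, 0.446, 2]
  maxs: [20, 0.399, 0.785, 10]
  units: [day, m/s, "", "%"]
emulator: {}
n_train: 512
surrogate:
  n_snapshots: 100
  energy: 0.999
  folds: 4
  restarts: 10
uq:
  n_samples: 10000
  reps: 10
  days: [5, 10, 15, 20, 30]
  restenosis_threshold: 0.5
sensitivity:
  n_base: 4096
  reps: 10
seeds:
  master: 1
output_dir: isruq-output
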