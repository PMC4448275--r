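# Example mvsim run configuration: a small two-condition study.
network:
  n_genes: 60
  n_mirnas: 10
  n_signals: 3
  alpha: 2.2
  lambda: 0.5
  pool_size: 10
noise:
  sigma_bio: 0.05
  c: 0.0
  sigma_eps: 0.05
  sigma_eta: 0.1
simulation:
  t_max: 50
  n_points: 100
  initial_state: 0.1
conditions:
  - name: control
    n_subjects: 10
    signals:
      type: constant
      value: 0
  - name: treated
    n_subjects: 10
    signals:
      type: constant
      value: 1
seed: 42
out_prefix: example
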