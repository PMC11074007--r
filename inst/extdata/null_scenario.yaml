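# Null simulation scenario: mixture proteome, no DE proteins, no
# inter-peptide correlation. Replicates kept small here; override with
# --reps for full runs.
proteome:
  - [1400, 3]
  - [360, 10]
  - [40, 30]
rho: 0.0
n_samples: 30
de_fraction: 0.0
effect: 0.5
n_reps: 5
seed: 1
methods: [pepsettest_sd]
alpha: 0.05
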