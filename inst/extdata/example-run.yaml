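# Example run configuration: simulate a WT+b3 current-voltage experiment.
preset: WT+b3
cell:
  capacitance_pF: 20
  leak_nS: 0.5
  noise_sd_pA: 0
  seed: 1
protocol:
  kind: IV
  v_start: -84
  v_stop: 61
  step: 5
seed: 1
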