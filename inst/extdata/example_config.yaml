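# Example experiment configuration; keys mirror network_params() one-to-one.
network:
  n_pns: 50
  n_kcs: 2000
  pn_kc_prob: 0.14
  kc_threshold: 119
  kc_mbon_prob: 0.5
  pn_response_prob: 0.5
  spike_low: 10
  spike_high: 30
  n_odors: 100
  n_individuals: 2
experiment: simulate
seed: 1
output_dir: results
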