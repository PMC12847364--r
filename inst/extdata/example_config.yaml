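# Example run configuration: a reduced study that finishes in minutes.
# Omitted keys take the package defaults (full protocol, standard
# analysis constants); see ?protocol_config, ?sim_config,
# ?analysis_defaults.
protocol:
  trials_per_task_per_block: 10
  n_blocks: 1
  fs: 250
  n_channels: 16
sim:
  effect_size: 1.3
  overlap_alpha: 0.6
  sinokin_depth: 0.6
  seed: 1
analysis:
  n_repeats: 2
  scenario_sizes: [2, 6]
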