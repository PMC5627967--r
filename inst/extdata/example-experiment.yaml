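# Example experiment configuration for fabsense::read_experiment_config().
# Reduced trial count and duration keep this quick to run; drop the
# apparatus block to use the full study geometry (10 s, 10 trials).
scenario: rigid_vs_fabric
trials_per_condition: 4
master_seed: 42
apparatus:
  duration: 4.0
window_ms: [50, 250, 1000]
kernel: gaussian
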