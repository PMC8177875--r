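# Example cohort/analysis configuration for the megalpha CLI.
n_control: 6
n_patient: 6
duration: 24
sampling_rate: 300
n_channels: 8
master_seed: 7
n_permutations: 999
seed: 7
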