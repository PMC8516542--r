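# Y-shaped synthetic vessel tree with exact ground truth.
preset: ytree
noise_sigma: 0
rng_seed: 1
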