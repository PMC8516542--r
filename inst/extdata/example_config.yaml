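# Example coroseg configuration: every key is optional and defaults are
# sensible for X-ray angiograms (dark vessels on bright background).
vessel_polarity: bright
rng_seed: 1
denoise_sigma: 10
um_k: 1.5
clahe_clip_limit: 2.5
vesselness_sigma_min: 1
vesselness_sigma_max: 10
track_d: 5
track_delta_theta: 45
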