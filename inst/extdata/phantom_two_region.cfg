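# Reference two-region phantom: 32 x 32 grid, 50 m/z features,
# 5 planted markers for region A under log-normal noise.
grid_h = 32
grid_w = 32
n_features = 50
baseline_log_mean = 0
noise_sigma = 0.3
seed = 1
region = A rect 4 3 27 13
region = B rect 4 18 27 28
marker = 5 A UP 2.0
marker = 15 A UP 2.0
marker = 25 A UP 2.0
marker = 35 A DOWN 2.0
marker = 45 A DOWN 2.0
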