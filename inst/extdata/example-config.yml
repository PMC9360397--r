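# Example pipeline configuration: full study design, all four methods.
# Any key of pipeline_config() may appear here; params holds
# forward_params() overrides.
n_animals: 10
seed: 42
methods: [uv, red, pls, ann]
split_fraction: 0.7
cv_k: 10
max_epochs: 500
render_images: 2
image_size: 32
pixel_noise_sd: 1
out_dir: haemoquant-out
params:
  abs_intercept: 0.1051
  abs_slope: 0.0873
  red_intercept: 0.0929
  red_slope: 0.0187
  target_r_abs: 0.991
  target_r_red: 0.983
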