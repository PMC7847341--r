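# Default enhancement configuration (all keys of mhnn_config()).
# Pass to the CLI with:  geohnn enhance in.png out.png --config default.yaml
patch_rows: 22          # partition grid rows (22 x 20 = 440 patches)
patch_cols: 20
neighborhood: 4         # 4 or 8
kappa0: 0.01            # coupling ceiling; ~ squared quarter band-width at Q=5
hyperplane_dim: 2       # class count Q = class_count(hyperplane_dim) = 5
alpha: 0.7              # blend weight of the contrast remap
max_sweeps: 100
seed: 1
smoothness_sign: potts  # potts (reward neighbor agreement) or paper
recompute_orientation: false
proto_method: quantile  # quantile (deterministic) or kmeans
window_shape: gaussian  # orientation window
window_size: 5
window_sigma: 1.0
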