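# Marker discovery on the built-in two-region phantom, class A vs rest.
phantom = two_region
class = A
n_trees = 100
max_depth = 4
learning_rate = 0.3
lambda = 1
row_subsample = 0.8
col_subsample = 0.8
min_child_cover = 5
eta = 0.5
pos_fraction = 0.25
test_fraction = 0.25
scope = all_pixels
top_k = 10
direction_threshold = 0.3
accuracy_floor = 0.8
seed = 11
out_dir = discovery_out
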