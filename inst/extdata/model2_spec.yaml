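# Synthetic-bilayer spec preset: the realistic four-component OMM model
# (model 2) at full size. Equivalent to synthetic_spec(model = 2) with a
# short 10-ns trajectory.
model: 2
n_lipids: 784
box_xy: [15.6, 15.6]
d_pp: 4.13
sigma_z: 0.15
n_frames: 100
dt: 100
n_salt_pairs: 110
na_bound_per_lipid: 0.29
na_multiplicity: 3
seed: 1
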