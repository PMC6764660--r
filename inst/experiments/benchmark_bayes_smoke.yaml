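# Half-scale smoke benchmark for the Bayesian partial-pooling method:
# all lengths halved relative to the nominal conditions, analyzed at
# 6 mm voxels to keep the per-fit model size near 1000 voxels.
brain_radius_mm: 37
voxel_size_mm: 1
analysis_voxel_size_mm: 6
n_patients_per_cohort: 50
tumor_diameter_mm: 40
extent_of_resection: 0.60
effect_region_diameter_mm: 20
effect_region_center: [15, 0, 0]
p_avoid_A: 0.0
p_avoid_B: 1.0
n_repetitions: 3
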