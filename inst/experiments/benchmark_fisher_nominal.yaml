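# Nominal benchmarking conditions: 8 cm tumors, 50 patients per cohort,
# 60% extent of resection, 4 cm avoidance region (0% vs 100% avoidance),
# generated at 1 mm and analyzed at 4 mm voxels.
brain_radius_mm: 74
voxel_size_mm: 1
analysis_voxel_size_mm: 4
n_patients_per_cohort: 50
tumor_diameter_mm: 80
extent_of_resection: 0.60
effect_region_diameter_mm: 40
effect_region_center: [30, 0, 0]
p_avoid_A: 0.0
p_avoid_B: 1.0
n_repetitions: 1000
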