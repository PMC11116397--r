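# Example pipeline configuration for `mitograph run --config`.
# Lengths are in the units named by each key (nm or um).
seed: 1
Is: 0.864
scene:
  field_um: [10, 10]
  n_components: 5
  diameter_nm: [300, 550]
  cristae_spacing_nm: 70
  branch_prob_per_um: 0.15
placement:
  occupancy: 0.677
  per_um: 0.5
acquisition_im:
  I_dep: 34.7
  photon_budget: 300
acquisition_mtdna:
  I_dep: 0
  photon_budget: 200
segmentation:
  threshold: 0.3
stats:
  cutoff_um: 0.6
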