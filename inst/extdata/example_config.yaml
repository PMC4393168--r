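# Example configuration for the `kesct` command-line interface.
voxel_um: 2.74
calibration:
  slope_mu_to_dhap: 136
  intercept_dhap: -142
  gray_to_mu_factor: 0.392
  bone_mu_threshold: 4.74
segmentation:
  max_filter_radius: 1
  mean_filter_size: 3
  min_threshold_gray: 8
roi:
  diameter_um: 720
  height_um: 300
  axis: 1
registration:
  max_shift_vox: 5
  rotations: true
phantom:
  roi_diameter_um: 720
  roi_height_um: 300
  noise_sd_gray: 2
  blur_sigma_um: 2.74
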