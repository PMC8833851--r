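# Default registration configuration (schema v1). Any subset of these keys
# may be overridden in a user file passed via --config / load_config().
schema_version: 1
pyramid:
  n_levels: 3
  factor: 2
  smoothing_fwhm_vox: 2.0
nmi_bins: 64
w_init: 0.0
w_bounds: [-1.0, 1.0]
powell:
  xtol: 1.0e-3          # scaled parameter units
  ftol: 1.0e-5
stage1:                 # global affine + w, whole-volume NMI
  max_iter: [10, 8, 5]  # per pyramid level, coarsest first
  stride: [1, 1, 8]     # metric voxel subsampling per level
  w_starts: [-0.5, 0.0, 0.5]
stage2:                 # masked affine + 2nd-order polynomial + w
  enabled: true
  n_levels: 2
  max_iter: [5, 3]
  stride: [1, 4]
refine:                 # rigid cerebellum/brain-stem refinement (NCC)
  fraction: 0.85        # high-uptake quantile within the reference mask
  sigma_mm: 3.0         # Gaussian sigma of the blending mask
  max_iter: 12
scale_prior:            # soft prior tying affine scales to image moments
  weight: 0.002
  sd: 0.05
scales:                 # parameter units per Powell step
  trans: 1.0            # mm
  rot: 0.01             # rad
  scale: 0.01
  shear: 0.01
  poly_vox: 0.1         # voxels
  w: 0.1
seed: 0
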