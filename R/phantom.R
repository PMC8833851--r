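# Deterministic digital phantom. One latent burden parameter a in [0, 1]
# generates the amyloid appearance continuum: white matter and brain stem
# uptake are always high, cortical gray matter rises linearly with burden,
# cerebellar gray stays burden-independent. Geometry is a desk-scale
# ellipsoid anatomy on a 64 x 64 x 54 grid at 2 mm isotropic. All random
# draws flow from explicit seeds; no global random state leaks.

PHANTOM_LABELS <- c(background = 0L, cortical_gm = 1L, wm = 2L,
                    ventricles = 3L, cerebellar_gm = 4L, cerebellar_wm = 5L,
                    brain_stem = 6L, pons = 7L)

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

derive_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(i) * 7L + 13L
}

#' Deterministic phantom anatomy
#'
#' Ellipsoidal cerebrum with a thick cortical ribbon and interior white
#' matter, paired ventricles, an inferior cerebellum (gray shell, white core)
#' and a brain-stem cylinder with a pons bulge. Labels are mutually
#' exclusive; every atlas region is derivable from them.
#'
#' @param shape Grid extents (default 64 x 64 x 54).
#' @param voxel_mm Isotropic voxel size in mm (default 2).
#' @return Object of class `phantom_anatomy` with `labels` (integer array),
#'   `affine`, `shape`, `voxel_mm`.
#' @export
make_anatomy <- function(shape = c(64L, 64L, 54L), voxel_mm = 2) {
  if (any(shape < 32L))
    pct_error("grid must have at least 32 voxels per axis", "pct_value_error")
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- -(shape - 1) * voxel_mm / 2
  ax <- (seq_len(shape[1]) - 1) * voxel_mm + affine[1, 4]
  ay <- (seq_len(shape[2]) - 1) * voxel_mm + affine[2, 4]
  az <- (seq_len(shape[3]) - 1) * voxel_mm + affine[3, 4]
  X <- array(ax, shape)
  Y <- array(rep(ay, each = shape[1]), shape)
  Z <- array(rep(az, each = shape[1] * shape[2]), shape)

  ell <- function(cx, cy, cz, rx, ry, rz)
    ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 + ((Z - cz) / rz)^2 <= 1

  lab <- array(0L, shape)
  cer_out <- ell(0, 8, 14, 44, 50, 38)
  cer_in <- ell(0, 8, 14, 38, 44, 32)      # 6 mm cortical ribbon
  lab[cer_out] <- PHANTOM_LABELS[["cortical_gm"]]
  lab[cer_in] <- PHANTOM_LABELS[["wm"]]
  vent <- ell(-10, 4, 10, 7, 16, 9) | ell(10, 4, 10, 7, 16, 9)
  lab[vent] <- PHANTOM_LABELS[["ventricles"]]

  stem <- (X^2 + (Y + 10)^2 <= 9^2) & Z >= -48 & Z <= -12 & lab == 0L
  lab[stem] <- PHANTOM_LABELS[["brain_stem"]]
  pons <- (X^2 + (Y + 10)^2 <= 9^2) & Z >= -38 & Z <= -24 &
    lab == PHANTOM_LABELS[["brain_stem"]]
  lab[pons] <- PHANTOM_LABELS[["pons"]]

  # foliated cerebellum: alternating white-matter lamellae (arbor vitae)
  # inside a gray shell, so the reference region has internal structure
  cb <- ell(0, -36, -28, 26, 20, 16) & lab == 0L
  cb_core <- ell(0, -36, -28, 22, 16, 12) & lab == 0L
  foli <- sin(2 * pi * ((Y + 36) + 0.6 * (Z + 28)) / 11) +
    0.4 * sin(2 * pi * X / 13)
  lab[cb] <- PHANTOM_LABELS[["cerebellar_gm"]]
  lab[cb_core & foli > 0] <- PHANTOM_LABELS[["cerebellar_wm"]]

  present <- PHANTOM_LABELS %in% unique(as.integer(lab))
  if (!all(present))
    pct_error(paste("phantom labels missing:",
                    paste(names(PHANTOM_LABELS)[!present], collapse = ", ")),
              "pct_value_error")
  structure(list(labels = lab, affine = affine, shape = shape,
                 voxel_mm = voxel_mm),
            class = "phantom_anatomy")
}

label_volume <- function(anatomy) {
  as_volume(array(as.numeric(anatomy$labels), anatomy$shape), anatomy$affine)
}

uptake_constants <- function(burden, wm_level = 1) {
  c(background = 0, cortical_gm = 0.8 + 1.6 * burden, wm = 2.0 * wm_level,
    ventricles = 0.1, cerebellar_gm = 0.8 * wm_level,
    cerebellar_wm = 2.0 * wm_level, brain_stem = 2.2, pons = 2.2)
}

#' Render the amyloid-like uptake image of the phantom
#'
#' Assigns region intensities (white matter and brain stem always high;
#' cortical gray matter scaling linearly with burden; cerebellar gray
#' burden-independent) and blurs with an isotropic Gaussian mimicking the
#' scanner point-spread function. The intensity constants are fixture
#' conventions of the generator.
#'
#' @param anatomy `phantom_anatomy`.
#' @param burden Amyloid burden a in \[0, 1\].
#' @param psf_fwhm_mm Scanner blur FWHM in mm (0 for none; default 4).
#' @param wm_level Per-subject nonspecific (white-matter-type) binding level
#'   multiplying the cerebral white matter and the cerebellum (gray and
#'   white), leaving the brain stem and pons untouched: the
#'   burden-independent appearance mode of a cohort. Its support is disjoint
#'   from the cortical burden signal, so the two cohort appearance modes stay
#'   separable, and the pons is untouched so the mode survives pons intensity
#'   normalization. Default 1.
#' @param heterogeneity Amplitude of the fixed smooth regional-heterogeneity
#'   field multiplying the tissue intensities (default 0.15, mimicking the
#'   regional variation of tracer uptake within tissue classes; 0 yields a
#'   piecewise-constant image). Identical for every subject, so it shifts no
#'   variance between the cohort's appearance modes.
#' @return `pet_volume` in template space.
#' @export
render_uptake <- function(anatomy, burden, psf_fwhm_mm = 4, wm_level = 1,
                          heterogeneity = 0.15) {
  if (burden < 0 || burden > 1)
    pct_error("burden must lie in [0, 1]", "pct_value_error")
  if (wm_level <= 0)
    pct_error("wm_level must be positive", "pct_value_error")
  ints <- uptake_constants(burden, wm_level)
  img <- array(ints[anatomy$labels + 1L], anatomy$shape)
  if (heterogeneity > 0)
    img <- img * (1 + heterogeneity * heterogeneity_field(anatomy))
  v <- as_volume(img, anatomy$affine)
  if (psf_fwhm_mm > 0) v <- smooth_volume(v, psf_fwhm_mm)
  v
}

# fixed low-frequency modulation pattern (world-coordinate based, so it is
# resolution independent and identical across subjects)
heterogeneity_field <- function(anatomy) {
  shape <- anatomy$shape
  aff <- anatomy$affine
  ax <- (seq_len(shape[1]) - 1) * aff[1, 1] + aff[1, 4]
  ay <- (seq_len(shape[2]) - 1) * aff[2, 2] + aff[2, 4]
  az <- (seq_len(shape[3]) - 1) * aff[3, 3] + aff[3, 4]
  X <- array(ax, shape)
  Y <- array(rep(ay, each = shape[1]), shape)
  Z <- array(rep(az, each = shape[1] * shape[2]), shape)
  sin(2 * pi * X / 90 + 0.7) * cos(2 * pi * Y / 110 + 1.3) +
    0.5 * cos(2 * pi * Z / 70 + 2.1) * sin(2 * pi * Y / 80 + 0.4)
}

#' Ground-truth generating parameters of a synthetic subject
#'
#' @param burden Amyloid burden in \[0, 1\].
#' @param affine `affine_transform` mapping template to subject world
#'   coordinates (the truth the registration must recover).
#' @param poly Optional `polynomial_transform` truth deformation.
#' @param local_shift Optional `rigid_transform` applied to the
#'   cerebellum/brain-stem block in template space before warping.
#' @param noise_sigma Additive Gaussian noise, as a fraction of the brain
#'   mean intensity.
#' @param seed Integer seed for the noise draw.
#' @param wm_level Per-subject white-matter level (see [render_uptake()]).
#' @return Object of class `phantom_truth`.
#' @export
phantom_truth <- function(burden, affine = affine_transform(), poly = NULL,
                          local_shift = NULL, noise_sigma = 0, seed = 1L,
                          wm_level = 1) {
  structure(list(burden = burden, affine = affine, poly = poly,
                 local_shift = local_shift, noise_sigma = noise_sigma,
                 seed = as.integer(seed), wm_level = wm_level),
            class = "phantom_truth")
}

shift_reference_block <- function(anatomy, local_shift) {
  block_codes <- PHANTOM_LABELS[c("cerebellar_gm", "cerebellar_wm",
                                  "brain_stem", "pons")]
  lab <- anatomy$labels
  block <- array(ifelse(lab %in% block_codes, as.numeric(lab), 0),
                 anatomy$shape)
  block_vol <- as_volume(block, anatomy$affine)
  # pull-back with the inverse rigid places the block at its shifted position
  shifted <- resample(block_vol, invert_affine(local_shift), block_vol,
                      "nearest")
  lab[lab %in% block_codes] <- 0L
  moved <- shifted$data > 0
  lab[moved] <- as.integer(shifted$data[moved])
  anatomy$labels <- lab
  anatomy
}

# Map subject-grid world points into template world coordinates: the inverse
# of the truth transform (affine, optionally followed by iterative inversion
# of the polynomial displacement).
inverse_truth_transform <- function(truth) {
  Ainv <- invert_affine(truth$affine)
  if (is.null(truth$poly)) return(Ainv)
  function(pts) {
    x <- apply_transform(Ainv, pts)
    for (it in 1:20) {
      d <- poly_displacement(truth$poly, x)
      x_new <- apply_transform(Ainv, pts - d)
      if (max(abs(x_new - x)) < 1e-6) { x <- x_new; break }
      x <- x_new
    }
    x
  }
}

resample_with_fn <- function(moving, fn, target_grid, interpolation) {
  pts <- grid_world_coords(target_grid)
  pts <- if (is.function(fn)) fn(pts) else apply_transform(fn, pts)
  vals <- sample_at_world(moving, pts, interpolation)
  as_volume(array(vals, dim(target_grid$data)), target_grid$affine)
}

#' Generate a subject-space phantom scan with known ground truth
#'
#' Renders the uptake at the truth burden, applies the optional local
#' cerebellum/brain-stem shift in template space, warps to subject space by
#' the truth affine (plus optional polynomial), and adds white Gaussian noise
#' of standard deviation `noise_sigma` times the brain mean. Identical truth
#' yields a bit-identical image.
#'
#' @param anatomy `phantom_anatomy`.
#' @param truth `phantom_truth`.
#' @param psf_fwhm_mm Scanner blur FWHM in mm.
#' @return List with `volume` (`pet_volume`) and `truth` (echoed).
#' @export
generate_subject <- function(anatomy, truth, psf_fwhm_mm = 4) {
  anat <- if (is.null(truth$local_shift)) anatomy
          else shift_reference_block(anatomy, truth$local_shift)
  uptake <- render_uptake(anat, truth$burden, psf_fwhm_mm,
                          truth$wm_level %||% 1)
  inv_fn <- inverse_truth_transform(truth)
  subj <- resample_with_fn(uptake, inv_fn, uptake, "trilinear")
  if (truth$noise_sigma > 0) {
    brain <- resample_with_fn(label_volume(anat), inv_fn, uptake, "nearest")
    bm <- brain$data > 0
    sigma <- truth$noise_sigma * mean(subj$data[bm])
    noise <- with_seed(truth$seed,
                       rnorm(length(subj$data), sd = sigma))
    subj$data <- subj$data + array(noise, dim(subj$data))
  }
  list(volume = subj, truth = truth)
}

sample_warp <- function(sampler, seed) {
  s <- sampler
  with_seed(seed, {
    rot <- stats::runif(3, -1, 1) * s$rot_deg * pi / 180
    tr <- stats::runif(3, -1, 1) * s$trans_mm
    sc <- stats::runif(3, s$scale[1], s$scale[2])
    sh <- stats::runif(3, -1, 1) * s$shear
    affine_transform(c(tr, rot, sc, sh))
  })
}

#' Default subject-warp sampler settings
#'
#' Small affines typical of head-position differences: rotations up to 10
#' degrees, translations up to 8 mm, scales in \[0.95, 1.05\], shears up to
#' 0.02.
#'
#' @return Named list understood by [generate_cohort()].
#' @export
default_warp_sampler <- function() {
  list(rot_deg = 10, trans_mm = 8, scale = c(0.95, 1.05), shear = 0.02)
}

#' Generate a synthetic cohort
#'
#' Draws burdens covering \[0, 1\] (stratified grid by default) and a
#' per-subject white-matter level (the burden-independent appearance mode,
#' normal with sd `mode_sd` around 1), renders template-space images
#' (no warp, for template building), adds noise, intensity-normalizes each by
#' its pons mean, and returns the stack plus per-subject ground truth. With
#' `warp_sampler` set, additionally emits subject-space warped copies for
#' registration tests.
#'
#' @param anatomy `phantom_anatomy`.
#' @param n Number of subjects (>= 4).
#' @param burden_sampler `"stratified"` (default) or `"uniform"`.
#' @param warp_sampler `NULL`, `TRUE` (defaults) or a list as
#'   [default_warp_sampler()].
#' @param noise_sigma Noise fraction of brain mean (default 0.05).
#' @param psf_fwhm_mm Scanner blur FWHM in mm (default 4).
#' @param mode_sd Spread of the per-subject nonspecific-binding level
#'   (default 0.3, truncated to \[0.5, 1.5\]); 0 disables the mode.
#' @param seed Integer master seed; all draws derive from it.
#' @return Object of class `phantom_cohort`: list with `stack`
#'   (`image_stack` of normalized template-space images), `truths`,
#'   `subjects` (when warped), `anatomy`.
#' @export
generate_cohort <- function(anatomy, n = 20L, burden_sampler = "stratified",
                            warp_sampler = NULL, noise_sigma = 0.05,
                            psf_fwhm_mm = 4, mode_sd = 0.3, seed = 1L) {
  if (n < 4L) pct_error("cohort needs n >= 4", "pct_value_error")
  burdens <- switch(burden_sampler,
    stratified = seq(0, 1, length.out = n),
    uniform = with_seed(derive_seed(seed, 0L), stats::runif(n)),
    pct_error("unknown burden sampler", "pct_value_error"))
  if (max(burdens) == min(burdens))
    warning("degenerate burden sampler: all burdens equal")
  if (isTRUE(warp_sampler)) warp_sampler <- default_warp_sampler()
  mode_coefs <- if (mode_sd > 0)
    with_seed(derive_seed(seed, 20000L),
              pmin(pmax(stats::rnorm(n, 1, mode_sd), 0.5), 1.5))
  else rep(1, n)

  pons_mask <- anatomy$labels == PHANTOM_LABELS[["pons"]]
  vols <- vector("list", n)
  truths <- vector("list", n)
  subjects <- if (is.null(warp_sampler)) NULL else vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- derive_seed(seed, i)
    aff <- if (is.null(warp_sampler)) affine_transform()
           else sample_warp(warp_sampler, derive_seed(seed, 10000L + i))
    truths[[i]] <- phantom_truth(burdens[i], aff,
                                 noise_sigma = noise_sigma, seed = seed_i,
                                 wm_level = mode_coefs[i])
    # template-space image for template building: no warp
    tmpl_truth <- phantom_truth(burdens[i], affine_transform(),
                                noise_sigma = noise_sigma, seed = seed_i,
                                wm_level = mode_coefs[i])
    img <- generate_subject(anatomy, tmpl_truth, psf_fwhm_mm)$volume
    img$data <- img$data / mean(img$data[pons_mask])
    vols[[i]] <- img
    if (!is.null(warp_sampler))
      subjects[[i]] <- generate_subject(anatomy, truths[[i]], psf_fwhm_mm)$volume
  }
  structure(list(stack = image_stack(vols),
                 truths = truths, subjects = subjects, anatomy = anatomy,
                 burdens = burdens, seed = as.integer(seed)),
            class = "phantom_cohort")
}

#' Build the template-space VOI atlas of the phantom
#'
#' Derives the quantification regions from the anatomy labels: CTX is the
#' cortical ribbon, CG the cerebellar gray shell, WC the whole cerebellum,
#' WC plus brain stem adds the stem and pons, and ThPons is the high-uptake
#' pons subset taken from the reference image (the training mean by
#' convention). Auxiliary masks for registration (brain with and without
#' ventricles, the cerebellum+brain-stem refinement mask, the gray-matter
#' mask) ride along.
#'
#' @param anatomy `phantom_anatomy`.
#' @param reference_image `pet_volume` used for ThPons; defaults to the
#'   rendered mid-burden phantom.
#' @param thpons_fraction Quantile fraction for ThPons (default 0.85).
#' @return `voi_atlas`.
#' @export
atlas_from_anatomy <- function(anatomy, reference_image = NULL,
                               thpons_fraction = 0.85) {
  lab <- anatomy$labels
  L <- PHANTOM_LABELS
  if (is.null(reference_image))
    reference_image <- render_uptake(anatomy, 0.5, 4)
  cg <- lab == L[["cerebellar_gm"]]
  wc <- cg | lab == L[["cerebellar_wm"]]
  wcbs <- wc | lab == L[["brain_stem"]] | lab == L[["pons"]]
  pons <- lab == L[["pons"]]
  masks <- list(
    CG = cg, WC = wc, WC_brainstem = wcbs, pons = pons,
    ThPons = make_thpons(pons, reference_image, thpons_fraction),
    CTX = lab == L[["cortical_gm"]]
  )
  # the refinement mask covers (not hugs) the cerebellum and brain stem:
  # a one-to-two voxel dilation keeps the pons interior fully inside the
  # blend plateau of the smoothed mask
  dil <- cpp_gaussian_blur(as.numeric(wcbs), dim(wcbs),
                           rep(1, 3)) > 0.15
  aux <- list(
    brain = lab > 0L,
    brain_noventricles = lab > 0L & lab != L[["ventricles"]],
    gm = lab == L[["cortical_gm"]],
    cereb_brainstem = array(dil, dim(wcbs))
  )
  voi_atlas(masks, list(affine = anatomy$affine), aux)
}
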