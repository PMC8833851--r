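# Rigid refinement of the cerebellum / brain-stem fit. Only the
# characteristic high-uptake voxels of the synthetic template inside the
# cerebellum+brain-stem mask drive the fit (85th-percentile threshold of the
# within-mask intensity histogram); the metric is normalized
# cross-correlation and the 6 rigid parameters start from identity. The
# resulting transform is blended into the global one through a
# Gaussian-smoothed copy of the binary mask so the final displacement field
# stays continuous.

#' Select the high-uptake template voxels inside a mask
#'
#' Thresholds the synthetic template at the `fraction` quantile
#' (linear-interpolation convention) of the within-mask intensity
#' distribution and keeps voxels at or above it, i.e. roughly the top
#' `1 - fraction` of masked voxels.
#'
#' @param template `synthetic_template` (or `pet_volume`).
#' @param binary_mask Mask (`pet_volume` or array) on the template grid.
#' @param fraction Quantile fraction in (0, 1); default 0.85.
#' @return `pet_volume` holding the 0/1 subsampled VOI.
#' @export
subsample_high_uptake <- function(template, binary_mask, fraction = 0.85) {
  vol <- if (inherits(template, "synthetic_template")) template$volume
         else template
  m <- if (inherits(binary_mask, "pet_volume")) binary_mask$data else binary_mask
  m <- m > 0
  if (!any(m)) pct_error("empty mask", "pct_empty_mask_error")
  if (fraction <= 0 || fraction >= 1)
    pct_error("fraction must lie in (0, 1)", "pct_value_error")
  vals <- vol$data[m]
  thr <- stats::quantile(vals, fraction, names = FALSE, type = 7)
  # tiny relative slack so the fraction -> 0 limit returns the whole mask
  eps <- 1e-6 * (max(vals) - min(vals))
  sel <- m & (vol$data >= thr - eps)
  if (max(vals) == min(vals))
    pct_error(sprintf(
      "constant template within mask; threshold %.6g selects no informative voxels",
      thr), "pct_constant_input_error")
  if (!any(sel))
    pct_error(sprintf("no voxels at or above threshold %.6g", thr),
              "pct_empty_mask_error")
  as_volume(array(as.numeric(sel), dim(vol$data)), vol$affine)
}

#' Gaussian-smoothed blending mask
#'
#' Blurs a 0/1 mask with an isotropic 3-D Gaussian of the given sigma and
#' clips to \[0, 1\]; the deep interior stays at 1 and values far outside at 0,
#' giving the weight field used to blend the rigid refinement into the global
#' transform.
#'
#' @param binary Mask (`pet_volume` or array with grid of `grid`).
#' @param sigma_mm Gaussian sigma in mm (> 0).
#' @param grid `pet_volume` supplying the grid when `binary` is a bare array.
#' @return `pet_volume` with values in \[0, 1\].
#' @export
make_smoothed_mask <- function(binary, sigma_mm = 3, grid = NULL) {
  vol <- if (inherits(binary, "pet_volume")) binary
         else as_volume(array(as.numeric(binary > 0), dim(binary)), grid$affine)
  if (sigma_mm <= 0) pct_error("sigma must be > 0", "pct_value_error")
  if (!any(vol$data > 0)) pct_error("empty mask", "pct_empty_mask_error")
  sigma_vox <- sigma_mm / voxel_size(vol)
  sm <- cpp_gaussian_blur(as.numeric(vol$data > 0), dim(vol$data), sigma_vox)
  sm <- pmin(pmax(sm, 0), 1)
  as_volume(array(sm, dim(vol$data)), vol$affine)
}

#' Rigid refinement of the reference regions
#'
#' Optimizes a 6-parameter rigid increment R (starting from identity) so that
#' the subject, sampled through global-chain(R(x)) at the subsampled
#' high-uptake voxels x, maximizes normalized cross-correlation with the
#' accepted synthetic template. The template weight is frozen at the value
#' accepted by the global stages.
#'
#' @param subject `pet_volume` in subject space.
#' @param template `synthetic_template` at the accepted weight.
#' @param chain Converged global `transform_chain`.
#' @param subsampled High-uptake VOI from [subsample_high_uptake()].
#' @param config Configuration list.
#' @return `rigid_transform` increment.
#' @export
rigid_refine <- function(subject, template, chain, subsampled,
                         config = default_config()) {
  m <- subsampled$data > 0
  if (!any(m)) pct_error("empty subsampled mask", "pct_empty_mask_error")
  idx <- which(m)
  pts <- grid_world_coords(subsampled)[idx, , drop = FALSE]
  tv <- template$volume$data[idx]
  if (stats::sd(tv) == 0)
    pct_error("constant template over subsampled voxels",
              "pct_constant_input_error")
  inv_subj <- solve(subject$affine)
  sdim <- dim(subject$data)
  scales <- c(rep(config$scales$trans, 3), rep(config$scales$rot, 3))
  g_chain <- transform_chain(chain$affine, chain$polynomial, NULL,
                             chain$weight)
  obj <- function(z) {
    p6 <- z * scales
    R <- rigid_transform(p6)$matrix
    x2 <- apply_transform(R, pts)
    mapped <- apply_global(g_chain, x2)
    vox <- mapped %*% t(inv_subj[1:3, 1:3]) +
      matrix(inv_subj[1:3, 4], nrow(pts), 3, byrow = TRUE)
    sv <- cpp_sample_volume(subject$data, sdim, vox, FALSE, 0)
    if (stats::sd(sv) == 0) return(1)  # fully out of field: worst score
    -stats::cor(tv, sv)
  }
  # the refinement is a small local correction by construction; box bounds
  # keep Powell off degenerate far solutions (the reference region is close
  # to rotationally symmetric, so unbounded rotations are ill-determined)
  bnd <- list(lower = c(rep(-6 / config$scales$trans, 3),
                        rep(-0.15 / config$scales$rot, 3)),
              upper = c(rep(6 / config$scales$trans, 3),
                        rep(0.15 / config$scales$rot, 3)))
  res <- powell_minimize(obj, numeric(6), bounds = bnd,
                         xtol = config$powell$xtol,
                         ftol = config$powell$ftol,
                         max_iter = config$refine$max_iter)
  rigid <- rigid_transform(res$par * scales)
  # plausibility guard: the drive voxels are high-uptake by construction, so
  # a genuine correction must not land them on clearly lower subject uptake
  # (a correlation rise paired with an intensity drop marks a degenerate
  # match to background structure); fall back to identity in that case
  sample_mean <- function(R) {
    mapped <- apply_global(g_chain, apply_transform(R, pts))
    vox <- mapped %*% t(inv_subj[1:3, 1:3]) +
      matrix(inv_subj[1:3, 4], nrow(pts), 3, byrow = TRUE)
    mean(cpp_sample_volume(subject$data, sdim, vox, FALSE, 0))
  }
  if (sample_mean(rigid$matrix) < 0.9 * sample_mean(diag(4))) {
    warning("rigid refinement rejected (uptake drop at drive voxels); identity kept")
    rigid <- rigid_transform(numeric(6))
  }
  rigid
}

#' Blend the rigid refinement into the global transform
#'
#' Sets the chain's local stage so the final mapping at template point x is
#' y(x) = (1 - s(x)) G(x) + s(x) G(R(x)): linear interpolation between the
#' globally mapped coordinate and the rigidly pre-transformed one, weighted
#' by the smoothed mask s. Voxels with s = 0 are untouched and the
#' displacement field is continuous wherever s is.
#'
#' @param chain Global `transform_chain`.
#' @param rigid `rigid_transform` increment from [rigid_refine()].
#' @param smoothed Smoothed weight mask (`pet_volume`, values in \[0, 1\]).
#' @return Updated `transform_chain`.
#' @export
blend_local_transform <- function(chain, rigid, smoothed) {
  rng <- range(smoothed$data)
  if (rng[1] < 0 || rng[2] > 1)
    pct_error("smoothed mask values must lie in [0, 1]", "pct_value_error")
  chain$local_rigid <- list(rigid = rigid, blend = smoothed)
  chain
}
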