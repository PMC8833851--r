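# Adaptive-template registration. The template appearance weight w is one
# extra coordinate in Powell's parameter vector at every stage, so the
# optimizer jointly searches spatial parameters and template appearance;
# at every objective evaluation the template is re-synthesized as
# I_PC1 + w I_PC2 for the current w. Parameters are expressed in scaled units
# (rotations in 0.01 rad, scales/shears in 0.01, polynomial coefficients in
# 0.1 voxel, w in 0.1) so that one Powell step is commensurate across types.

#' Default registration configuration
#'
#' All tunable settings of the registration cascade: pyramid geometry, NMI
#' histogram bins, Powell tolerances and iteration caps per stage, the
#' appearance-weight bounds and start value, parameter scaling, and the
#' reference-refinement settings (high-uptake quantile fraction, mask
#' smoothing sigma).
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    pyramid = list(n_levels = 3L, factor = 2L, smoothing_fwhm_vox = 2),
    nmi_bins = 64L,
    w_init = 0, w_bounds = c(-1, 1),
    powell = list(xtol = 1e-3, ftol = 1e-5),
    stage1 = list(max_iter = c(10L, 8L, 5L), stride = c(1L, 1L, 8L),
                  w_starts = c(-0.5, 0, 0.5)),
    stage2 = list(enabled = TRUE, n_levels = 2L, max_iter = c(5L, 3L),
                  stride = c(1L, 4L)),
    refine = list(fraction = 0.85, sigma_mm = 3, max_iter = 12L),
    scales = list(trans = 1, rot = 0.01, scale = 0.01, shear = 0.01,
                  poly_vox = 0.1, w = 0.1),
    # soft prior tying the affine scales to the image-moment estimate
    # (second moments are appearance-insensitive; the prior breaks the
    # near-ties NMI exhibits between the true fit and intensity-consistent
    # but geometrically wrong enlarged/shrunken mappings)
    scale_prior = list(weight = 0.002, sd = 0.05),
    seed = 0L
  )
}

#' Load a configuration, merging user overrides into the defaults
#'
#' @param path Optional YAML file; top-level keys override [default_config()].
#' @return Configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    merge_into <- function(base, over) {
      for (nm in names(over)) {
        if (is.list(base[[nm]]) && is.list(over[[nm]]))
          base[[nm]] <- merge_into(base[[nm]], over[[nm]])
        else base[[nm]] <- over[[nm]]
      }
      base
    }
    cfg <- merge_into(cfg, user)
  }
  cfg
}

affine_scale_vec <- function(cfg) {
  s <- cfg$scales
  c(rep(s$trans, 3), rep(s$rot, 3), rep(s$scale, 3), rep(s$shear, 3))
}

# Moments-based initialization: align intensity centroids and match per-axis
# second moments between the model mean image and the subject. Gives the
# global stage a start near the true translation and scale, away from the
# background-overlap local optima that plague whole-volume NMI.
moment_init_params <- function(subject, mean_image) {
  moments <- function(v) {
    w <- as.numeric(v$data)
    # background-robust weights: noise in the (large) air region otherwise
    # dominates the second moments through its sheer voxel count
    thr <- 0.15 * stats::quantile(w, 0.999, names = FALSE)
    w <- pmax(w - thr, 0)
    pts <- grid_world_coords(v)
    ws <- sum(w)
    c0 <- colSums(pts * w) / ws
    s0 <- sqrt(colSums(sweep(pts, 2, c0)^2 * w) / ws)
    list(center = c0, sd = s0)
  }
  mt <- moments(mean_image)
  ms <- moments(subject)
  scales <- pmin(pmax(ms$sd / mt$sd, 0.8), 1.25)
  # template point x maps to scale * x + t with t chosen so centroids match
  tr <- ms$center - scales * mt$center
  c(tr, 0, 0, 0, scales, 0, 0, 0)
}

identity_affine_params <- function() c(0, 0, 0, 0, 0, 0, 1, 1, 1, 0, 0, 0)

# Downsample the template-space fixed images (eigenimages) and build the
# matching smoothed versions of the moving subject image for each level.
registration_levels <- function(subject, model, cfg) {
  np <- cfg$pyramid
  pyr1 <- build_pyramid(model$components[[1]], np$n_levels, np$factor,
                        np$smoothing_fwhm_vox)
  pyr2 <- build_pyramid(model$components[[2]], np$n_levels, np$factor,
                        np$smoothing_fwhm_vox)
  lapply(seq_len(np$n_levels), function(k) {
    fwhm <- if (k == np$n_levels) 0 else
      np$smoothing_fwhm_vox * voxel_size(pyr1$levels[[k]]) / np$factor
    list(pc1 = pyr1$levels[[k]], pc2 = pyr2$levels[[k]],
         subject = smooth_volume(subject, fwhm))
  })
}

make_nmi_objective <- function(level, mask_idx, cfg, use_poly, poly_domain,
                               poly_scale = 0.2, scale_anchor = NULL) {
  grid <- level$pc1
  pts_all <- grid_world_coords(grid)
  pts <- pts_all[mask_idx, , drop = FALSE]
  basis <- if (use_poly) poly_basis(pts, poly_domain) else NULL
  pc1v <- as.numeric(level$pc1$data)[mask_idx]
  pc2v <- as.numeric(level$pc2$data)[mask_idx]
  inv_subj <- solve(level$subject$affine)
  sdata <- level$subject$data
  sdim <- dim(sdata)
  sc12 <- affine_scale_vec(cfg)
  wb <- cfg$w_bounds
  nw <- if (use_poly) 43L else 13L
  bins <- cfg$nmi_bins
  n_off <- matrix(inv_subj[1:3, 4], nrow(pts), 3, byrow = TRUE)
  # fixed histogram ranges so the metric is continuous across evaluations:
  # the template range covers the whole w continuum, the subject range is
  # global (out-of-field samples fill with 0, which range(sdata) includes)
  rng_t <- range(range(pc1v - pc2v), range(pc1v + pc2v))
  rng_s <- range(range(sdata), 0)

  function(z) {
    p12 <- identity_affine_params() + z[1:12] * sc12
    if (any(p12[7:9] < 0.2)) return(10)  # reject collapsing scales
    A <- affine_transform(p12)$matrix
    w <- min(max(cfg$w_init + z[nw] * cfg$scales$w, wb[1]), wb[2])
    mapped <- pts %*% t(A[1:3, 1:3]) +
      matrix(A[1:3, 4], nrow(pts), 3, byrow = TRUE)
    if (use_poly) {
      co <- matrix(z[13:42] * poly_scale, 3, 10)
      mapped <- mapped + basis %*% t(co)
    }
    vox <- mapped %*% t(inv_subj[1:3, 1:3]) + n_off
    sv <- cpp_sample_volume(sdata, sdim, vox, FALSE, 0)
    tv <- pc1v + w * pc2v
    nmi <- suppressWarnings(nmi_from_values(tv, sv, bins, rng_t, rng_s,
                                            partial_volume = TRUE))
    pen <- 0
    if (!is.null(scale_anchor)) {
      sp <- cfg$scale_prior
      pen <- sp$weight * sum(((p12[7:9] - scale_anchor) / sp$sd)^2)
    }
    pen - nmi
  }
}

level_mask_idx <- function(mask_vol, grid, stride = 1L) {
  idx <- if (is.null(mask_vol)) seq_len(prod(dim(grid$data))) else {
    m <- resample(mask_vol, NULL, grid, "nearest")
    which(m$data > 0)
  }
  if (stride > 1L) idx <- idx[seq(1L, length(idx), by = stride)]
  idx
}

chain_from_z <- function(z, cfg, poly_domain, poly_scale) {
  sc12 <- affine_scale_vec(cfg)
  p12 <- identity_affine_params() + z[1:12] * sc12
  use_poly <- length(z) > 13L
  poly <- NULL
  if (use_poly) {
    poly <- polynomial_transform(matrix(z[13:42] * poly_scale, 3, 10),
                                 poly_domain)
  }
  nw <- if (use_poly) 43L else 13L
  w <- min(max(cfg$w_init + z[nw] * cfg$scales$w, cfg$w_bounds[1]),
           cfg$w_bounds[2])
  transform_chain(affine_transform(p12), poly, NULL, w)
}

#' Register a subject scan to template space with the adaptive template
#'
#' Stage 1 optimizes the 12 affine parameters jointly with the template
#' weight w, coarse to fine over a multiresolution pyramid, with normalized
#' mutual information over the whole volume. Stage 2 continues the affine,
#' adds a second-order polynomial deformation (30 coefficients), and restricts
#' the metric to a brain mask without ventricles. The template is
#' re-synthesized as I_PC1 + w I_PC2 at every objective evaluation. The local
#' rigid refinement of the cerebellum and brain stem is left to
#' [rigid_refine()] / [blend_local_transform()] (see also
#' [register_subject()] for the full cascade).
#'
#' @param subject `pet_volume` in subject space.
#' @param model `pc_model` with at least 2 components.
#' @param config Configuration list from [default_config()]/[load_config()].
#' @param brain_mask_noventricles Template-space mask (`pet_volume` or array)
#'   used by stage 2; `NULL` disables stage 2.
#' @return `transform_chain` with the accepted w and per-stage metrics in
#'   `$report` (`local_rigid` empty).
#' @export
register_adaptive <- function(subject, model, config = default_config(),
                              brain_mask_noventricles = NULL) {
  if (length(model$components) < 2L)
    pct_error("model needs at least 2 components", "pct_component_error")
  cfg <- config
  levels <- registration_levels(subject, model, cfg)
  nlev <- length(levels)
  poly_domain <- poly_domain_from_grid(model$components[[1]])
  poly_scale <- cfg$scales$poly_vox * mean(voxel_size(model$components[[1]]))
  report <- list()
  warnings <- character()

  # ---- stage 1: global affine + w, whole volume, coarse to fine.
  # At the coarsest level Powell is restarted from several w values and the
  # best basin kept, since the appearance weight landscape can be multimodal.
  z <- numeric(13)
  init <- moment_init_params(subject, model$mean_image)
  z[1:12] <- (init - identity_affine_params()) / affine_scale_vec(cfg)
  anchor <- init[7:9]
  it1 <- rep_len(cfg$stage1$max_iter, nlev)
  st1 <- rep_len(cfg$stage1$stride, nlev)
  for (k in seq_len(nlev)) {
    obj <- make_nmi_objective(levels[[k]],
                              level_mask_idx(NULL, levels[[k]]$pc1, st1[k]),
                              cfg, use_poly = FALSE, poly_domain,
                              scale_anchor = anchor)
    f0 <- obj(z)
    if (k == 1L) {
      best <- NULL
      for (w_start in cfg$stage1$w_starts) {
        z_try <- z
        z_try[13] <- (w_start - cfg$w_init) / cfg$scales$w
        r <- powell_minimize(obj, z_try, xtol = cfg$powell$xtol,
                             ftol = cfg$powell$ftol, max_iter = it1[k])
        if (is.null(best) || r$value < best$value) best <- r
      }
      res <- best
    } else {
      res <- powell_minimize(obj, z, xtol = cfg$powell$xtol,
                             ftol = cfg$powell$ftol, max_iter = it1[k])
    }
    z <- res$par
    report[[sprintf("stage1_level%d", k)]] <-
      list(nmi_start = -f0, nmi_end = -res$value, n_eval = res$n_eval,
           n_iter = res$n_iter)
  }
  z1 <- z

  # ---- stage 2: masked affine + polynomial + w refinement
  use_stage2 <- isTRUE(cfg$stage2$enabled) && !is.null(brain_mask_noventricles)
  if (use_stage2) {
    mask_vol <- if (inherits(brain_mask_noventricles, "pet_volume"))
      brain_mask_noventricles
    else as_volume(array(as.numeric(brain_mask_noventricles > 0),
                         model$grid$shape), model$grid$affine)
    n2 <- min(cfg$stage2$n_levels, nlev)
    lev_idx <- seq(nlev - n2 + 1L, nlev)
    it2 <- rep_len(cfg$stage2$max_iter, n2)
    st2 <- rep_len(cfg$stage2$stride, n2)
    z <- c(z1[1:12], numeric(30), z1[13])
    z_s1 <- z
    obj_fin <- NULL
    for (j in seq_along(lev_idx)) {
      k <- lev_idx[j]
      midx <- level_mask_idx(mask_vol, levels[[k]]$pc1, st2[j])
      obj <- make_nmi_objective(levels[[k]], midx, cfg, use_poly = TRUE,
                                poly_domain, poly_scale,
                                scale_anchor = anchor)
      f0 <- obj(z)
      res <- powell_minimize(obj, z, xtol = cfg$powell$xtol,
                             ftol = cfg$powell$ftol, max_iter = it2[j])
      z <- res$par
      obj_fin <- obj
      report[[sprintf("stage2_level%d", k)]] <-
        list(nmi_start = -f0, nmi_end = -res$value, n_eval = res$n_eval,
             n_iter = res$n_iter)
    }
    # guard (same level, same mask): stage 2 must not end worse than stage 1
    if (-res$value < -obj_fin(z_s1)) {
      warnings <- c(warnings, "stage 2 worsened the masked NMI; kept stage 1")
      z <- z_s1
    }
  }

  chain <- chain_from_z(z, cfg, poly_domain, poly_scale)
  if (chain$weight >= cfg$w_bounds[2] - 1e-12 ||
      chain$weight <= cfg$w_bounds[1] + 1e-12) {
    warnings <- c(warnings, sprintf(
      "template weight pinned at bound (w = %.3f)", chain$weight))
  }
  chain$report <- c(report, list(warnings = warnings, config = cfg))
  chain
}

#' Run the full registration cascade including reference refinement
#'
#' Convenience wrapper: [register_adaptive()] (global affine + masked
#' polynomial stages), then the rigid cerebellum/brain-stem refinement driven
#' by high-uptake template voxels, blended into the global transform through
#' a Gaussian-smoothed mask.
#'
#' @param subject `pet_volume`.
#' @param model `pc_model`.
#' @param atlas `voi_atlas` providing `brain_noventricles` and
#'   `cereb_brainstem` auxiliary masks on the template grid.
#' @param config Configuration list.
#' @return Complete `transform_chain` (with `local_rigid`).
#' @export
register_subject <- function(subject, model, atlas,
                             config = default_config()) {
  grid <- model$components[[1]]
  bm <- as_volume(array(as.numeric(atlas$aux$brain_noventricles), dim(grid$data)),
                  grid$affine)
  chain <- register_adaptive(subject, model, config, bm)
  cb <- as_volume(array(as.numeric(atlas$aux$cereb_brainstem), dim(grid$data)),
                  grid$affine)
  templ <- synthesize_template(model, chain$weight)
  sub_voi <- subsample_high_uptake(templ, cb, config$refine$fraction)
  rigid <- rigid_refine(subject, templ, chain, sub_voi, config)
  smoothed <- make_smoothed_mask(cb, config$refine$sigma_mm)
  blend_local_transform(chain, rigid, smoothed)
}

#' Serialize a transform chain to JSON
#'
#' Writes all parameters, the accepted weight, stage metrics and warnings;
#' the blend-weight volume (if any) is written as NIfTI next to the JSON.
#'
#' @param chain `transform_chain`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_chain <- function(chain, path) {
  obj <- list(
    affine_parameters = chain$affine$parameters,
    polynomial_coefficients = if (!is.null(chain$polynomial))
      chain$polynomial$coefficients,
    polynomial_domain = if (!is.null(chain$polynomial))
      chain$polynomial$domain,
    local_rigid_parameters = if (!is.null(chain$local_rigid))
      chain$local_rigid$rigid$parameters,
    weight = chain$weight,
    report = chain$report[setdiff(names(chain$report), "config")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(chain$local_rigid)) {
    write_volume(chain$local_rigid$blend,
                 sub("\\.json$", "_blend.nii.gz", path))
  }
  invisible(path)
}

#' Load a transform chain saved by [save_chain()]
#'
#' @param path JSON path.
#' @return `transform_chain`.
#' @export
load_chain <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  poly <- NULL
  if (!is.null(obj$polynomial_coefficients)) {
    dom <- list(center = as.numeric(obj$polynomial_domain$center),
                halfwidth = as.numeric(obj$polynomial_domain$halfwidth))
    poly <- polynomial_transform(matrix(unlist(obj$polynomial_coefficients),
                                        3, 10), dom)
  }
  lr <- NULL
  if (!is.null(obj$local_rigid_parameters)) {
    blend_path <- sub("\\.json$", "_blend.nii.gz", path)
    lr <- list(rigid = rigid_transform(as.numeric(obj$local_rigid_parameters)),
               blend = load_volume(blend_path))
  }
  transform_chain(affine_transform(as.numeric(obj$affine_parameters)),
                  poly, lr, as.numeric(obj$weight))
}
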