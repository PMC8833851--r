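test_that("high-uptake subsampling follows the linear-interpolation quantile", {
  # 100 voxels with intensities 1..100 inside the mask
  arr <- array(0, c(10, 10, 2)); arr[, , 1] <- 1:100
  v <- as_volume(arr, diag(4))
  m <- array(0, c(10, 10, 2)); m[, , 1] <- 1
  sel <- subsample_high_uptake(v, m, 0.85)
  expect_equal(sum(sel$data), 15)   # threshold 85.15 keeps 86..100
  # near-zero fraction keeps the whole mask
  sel0 <- subsample_high_uptake(v, m, 1e-9)
  expect_equal(sum(sel0$data), 100)
  k <- as_volume(array(1, c(10, 10, 2)), diag(4))
  expect_error(subsample_high_uptake(k, m, 0.85),
               class = "pct_constant_input_error")
  expect_error(subsample_high_uptake(v, array(0, c(10, 10, 2))),
               class = "pct_empty_mask_error")
})

test_that("smoothed mask approximates the binary mask at small sigma and stays in [0,1]", {
  m <- array(0, c(16, 16, 16)); m[5:12, 5:12, 5:12] <- 1
  g <- as_volume(m, diag(4))
  near <- make_smoothed_mask(m, sigma_mm = 0.1, grid = g)
  expect_lt(max(abs(near$data - m)), 1e-6)
  sm <- make_smoothed_mask(m, sigma_mm = 1, grid = g)
  expect_true(all(sm$data >= 0 & sm$data <= 1))
  expect_gte(sm$data[8, 8, 8], 0.99)   # centre is > 3 sigma inside
  expect_error(make_smoothed_mask(m, sigma_mm = 0, grid = g),
               class = "pct_value_error")
})

test_that("a single-voxel mask blurs to the separable kernel centre weight", {
  m <- array(0, c(17, 17, 17)); m[9, 9, 9] <- 1
  g <- as_volume(m, diag(4))
  sigma <- 2
  sm <- make_smoothed_mask(m, sigma_mm = sigma, grid = g)
  # oracle: the centre weight of the truncated renormalized 1-D kernel, cubed
  r <- ceiling(3 * sigma)
  k1 <- exp(-0.5 * ((-r):r)^2 / sigma^2); k1 <- k1 / sum(k1)
  expect_equal(sm$data[9, 9, 9], k1[r + 1]^3, tolerance = 1e-10)
})

test_that("blending leaves zero-weight voxels bit-identical and is continuous", {
  anat <- std_anatomy()
  grid <- as_volume(array(0, anat$shape), anat$affine)
  A <- affine_transform(c(2, -1, 1, 0.03, 0, -0.02, 1.01, 0.99, 1, 0, 0, 0))
  cb <- std_atlas_raw()$aux$cereb_brainstem
  sm <- make_smoothed_mask(array(as.numeric(cb), anat$shape), 3, grid)
  R <- rigid_transform(c(1.5, 0, -2, 0.02, 0, 0))
  ch <- blend_local_transform(transform_chain(A), R, sm)
  pts <- grid_world_coords(grid)
  y <- apply_transform(ch, pts)
  g <- apply_transform(A$matrix, pts)
  zero <- sm$data == 0
  expect_identical(y[zero, ], g[zero, ])

  # continuity: over x-neighbour pairs straddling the mask edge the jump is
  # bounded by (max rigid displacement) * (max neighbour weight difference)
  # plus the affinely mapped grid step
  d <- anat$shape
  i1 <- seq_len(prod(d) - 1)
  ds <- abs(as.numeric(sm$data)[i1] - as.numeric(sm$data)[i1 + 1])
  edge <- which(ds > 1e-6 & (i1 %% d[1]) != 0)
  jump <- sqrt(rowSums((y[edge, ] - y[edge + 1, ])^2))
  rdisp <- apply_transform(A$matrix, apply_transform(R$matrix, pts)) - g
  bound <- max(sqrt(rowSums(rdisp^2))) * max(ds[edge]) +
    max(sqrt(rowSums((g[edge, ] - g[edge + 1, ])^2)))
  expect_lte(max(jump), bound + 1e-9)

  expect_error(blend_local_transform(transform_chain(A), R,
                                     as_volume(array(1.5, anat$shape), anat$affine)),
               class = "pct_value_error")
})

test_that("rigid refinement is near-identity when there is nothing to correct", {
  anat <- std_anatomy()
  model <- std_model()
  atlas <- std_atlas()
  subj <- generate_subject(anat, phantom_truth(0.5, affine_transform(),
                                               noise_sigma = 0, seed = 3))$volume
  templ <- synthesize_template(model, 0.4)
  grid <- model$components[[1]]
  cb <- mask_volume_from(atlas$aux$cereb_brainstem, grid)
  voi <- subsample_high_uptake(templ, cb, 0.85)
  ch <- transform_chain(affine_transform(), NULL, NULL, 0.4)
  r <- rigid_refine(subj, templ, ch, voi, default_config())
  expect_lt(max(abs(r$parameters[1:3])), 0.5)            # < 0.5 mm
  expect_lt(max(abs(r$parameters[4:6])), 0.5 * pi / 180) # < 0.5 degrees

  # monotone improvement: NCC over the drive voxels does not decrease
  idx <- voi$data > 0
  tv <- as_volume(templ$volume$data, grid$affine)
  s0 <- resample(subj, NULL, grid, "trilinear")
  s1 <- resample(subj, r$matrix, grid, "trilinear")
  ncc0 <- normalized_cross_correlation(tv, s0, idx)
  ncc1 <- normalized_cross_correlation(tv, s1, idx)
  expect_gte(ncc1, ncc0 - 1e-9)
})
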