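# Module-level registration checks on cheap fixtures; the full recovery
# properties over cohorts are exercised in test-acceptance.R.

test_that("an already-registered synthetic subject yields a near-identity chain", {
  model <- std_model()
  atlas <- std_atlas_raw()
  subj <- synthesize_template(model, -1)$volume
  cfg <- default_config()
  cfg$stage2$enabled <- FALSE
  chain <- register_adaptive(subj, model, cfg, NULL)
  expect_lt(max(abs(chain$affine$parameters[1:3])), 0.1)   # translations, mm
  expect_lt(abs(chain$weight - (-1)), 0.02)
  # determinism: the whole chain is bit-identical across runs
  chain2 <- register_adaptive(subj, model, cfg, NULL)
  expect_identical(chain$affine$parameters, chain2$affine$parameters)
  expect_identical(chain$weight, chain2$weight)
})

test_that("with the polynomial disabled and w frozen, the cascade is plain affine NMI registration", {
  model <- std_model()
  wfix <- 0.5
  A <- affine_transform(c(2, -1, 0, 0.02, 0, -0.01, 1.01, 1, 0.99, 0, 0, 0))
  tmpl <- synthesize_template(model, wfix)$volume
  subj <- resample(tmpl, solve(A$matrix), tmpl, "trilinear")
  cfg <- default_config()
  cfg$stage2$enabled <- FALSE
  cfg$w_init <- wfix
  cfg$w_bounds <- c(wfix, wfix)       # freeze the appearance weight
  cfg$stage1$w_starts <- wfix
  chain <- register_adaptive(subj, model, cfg, NULL)
  expect_equal(chain$weight, wfix)
  # direct affine-only NMI registration over the same pyramid
  pyr1 <- build_pyramid(model$components[[1]], 3)
  pyr2 <- build_pyramid(model$components[[2]], 3)
  sc <- c(rep(1, 3), rep(0.01, 3), rep(0.01, 3), rep(0.01, 3))
  id12 <- c(0, 0, 0, 0, 0, 0, 1, 1, 1, 0, 0, 0)
  z <- numeric(12)
  strides <- c(1L, 1L, 8L)
  iters <- c(10L, 8L, 5L)
  for (k in 1:3) {
    p1 <- pyr1$levels[[k]]; p2 <- pyr2$levels[[k]]
    fixed <- as_volume(p1$data + wfix * p2$data, p1$affine)
    fwhm <- if (k == 3) 0 else 2 * voxel_size(fixed) / 2
    mov <- smooth_volume(subj, fwhm)
    idx <- seq(1, prod(dim(fixed$data)), by = strides[k])
    tv <- as.numeric(fixed$data)[idx]
    p1v <- as.numeric(p1$data)[idx]; p2v <- as.numeric(p2$data)[idx]
    rng_t <- range(range(p1v - p2v), range(p1v + p2v))
    rng_s <- range(range(mov$data), 0)
    obj <- function(zz) {
      Af <- affine_transform(id12 + zz * sc)
      sv <- resample(mov, Af$matrix, fixed, "trilinear")$data[idx]
      -pctemplate:::nmi_from_values(tv, sv, 64, rng_t, rng_s,
                                    partial_volume = TRUE)
    }
    res <- powell_minimize(obj, z, xtol = 1e-3, ftol = 1e-5,
                           max_iter = iters[k])
    z <- res$par
  }
  direct <- affine_transform(id12 + z * sc)
  # both routes must land on the same registration (sub-0.1-voxel agreement)
  pts <- grid_world_coords(model$components[[1]])
  pts <- pts[seq(1, nrow(pts), by = 53), ]
  d <- sqrt(rowSums((apply_transform(chain$affine$matrix, pts) -
                       apply_transform(direct$matrix, pts))^2))
  expect_lt(max(d), 0.2)
})

test_that("the NMI objective never worsens within a stage", {
  model <- std_model()
  atlas <- std_atlas_raw()
  tmpl <- synthesize_template(model, 0.3)$volume
  A <- affine_transform(c(3, 1, -2, 0.04, -0.02, 0.03, 1.02, 0.97, 1.01, 0, 0, 0))
  subj <- resample(tmpl, solve(A$matrix), tmpl, "trilinear")
  chain <- register_adaptive(subj, model, default_config(),
                             mask_volume_from(atlas$aux$brain_noventricles,
                                              model$components[[1]]))
  for (nm in grep("^stage", names(chain$report), value = TRUE)) {
    r <- chain$report[[nm]]
    expect_gte(r$nmi_end, r$nmi_start - 1e-9)
  }
})

test_that("configuration loading merges user overrides over defaults", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("nmi_bins: 32", "powell:", "  xtol: 0.01"), p)
  cfg <- load_config(p)
  expect_equal(cfg$nmi_bins, 32)
  expect_equal(cfg$powell$xtol, 0.01)
  expect_equal(cfg$powell$ftol, default_config()$powell$ftol)
})

test_that("a chain serializes to JSON and back", {
  model <- std_model()
  dom <- poly_domain_from_grid(model$components[[1]])
  poly <- polynomial_transform(matrix(rnorm(30, sd = 0.1), 3, 10), dom)
  sm <- make_smoothed_mask(array(as.numeric(std_atlas_raw()$aux$cereb_brainstem),
                                 std_anatomy()$shape), 3,
                           model$components[[1]])
  ch <- transform_chain(affine_transform(c(1, 2, 3, 0.01, 0.02, 0.03,
                                           1.01, 0.99, 1, 0.001, 0, 0)),
                        poly,
                        list(rigid = rigid_transform(c(1, -1, 0.5, 0.01, 0, 0)),
                             blend = sm),
                        weight = 0.37)
  path <- file.path(withr::local_tempdir(), "chain.json")
  save_chain(ch, path)
  ch2 <- load_chain(path)
  expect_equal(ch2$affine$parameters, ch$affine$parameters, tolerance = 1e-12)
  expect_equal(ch2$polynomial$coefficients, ch$polynomial$coefficients,
               tolerance = 1e-12)
  expect_equal(ch2$weight, 0.37)
  pts <- matrix(rnorm(30, sd = 20), 10, 3)
  expect_equal(apply_transform(ch2, pts), apply_transform(ch, pts),
               tolerance = 1e-4)
})
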