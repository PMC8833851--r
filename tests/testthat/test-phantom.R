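test_that("anatomy contains every label, deterministically, with a bounded pons", {
  a1 <- std_anatomy()
  a2 <- make_anatomy()
  expect_identical(a1$labels, a2$labels)
  expect_setequal(unique(as.integer(a1$labels)), 0:7)
  # pons inside the brain-stem bounding box
  stem <- which(a1$labels == 6L, arr.ind = TRUE)
  pons <- which(a1$labels == 7L, arr.ind = TRUE)
  for (j in 1:3) {
    expect_gte(min(pons[, j]), min(stem[, j]))
    expect_lte(max(pons[, j]), max(stem[, j]))
  }
  expect_error(make_anatomy(shape = c(16, 64, 54)), class = "pct_value_error")
})

test_that("burden changes only cortical gray matter before blurring", {
  anat <- std_anatomy()
  v0 <- render_uptake(anat, 0, psf_fwhm_mm = 0)
  v1 <- render_uptake(anat, 1, psf_fwhm_mm = 0)
  d <- v1$data - v0$data
  expect_true(all(d[anat$labels != 1L] == 0))
  expect_true(all(d[anat$labels == 1L] > 0))
  expect_error(render_uptake(anat, 1.2), class = "pct_value_error")
})

test_that("subject generation is reproducible and respects the noise model", {
  anat <- std_anatomy()
  tr0 <- phantom_truth(0.3, affine_transform(), noise_sigma = 0, seed = 5)
  s0 <- generate_subject(anat, tr0)
  expect_equal(s0$volume$data, render_uptake(anat, 0.3)$data,
               tolerance = 1e-12)

  trn <- phantom_truth(0.3, affine_transform(), noise_sigma = 0.05, seed = 5)
  sa <- generate_subject(anat, trn)
  sb <- generate_subject(anat, trn)
  expect_identical(sa$volume$data, sb$volume$data)

  bm <- anat$labels > 0
  resid <- sa$volume$data - s0$volume$data
  target <- 0.05 * mean(s0$volume$data[bm])
  expect_lt(abs(sd(resid[bm]) / target - 1), 0.05)
})

test_that("cohorts are stratified, pons-normalized and reproducible", {
  coh <- std_cohort()
  expect_equal(sort(coh$burdens), seq(0, 1, length.out = 20))
  pm <- std_anatomy()$labels == 7L
  for (v in coh$stack$volumes[c(1, 10, 20)])
    expect_equal(mean(v$data[pm]), 1, tolerance = 1e-12)
  coh2 <- generate_cohort(std_anatomy(), n = 20, seed = 42)
  expect_identical(coh$stack$volumes[[7]]$data, coh2$stack$volumes[[7]]$data)
  expect_error(generate_cohort(std_anatomy(), n = 3), class = "pct_value_error")
})

test_that("the template continuum has monotonically increasing cortical uptake", {
  model <- std_model()
  atlas <- std_atlas_raw()
  wm <- std_anatomy()$labels == 2L
  ratios <- vapply(seq(-1, 1, 0.25), function(w) {
    t <- synthesize_template(model, w)$volume
    mean(t$data[atlas$masks$CTX]) / mean(t$data[wm])
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("a local reference-block shift moves only the intended labels", {
  anat <- std_anatomy()
  shift <- rigid_transform(c(0, 0, 4, 0, 0, 0))
  tr <- phantom_truth(0.4, affine_transform(), local_shift = shift,
                      noise_sigma = 0, seed = 1)
  s <- generate_subject(anat, tr)$volume
  ref <- generate_subject(anat, phantom_truth(0.4, affine_transform(),
                                              noise_sigma = 0, seed = 1))$volume
  d <- abs(s$data - ref$data) > 1e-9
  # differences confined to the inferior half of the volume (the
  # cerebellum / brain-stem block and its blur halo)
  zidx <- which(d, arr.ind = TRUE)[, 3]
  expect_lt(max(zidx), anat$shape[3] * 0.6)
  expect_gt(sum(d), 0)
})

test_that("recovered SUVR ordering matches true burden ordering end to end", {
  anat <- std_anatomy()
  model <- std_model()
  atlas <- std_atlas()
  held <- generate_cohort(anat, n = 6, warp_sampler = TRUE,
                          noise_sigma = 0, seed = 99)
  suvr <- vapply(seq_len(6), function(i) {
    ch <- suppressWarnings(register_subject(held$subjects[[i]], model, atlas,
                                            default_config()))
    quantify_subject(held$subjects[[i]], ch, atlas, model)$suvr[["pons"]]
  }, numeric(1))
  expect_equal(cor(suvr, held$burdens, method = "spearman"), 1)
})
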