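test_that("atlas construction validates region nesting and disjointness", {
  atlas <- std_atlas_raw()
  expect_s3_class(atlas, "voi_atlas")
  m <- atlas$masks
  expect_false(any(m$CG & !m$WC))
  expect_false(any(m$WC & !m$WC_brainstem))
  expect_false(any(m$ThPons & !m$pons))
  expect_false(any(m$CTX & m$WC_brainstem))
  bad <- m
  bad$CG <- m$WC_brainstem   # CG no longer inside WC
  expect_error(voi_atlas(bad, list(affine = std_anatomy()$affine)),
               class = "pct_atlas_error")
})

test_that("intensity normalization pins the reference mean to 1 and is idempotent", {
  atlas <- std_atlas_raw()
  anat <- std_anatomy()
  k <- as_volume(array(7, anat$shape), anat$affine)
  expect_true(all(intensity_normalize(k, atlas)$data == 1))
  v <- render_uptake(anat, 0.5)
  nv <- intensity_normalize(v, atlas, "pons")
  expect_equal(mean(nv$data[atlas$masks$pons]), 1, tolerance = 1e-12)
  expect_equal(intensity_normalize(nv, atlas, "pons")$data, nv$data,
               tolerance = 1e-12)
})

test_that("ThPons selection matches the counting oracle and stays inside the pons", {
  pons <- array(0, c(10, 10, 2)); pons[, , 1] <- 1
  ref <- as_volume(array(c(1:100, rep(0, 100)), c(10, 10, 2)), diag(4))
  th <- make_thpons(pons, ref, 0.85)
  expect_equal(sum(th), 15)
  expect_false(any(th & !pons))
  full <- make_thpons(pons, ref, 1e-9)
  expect_equal(sum(full), 100)
})

test_that("SUVR is the target/reference mean ratio and is scale invariant", {
  atlas <- std_atlas_raw()
  anat <- std_anatomy()
  v <- render_uptake(anat, 0.7)
  nv <- intensity_normalize(v, atlas)
  s <- compute_suvr(nv, atlas, "CTX", "pons")
  expect_equal(s, mean(nv$data[atlas$masks$CTX]) /
                 mean(nv$data[atlas$masks$pons]), tolerance = 1e-12)
  expect_equal(compute_suvr(nv, atlas, "CTX", "CTX"), 1)
  # scale invariance: SUVR computed from the raw image equals the
  # normalize-then-average route to near machine precision
  raw_ratio <- mean(v$data[atlas$masks$CTX]) / mean(v$data[atlas$masks$pons])
  expect_equal(s, raw_ratio, tolerance = 1e-10)
  v2 <- as_volume(v$data * 17.3, v$affine)
  expect_equal(compute_suvr(intensity_normalize(v2, atlas), atlas,
                            "CTX", "pons"), s, tolerance = 1e-10)
})

test_that("blur-free rendering matches the closed-form uptake ratio", {
  anat <- std_anatomy()
  atlas <- std_atlas_raw()
  a <- 0.35
  v <- render_uptake(anat, a, psf_fwhm_mm = 0, heterogeneity = 0)
  expect_equal(mean(v$data[atlas$masks$CTX]), 0.8 + 1.6 * a,
               tolerance = 1e-10)
  expect_equal(mean(v$data[atlas$masks$pons]), 2.2, tolerance = 1e-10)
  s <- compute_suvr(intensity_normalize(v, atlas), atlas, "CTX", "pons")
  expect_equal(s, (0.8 + 1.6 * a) / 2.2, tolerance = 1e-10)
})

test_that("quantification through an identity chain equals the direct computation", {
  anat <- std_anatomy()
  model <- std_model()
  atlas <- std_atlas()
  subj <- generate_subject(anat, phantom_truth(0.6, affine_transform(),
                                               noise_sigma = 0.05, seed = 9))$volume
  ch <- transform_chain(affine_transform(), NULL, NULL, 0.2)
  rep1 <- quantify_subject(subj, ch, atlas, model, id = "t1")
  nv <- intensity_normalize(subj, atlas, "pons")
  for (r in names(rep1$suvr))
    expect_equal(rep1$suvr[[r]], compute_suvr(nv, atlas, "CTX", r),
                 tolerance = 1e-10)
  rep2 <- quantify_subject(subj, ch, atlas, model, id = "t1")
  expect_identical(rep1$suvr, rep2$suvr)
  expect_equal(rep1$weight, 0.2)
  # report writers produce the documented row
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_suvr_report(rep1, jp, cp)
  row <- utils::read.csv(cp)
  expect_named(row, c("id", "w", "suvr_cg", "suvr_wc", "suvr_wc_bs",
                      "suvr_pons", "suvr_thpons", "warnings"))
  expect_equal(row$suvr_pons, rep1$suvr[["pons"]], tolerance = 1e-6)
})

test_that("cortical SUVR increases strictly with true burden", {
  anat <- std_anatomy()
  atlas <- std_atlas_raw()
  s <- vapply(seq(0, 1, 0.25), function(a) {
    v <- render_uptake(anat, a)
    compute_suvr(intensity_normalize(v, atlas), atlas, "CTX", "pons")
  }, numeric(1))
  expect_true(all(diff(s) > 0))
})
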