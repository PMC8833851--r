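# Shared fixtures, built once per test run. The standard phantom cohort and
# its principal-component model back most module tests; registration-heavy
# checks live in test-acceptance.R.

fixture_env <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

std_anatomy <- function() {
  if (is.null(fixture_env$anat)) fixture_env$anat <- make_anatomy()
  fixture_env$anat
}

std_cohort <- function() {
  if (is.null(fixture_env$cohort))
    fixture_env$cohort <- generate_cohort(std_anatomy(), n = 20, seed = 42)
  fixture_env$cohort
}

std_model <- function() {
  if (is.null(fixture_env$model)) {
    anat <- std_anatomy()
    atlas <- std_atlas_raw()
    m <- fit_pc_model(std_cohort()$stack, k = 2, mask = anat$labels > 0)
    fixture_env$model <- fix_component_signs(m, atlas$aux$brain,
                                             atlas$masks$CTX)
  }
  fixture_env$model
}

std_atlas_raw <- function() {
  if (is.null(fixture_env$atlas_raw))
    fixture_env$atlas_raw <- atlas_from_anatomy(std_anatomy())
  fixture_env$atlas_raw
}

std_atlas <- function() {
  if (is.null(fixture_env$atlas))
    fixture_env$atlas <- atlas_from_anatomy(std_anatomy(),
                                            reference_image = std_model()$mean_image)
  fixture_env$atlas
}

rand_volume <- function(dims = c(4, 4, 4), seed = 1, affine = diag(4)) {
  set.seed(seed)
  as_volume(array(rnorm(prod(dims)), dims), affine)
}

mask_volume_from <- function(arr, grid) {
  as_volume(array(as.numeric(arr > 0), dim(arr)), grid$affine)
}
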