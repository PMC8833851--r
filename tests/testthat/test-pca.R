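# The Gram-path decomposition is checked against independent oracles: a
# per-voxel loop for the mean, a closed form for the two-image case, and a
# dense p x p covariance eigendecomposition at tiny p.

make_stack <- function(arrs, affine = diag(4)) {
  image_stack(lapply(arrs, function(a) as_volume(a, affine)))
}

test_that("the mean image matches a direct per-voxel loop", {
  set.seed(31)
  arrs <- replicate(5, array(rnorm(64), c(4, 4, 4)), simplify = FALSE)
  st <- make_stack(arrs)
  mu <- compute_mean(st)
  ref <- array(0, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    ref[i, j, k] <- sum(vapply(arrs, function(a) a[i, j, k], 1)) / 5
  expect_equal(mu$data, ref, tolerance = 1e-12)

  same <- make_stack(replicate(3, arrs[[1]], simplify = FALSE))
  expect_equal(compute_mean(same)$data, arrs[[1]], tolerance = 1e-12)
  two <- make_stack(list(array(0, c(4, 4, 4)), array(2, c(4, 4, 4))))
  expect_true(all(compute_mean(two)$data == 1))
})

test_that("a zero-variance stack yields all-zero eigenvalues", {
  a <- array(rnorm(64), c(4, 4, 4))
  st <- make_stack(replicate(3, a, simplify = FALSE))
  m <- fit_pc_model(st, k = 1)
  expect_true(all(abs(m$eigenvalues) < 1e-20))
  expect_equal(m$mean_image$data, a, tolerance = 1e-12)
  expect_equal(explained_variance_fraction(m, 1), 1)
})

test_that("the two-image case matches the closed-form rank-1 solution", {
  set.seed(32)
  mu <- array(rnorm(64), c(4, 4, 4))
  d <- array(rnorm(64), c(4, 4, 4))
  st <- make_stack(list(mu + d, mu - d))
  m <- fit_pc_model(st, k = 1)
  # C is 2x2 with entries +/- ||d||^2; nonzero eigenvalue = 2||d||^2/(n-1)
  expect_equal(m$eigenvalues[1], 2 * sum(d^2), tolerance = 1e-10)
  # the single eigenimage is proportional to d with norm sqrt((n-1)*lambda)
  cosang <- sum(m$components[[1]]$data * d) /
    sqrt(sum(m$components[[1]]$data^2) * sum(d^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-10)
  expect_equal(sqrt(sum(m$components[[1]]$data^2)),
               sqrt(m$eigenvalues[1]), tolerance = 1e-8)
})

test_that("Gram-path eigenpairs match a dense voxel-covariance oracle", {
  set.seed(33)
  arrs <- replicate(6, array(rnorm(216), c(6, 6, 6)), simplify = FALSE)
  st <- make_stack(arrs)
  m <- fit_pc_model(st, k = 2)
  X <- vapply(arrs, as.numeric, numeric(216))
  D <- X - rowMeans(X)
  Cfull <- D %*% t(D) / (ncol(X) - 1)        # dense p x p covariance
  ev <- eigen(Cfull, symmetric = TRUE)
  expect_equal(m$eigenvalues, ev$values[1:5], tolerance = 1e-8)
  for (i in 1:2) {
    ci <- as.numeric(m$components[[i]]$data)
    cosang <- sum(ci * ev$vectors[, i]) / sqrt(sum(ci^2))
    expect_equal(abs(cosang), 1, tolerance = 1e-8)
  }
})

test_that("every training image is reconstructed from mean plus all components", {
  set.seed(34)
  arrs <- replicate(6, array(rnorm(216, sd = 2), c(6, 6, 6)), simplify = FALSE)
  st <- make_stack(arrs)
  m <- fit_pc_model(st, k = 5)
  mu <- as.numeric(m$mean_image$data)
  E <- vapply(m$components, function(v) as.numeric(v$data), numeric(216))
  En <- sweep(E, 2, sqrt(colSums(E^2)), "/")    # unit-norm directions
  for (i in seq_along(arrs)) {
    x <- as.numeric(arrs[[i]])
    d <- x - mu
    rec <- mu + En %*% crossprod(En, d)
    expect_lt(sqrt(sum((rec - x)^2)) / sqrt(sum(x^2)), 1e-4)
  }
})

test_that("explained variance fraction is monotone and reaches 1", {
  set.seed(35)
  arrs <- replicate(6, array(rnorm(216), c(6, 6, 6)), simplify = FALSE)
  m <- fit_pc_model(make_stack(arrs), k = 2)
  fr <- vapply(1:5, function(j) explained_variance_fraction(m, j), 1)
  expect_true(all(diff(fr) >= -1e-12))
  expect_equal(fr[5], 1, tolerance = 1e-12)
  expect_error(explained_variance_fraction(m, 0), class = "pct_value_error")
})

test_that("template synthesis is affine in the weight", {
  m <- std_model()
  t0 <- synthesize_template(m, 0)
  expect_equal(t0$volume$data, m$components[[1]]$data, tolerance = 1e-12)
  tp <- synthesize_template(m, 1); tn <- synthesize_template(m, -1)
  expect_equal((tp$volume$data + tn$volume$data) / 2,
               m$components[[1]]$data, tolerance = 1e-10)
  t04 <- synthesize_template(m, 0.4)
  expect_equal(t04$volume$data - t0$volume$data,
               0.4 * m$components[[2]]$data, tolerance = 1e-10)
  expect_warning(tc <- synthesize_template(m, 1.7), "clamped")
  expect_equal(tc$weight, 1)
})

test_that("sign fixing is idempotent and flips only negated components", {
  m <- std_model()
  atlas <- std_atlas_raw()
  fixed <- fix_component_signs(m, atlas$aux$brain, atlas$masks$CTX)
  expect_equal(fixed$components[[1]]$data, m$components[[1]]$data)
  neg <- m
  neg$components[[2]]$data <- -neg$components[[2]]$data
  ref <- fix_component_signs(neg, atlas$aux$brain, atlas$masks$CTX)
  expect_equal(ref$components[[2]]$data, m$components[[2]]$data,
               tolerance = 1e-12)
  # synthesize(w) after fixing equals synthesize(-w) before
  expect_equal(synthesize_template(ref, 0.3)$volume$data,
               synthesize_template(neg, -0.3)$volume$data, tolerance = 1e-12)
  twice <- fix_component_signs(ref, atlas$aux$brain, atlas$masks$CTX)
  expect_identical(twice$components[[2]]$data, ref$components[[2]]$data)
})

test_that("a model persists through its directory representation", {
  m <- std_model()
  dir <- withr::local_tempdir()
  save_pc_model(m, dir)
  m2 <- load_pc_model(dir)
  expect_equal(m2$eigenvalues, m$eigenvalues, tolerance = 1e-6)
  expect_equal(m2$n_train, m$n_train)
  expect_equal(m2$mean_image$data, m$mean_image$data, tolerance = 1e-5)
  expect_equal(m2$components[[2]]$data, m$components[[2]]$data,
               tolerance = 1e-5)
})

test_that("stack and model constructors validate their preconditions", {
  a <- as_volume(array(1:8, c(2, 2, 2)))
  expect_error(image_stack(list(a)), class = "pct_value_error")
  b <- as_volume(array(1:27, c(3, 3, 3)))
  expect_error(image_stack(list(a, b)), class = "pct_grid_mismatch_error")
  st <- image_stack(list(a, a, a))
  expect_error(fit_pc_model(st, k = 3), class = "pct_value_error")
})
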