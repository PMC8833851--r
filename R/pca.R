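# Principal-component template model. The decomposition works in subject
# space: with D the p x n matrix of mean-centred images, the n x n Gram-form
# covariance C = D'D/(n-1) is eigendecomposed and eigenimages are obtained by
# projecting D onto the eigenvectors, so the p x p voxel covariance is never
# materialized. Eigenimages keep the resulting intensity-like scale
# (||I_PCi|| = sqrt((n-1) lambda_i)); they are not re-normalized, so the
# appearance weight w in [-1, 1] spans the training appearance range.

#' Bundle volumes sharing one grid into an image stack
#'
#' @param volumes List of `pet_volume`s on an identical grid (n >= 2).
#' @param ids Optional character vector of subject identifiers.
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(volumes, ids = NULL) {
  n <- length(volumes)
  if (n < 2L) pct_error("an image stack needs at least 2 volumes",
                        "pct_value_error")
  for (i in seq_len(n)) stopifnot_same_grid(volumes[[1]], volumes[[i]])
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  structure(list(volumes = volumes, ids = as.character(ids)),
            class = "image_stack")
}

stack_matrix <- function(stack, mask = NULL) {
  sel <- if (is.null(mask)) TRUE else {
    m <- if (inherits(mask, "pet_volume")) mask$data else mask
    which(m > 0)
  }
  vapply(stack$volumes,
         function(v) as.numeric(v$data)[sel],
         numeric(if (isTRUE(sel)) length(stack$volumes[[1]]$data)
                 else length(sel)))
}

#' Voxel-wise mean image of a stack
#'
#' @param stack An `image_stack`.
#' @return `pet_volume` holding the arithmetic mean.
#' @export
compute_mean <- function(stack) {
  if (length(stack$volumes) == 0L)
    pct_error("empty stack", "pct_value_error")
  acc <- stack$volumes[[1]]$data
  for (v in stack$volumes[-1]) acc <- acc + v$data
  as_volume(acc / length(stack$volumes), stack$volumes[[1]]$affine)
}

embed_in_grid <- function(values, grid_vol, mask = NULL) {
  d <- dim(grid_vol$data)
  arr <- array(0, d)
  if (is.null(mask)) arr[] <- values
  else {
    m <- if (inherits(mask, "pet_volume")) mask$data else mask
    arr[m > 0] <- values
  }
  as_volume(arr, grid_vol$affine)
}

#' Fit the principal-component model of an image stack
#'
#' Centres the stack on its mean image, forms the n x n Gram-form covariance
#' C = D'D/(n-1), eigendecomposes it, and returns the top-k eigenimages
#' I_PCi = D q_i with eigenvalues sorted non-increasing. All n-1 eigenvalues
#' are retained in the model even when fewer eigenimages are kept, so
#' explained-variance fractions stay well defined.
#'
#' @param stack An `image_stack` (n >= 2).
#' @param k Number of eigenimages to retain (default and maximum: n - 1).
#' @param mask Optional brain mask (`pet_volume` or array); voxels outside it
#'   are excluded from the decomposition and set to 0 in the eigenimages.
#' @return Object of class `pc_model` with fields `mean_image`, `components`,
#'   `eigenvalues`, `n_train`, `grid`, `mask`, `flips`.
#' @export
fit_pc_model <- function(stack, k = NULL, mask = NULL) {
  n <- length(stack$volumes)
  if (is.null(k)) k <- n - 1L
  if (k >= n) pct_error("k must be <= n - 1", "pct_value_error")
  if (k < 1L) pct_error("k must be >= 1", "pct_value_error")
  X <- stack_matrix(stack, mask)
  mu <- rowMeans(X)
  D <- X - mu
  C <- crossprod(D) / (n - 1)
  ev <- eigen(C, symmetric = TRUE)
  lambda <- pmax(ev$values[seq_len(n - 1L)], 0)
  comps <- vector("list", k)
  grid_vol <- stack$volumes[[1]]
  for (i in seq_len(k)) {
    img <- as.numeric(D %*% ev$vectors[, i])
    comps[[i]] <- embed_in_grid(img, grid_vol, mask)
  }
  mean_vol <- embed_in_grid(mu, grid_vol, mask)
  structure(list(mean_image = mean_vol,
                 components = comps,
                 eigenvalues = lambda,
                 n_train = n,
                 grid = list(shape = dim(grid_vol$data),
                             affine = grid_vol$affine),
                 mask = if (is.null(mask)) NULL else
                   (if (inherits(mask, "pet_volume")) mask$data else mask) > 0,
                 flips = rep(1, k)),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("<pc_model> %d training images, %d eigenimages retained\n",
              x$n_train, length(x$components)))
  tot <- sum(x$eigenvalues)
  if (tot > 0) {
    cum <- cumsum(x$eigenvalues) / tot
    k <- min(4L, length(cum))
    cat("  cumulative explained variance:",
        paste(sprintf("%.1f%%", 100 * cum[seq_len(k)]), collapse = ", "),
        if (length(cum) > k) "...", "\n")
  } else {
    cat("  zero total variance (identical training images)\n")
  }
  invisible(x)
}

#' @export
summary.pc_model <- function(object, ...) {
  tot <- sum(object$eigenvalues)
  data.frame(component = seq_along(object$eigenvalues),
             eigenvalue = object$eigenvalues,
             fraction = if (tot > 0) object$eigenvalues / tot else
               rep(NA_real_, length(object$eigenvalues)))
}

#' Fraction of variance explained by the first m components
#'
#' @param model A `pc_model`.
#' @param m Number of leading components (1 <= m <= n - 1).
#' @return Fraction in \[0, 1\]; 1 when the stack has zero variance.
#' @export
explained_variance_fraction <- function(model, m) {
  if (m < 1L) pct_error("m must be >= 1", "pct_value_error")
  if (m > length(model$eigenvalues))
    pct_error("m exceeds the number of stored eigenvalues", "pct_value_error")
  tot <- sum(model$eigenvalues)
  if (tot == 0) return(1)
  sum(model$eigenvalues[seq_len(m)]) / tot
}

#' Synthesize the adaptive template at appearance weight w
#'
#' The synthetic template is the linear combination I_PC1 + w I_PC2 of the
#' first two eigenimages; w = -1 corresponds to the amyloid-negative end of
#' the training appearance range and w = +1 to the amyloid-positive end
#' (after [fix_component_signs()]).
#'
#' @param model A `pc_model` with at least 2 components.
#' @param w Appearance weight in \[-1, 1\]; values outside are clamped with a
#'   warning.
#' @return Object of class `synthetic_template` with fields `volume`, `weight`.
#' @export
synthesize_template <- function(model, w) {
  if (length(model$components) < 2L)
    pct_error("model needs at least 2 components", "pct_component_error")
  if (w < -1 || w > 1) {
    warning(sprintf("weight %.3f outside [-1, 1]; clamped", w))
    w <- min(max(w, -1), 1)
  }
  vol <- as_volume(model$components[[1]]$data + w * model$components[[2]]$data,
                   model$grid$affine)
  structure(list(volume = vol, weight = w), class = "synthetic_template")
}

#' @export
predict.pc_model <- function(object, w = 0, ...) {
  synthesize_template(object, w)
}

#' Fix the arbitrary signs of the eigenimages
#'
#' Eigenvector signs are mathematically arbitrary; this pins the convention
#' that the first eigenimage has positive mean inside the brain mask and the
#' second has positive mean inside the cortical mask, so w = +1 is the
#' amyloid-positive end of the template continuum. Higher components are
#' oriented by the brain mask. Idempotent.
#'
#' @param model A `pc_model`.
#' @param brain_mask Brain mask (`pet_volume` or array), non-empty.
#' @param ctx_mask Cortical mask used for the second component; defaults to
#'   `brain_mask`.
#' @return The model with signs fixed and flips recorded in `$flips`.
#' @export
fix_component_signs <- function(model, brain_mask, ctx_mask = brain_mask) {
  bm <- if (inherits(brain_mask, "pet_volume")) brain_mask$data else brain_mask
  cm <- if (inherits(ctx_mask, "pet_volume")) ctx_mask$data else ctx_mask
  if (sum(bm > 0) == 0 || sum(cm > 0) == 0)
    pct_error("empty positivity mask", "pct_empty_mask_error")
  for (i in seq_along(model$components)) {
    m <- if (i == 2L) cm else bm
    mu <- mean(model$components[[i]]$data[m > 0])
    if (mu < 0) {
      model$components[[i]]$data <- -model$components[[i]]$data
      model$flips[i] <- -model$flips[i]
    }
  }
  model
}

#' Persist a principal-component model to a directory
#'
#' Writes `mean.nii.gz`, `pc01.nii.gz` ... and `model.json` (eigenvalues,
#' training count, sign flips), plus `mask.nii.gz` when a mask was used.
#'
#' @param model A `pc_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_pc_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(model$mean_image, file.path(dir, "mean.nii.gz"))
  for (i in seq_along(model$components))
    write_volume(model$components[[i]], file.path(dir, sprintf("pc%02d.nii.gz", i)))
  if (!is.null(model$mask))
    write_volume(as_volume(array(as.numeric(model$mask), model$grid$shape),
                           model$grid$affine),
                 file.path(dir, "mask.nii.gz"))
  meta <- list(eigenvalues = model$eigenvalues, n_train = model$n_train,
               flips = model$flips, n_components = length(model$components))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a principal-component model saved by [save_pc_model()]
#'
#' @param dir Model directory.
#' @return A `pc_model`.
#' @export
load_pc_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  mean_vol <- load_volume(file.path(dir, "mean.nii.gz"))
  comps <- lapply(seq_len(meta$n_components), function(i)
    load_volume(file.path(dir, sprintf("pc%02d.nii.gz", i))))
  mask_path <- file.path(dir, "mask.nii.gz")
  mask <- if (file.exists(mask_path)) load_volume(mask_path)$data > 0 else NULL
  structure(list(mean_image = mean_vol, components = comps,
                 eigenvalues = as.numeric(meta$eigenvalues),
                 n_train = as.integer(meta$n_train),
                 grid = list(shape = dim(mean_vol$data),
                             affine = mean_vol$affine),
                 mask = mask, flips = as.numeric(meta$flips)),
            class = "pc_model")
}
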