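#' @useDynLib pctemplate, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optimize quantile rnorm sd cor setNames
#' @importFrom utils write.csv
NULL

pct_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "pct_error")))
}

#' Create a volume from an array and a voxel-to-world affine
#'
#' A volume is the universal image carrier of the package: a 3-D scalar array
#' together with a 4x4 affine mapping 0-based voxel indices (i, j, k) to world
#' coordinates in millimetres, following the NIfTI convention.
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 invertible voxel-index-to-world matrix (mm).
#' @return An object of class `pet_volume` with fields `data` and `affine`.
#' @export
as_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L)
    pct_error("data must be a 3-D array", "pct_dim_error")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    pct_error("affine must be an invertible 4x4 matrix", "pct_affine_error")
  storage.mode(data) <- "double"
  structure(list(data = data, affine = affine), class = "pet_volume")
}

#' @export
dim.pet_volume <- function(x) dim(x$data)

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x$data)
  vs <- voxel_size(x)
  cat(sprintf("<pet_volume> %d x %d x %d voxels, %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Voxel dimensions of a volume in mm
#' @param v A `pet_volume`.
#' @return Numeric length-3 vector of voxel edge lengths.
#' @export
voxel_size <- function(v) {
  sqrt(colSums(v$affine[1:3, 1:3]^2))
}

same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$data) == dim(b$data)) && max(abs(a$affine - b$affine)) <= tol
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b))
    pct_error("volumes are not on the same grid", "pct_grid_mismatch_error")
}

#' Load a single-frame NIfTI-1 volume
#'
#' Reads a 3-D NIfTI-1 file, casting voxel data to double. The affine is taken
#' from the header with the sform preferred over the qform when both are set.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `pet_volume`.
#' @export
load_volume <- function(path) {
  if (!file.exists(path))
    pct_error(sprintf("file not found: %s", path), "pct_missing_file_error")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1, drop = TRUE]
    d <- dim(img)
  }
  if (length(d) != 3L)
    pct_error(sprintf("expected a 3-D volume, got %d dimensions", length(d)),
              "pct_4d_input_error")
  # sform preferred when present (useQuaternionFirst = FALSE)
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = c(4L, 4L))
  data <- as.array(img)
  attributes(data) <- list(dim = d)
  if (anyNA(data))
    pct_error(sprintf("volume contains NaN/NA voxels: %s", path),
              "pct_nan_input_error")
  as_volume(data, aff)
}

#' Write a volume to NIfTI-1
#'
#' Data are stored as float32; the affine is written to both sform and qform.
#'
#' @param v A `pet_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  img <- RNifti::asNifti(v$data)
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::qform(img) <- structure(v$affine, code = 1L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Gaussian-smooth a volume
#'
#' Separable Gaussian filter with per-axis sigma derived from a FWHM in mm and
#' the voxel size; kernels are truncated at 3 sigma and renormalized at the
#' borders so constant images stay constant.
#'
#' @param v A `pet_volume`.
#' @param fwhm_mm Full-width-at-half-maximum in mm (scalar or length-3).
#' @return Smoothed `pet_volume` on the same grid.
#' @export
smooth_volume <- function(v, fwhm_mm) {
  if (any(fwhm_mm < 0)) pct_error("fwhm must be >= 0", "pct_value_error")
  if (all(fwhm_mm == 0)) return(v)
  fwhm_mm <- rep_len(fwhm_mm, 3L)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_size(v)
  out <- cpp_gaussian_blur(v$data, dim(v$data), sigma_vox)
  as_volume(array(out, dim(v$data)), v$affine)
}

#' World coordinates of every voxel centre of a grid
#'
#' Returns the N x 3 matrix (mm) of voxel-centre world coordinates in
#' column-major (R array) order.
#'
#' @param v `pet_volume` defining the grid.
#' @return N x 3 numeric matrix.
#' @export
grid_world_coords <- function(v) {
  d <- dim(v$data)
  idx <- cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  )
  idx %*% t(v$affine[1:3, 1:3]) +
    matrix(v$affine[1:3, 4], nrow(idx), 3, byrow = TRUE)
}

world_to_voxel <- function(v, pts) {
  inv <- solve(v$affine)
  pts %*% t(inv[1:3, 1:3]) + matrix(inv[1:3, 4], nrow(pts), 3, byrow = TRUE)
}

sample_at_world <- function(v, pts, interpolation = "trilinear", fill = 0) {
  vox <- world_to_voxel(v, pts)
  cpp_sample_volume(v$data, dim(v$data), vox,
                    nearest = identical(interpolation, "nearest"), fill = fill)
}

#' Resample a volume onto a target grid under a coordinate transform
#'
#' Pull-back resampling: for every voxel of the target grid, the transform maps
#' its world coordinate into the moving volume's world space and the moving
#' image is sampled there. Points falling outside the moving volume are filled
#' with 0.
#'
#' @param moving `pet_volume` to be sampled.
#' @param transform `NULL` (identity), a 4x4 world-to-world matrix, an
#'   `affine_transform`, or a `transform_chain` mapping target world
#'   coordinates to moving world coordinates.
#' @param target_grid `pet_volume` (or list with `data` dims and `affine`)
#'   defining the output grid.
#' @param interpolation `"trilinear"` (intensity images) or `"nearest"`
#'   (label images).
#' @return `pet_volume` on the target grid.
#' @export
resample <- function(moving, transform = NULL, target_grid = moving,
                     interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (abs(det(target_grid$affine)) < 1e-12)
    pct_error("target grid affine is not invertible", "pct_affine_error")
  pts <- grid_world_coords(target_grid)
  pts <- apply_transform(transform, pts)
  vals <- sample_at_world(moving, pts, interpolation)
  as_volume(array(vals, dim(target_grid$data)), target_grid$affine)
}

#' Build a multiresolution pyramid
#'
#' Each coarser level is produced by Gaussian pre-smoothing followed by
#' subsampling; the finest level is the unmodified input. Levels are ordered
#' coarsest first.
#'
#' @param v `pet_volume`.
#' @param n_levels Number of levels (>= 1).
#' @param factor Integer downsampling factor between levels.
#' @param smoothing_fwhm_vox Pre-smoothing FWHM, in voxels of the level being
#'   reduced, applied before each subsampling step.
#' @return Object of class `volume_pyramid`: list with `levels` (coarsest
#'   first) and `factors`.
#' @export
build_pyramid <- function(v, n_levels = 3L, factor = 2L,
                          smoothing_fwhm_vox = 2) {
  if (n_levels < 1L) pct_error("n_levels must be >= 1", "pct_value_error")
  d <- dim(v$data)
  if (any(ceiling(d / factor^(n_levels - 1)) < 8) && n_levels > 1L)
    pct_error("volume too small for requested pyramid levels",
              "pct_pyramid_error")
  levels <- vector("list", n_levels)
  levels[[n_levels]] <- v
  cur <- v
  if (n_levels > 1L) {
    for (k in seq(n_levels - 1L, 1L)) {
      fwhm_mm <- smoothing_fwhm_vox * voxel_size(cur)
      sm <- smooth_volume(cur, fwhm_mm)
      d <- dim(sm$data)
      ii <- seq(1, d[1], by = factor)
      jj <- seq(1, d[2], by = factor)
      kk <- seq(1, d[3], by = factor)
      sub <- sm$data[ii, jj, kk, drop = FALSE]
      aff <- sm$affine
      aff[1:3, 1:3] <- aff[1:3, 1:3] * factor
      cur <- as_volume(sub, aff)
      levels[[k]] <- cur
    }
  }
  structure(list(levels = levels,
                 factors = factor^rev(seq_len(n_levels) - 1L)),
            class = "volume_pyramid")
}
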