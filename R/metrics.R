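# Similarity metrics driving the registration cascade, plus the evaluation
# statistics. NMI uses a joint histogram with hard bin assignment over the
# masked voxels; entropies are in nats.

nmi_from_values <- function(va, vb, bins = 64L, ra = NULL, rb = NULL,
                            partial_volume = FALSE) {
  if (is.null(ra)) ra <- range(va)
  if (is.null(rb)) rb <- range(vb)
  if (ra[1] == ra[2] || rb[1] == rb[2]) {
    warning("constant image inside mask; NMI defined as 1")
    return(1)
  }
  h <- if (partial_volume)
    cpp_joint_hist_pv(va, vb, bins, ra[1], ra[2], rb[1], rb[2])
  else cpp_joint_hist(va, vb, bins, ra[1], ra[2], rb[1], rb[2])
  p <- h / sum(h)
  pa <- rowSums(p); pb <- colSums(p)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  hab <- -sum(p[p > 0] * log(p[p > 0]))
  if (hab == 0) {
    warning("zero joint entropy; NMI defined as 1")
    return(1)
  }
  (ha + hb) / hab
}

masked_values <- function(v, mask) {
  if (is.null(mask)) return(as.numeric(v$data))
  m <- if (inherits(mask, "pet_volume")) mask$data else mask
  as.numeric(v$data[m > 0])
}

#' Normalized mutual information between two volumes
#'
#' NMI = (H(A) + H(B)) / H(A, B) computed from a joint intensity histogram
#' over the masked voxels; values lie in \[1, 2\], higher meaning more shared
#' information. A constant image inside the mask has zero entropy; NMI is then
#' defined as 1 with a warning.
#'
#' @param a,b `pet_volume`s on the same grid.
#' @param mask Optional mask (`pet_volume` or logical/numeric array); `NULL`
#'   uses all voxels.
#' @param bins Number of histogram bins per image (>= 8).
#' @return Scalar NMI.
#' @export
normalized_mutual_information <- function(a, b, mask = NULL, bins = 64L) {
  stopifnot_same_grid(a, b)
  if (bins < 8L) pct_error("bins must be >= 8", "pct_value_error")
  va <- masked_values(a, mask)
  vb <- masked_values(b, mask)
  if (length(va) == 0) pct_error("empty mask", "pct_empty_mask_error")
  if (length(va) < 100L)
    pct_error("mask must contain at least 100 voxels", "pct_empty_mask_error")
  nmi_from_values(va, vb, bins)
}

#' Normalized cross-correlation between two volumes
#'
#' Pearson correlation of paired voxel intensities inside the mask.
#'
#' @param a,b `pet_volume`s on the same grid.
#' @param mask Mask (`pet_volume` or array); required non-empty.
#' @return Scalar in \[-1, 1\].
#' @export
normalized_cross_correlation <- function(a, b, mask = NULL) {
  stopifnot_same_grid(a, b)
  va <- masked_values(a, mask)
  vb <- masked_values(b, mask)
  if (length(va) == 0) pct_error("empty mask", "pct_empty_mask_error")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    pct_error("constant image within mask; NCC undefined",
              "pct_constant_input_error")
  stats::cor(va, vb)
}

#' Dice overlap coefficient of two binary masks
#'
#' 2|A n B| / (|A| + |B|); defined as 1 when both masks are empty.
#'
#' @param a,b Binary masks (`pet_volume` or logical/numeric arrays) on the
#'   same grid.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  ma <- if (inherits(a, "pet_volume")) a$data > 0 else a > 0
  mb <- if (inherits(b, "pet_volume")) b$data > 0 else b > 0
  if (!all(dim(ma) == dim(mb)))
    pct_error("masks are not on the same grid", "pct_grid_mismatch_error")
  sa <- sum(ma); sb <- sum(mb)
  if (sa + sb == 0) return(1)
  2 * sum(ma & mb) / (sa + sb)
}

#' Coefficient of determination between two SUVR series
#'
#' Squared Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length >= 3; `x` non-constant.
#' @return Scalar R-squared in \[0, 1\].
#' @export
correlation_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    pct_error("need equal-length vectors of length >= 3", "pct_value_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    pct_error("constant input; R^2 undefined", "pct_constant_input_error")
  stats::cor(x, y)^2
}
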