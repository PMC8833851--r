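# Spatial transforms. All transforms act on world coordinates (mm); the
# composition order of the 12-parameter affine is fixed as
# translation %*% rotation %*% shear %*% scale, with rotations applied as
# Rx %*% Ry %*% Rz about the world origin.

rot3 <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

#' 12-parameter affine transform
#'
#' Parameters are ordered as 3 translations (mm), 3 rotations (radians),
#' 3 scales, 3 shears (xy, xz, yz). The 4x4 matrix is composed as
#' T . R . Sh . Sc and acts on world coordinates.
#'
#' @param parameters Numeric length-12 vector.
#' @return Object of class `affine_transform` with `parameters` and `matrix`.
#' @export
affine_transform <- function(parameters = c(0, 0, 0, 0, 0, 0, 1, 1, 1, 0, 0, 0)) {
  p <- as.numeric(parameters)
  if (length(p) != 12L)
    pct_error("affine transform needs 12 parameters", "pct_value_error")
  if (any(p[7:9] <= 0))
    pct_error("affine scales must be strictly positive", "pct_value_error")
  R <- rot3(p[4:6])
  Sh <- rbind(c(1, p[10], p[11]), c(0, 1, p[12]), c(0, 0, 1))
  Sc <- diag(p[7:9])
  m <- diag(4)
  m[1:3, 1:3] <- R %*% Sh %*% Sc
  m[1:3, 4] <- p[1:3]
  structure(list(parameters = p, matrix = m), class = "affine_transform")
}

#' 6-parameter rigid transform
#'
#' 3 translations (mm) followed by 3 rotations (radians); the linear part is a
#' pure rotation (unit determinant).
#'
#' @param parameters Numeric length-6 vector.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(parameters = numeric(6)) {
  p <- as.numeric(parameters)
  if (length(p) != 6L)
    pct_error("rigid transform needs 6 parameters", "pct_value_error")
  m <- diag(4)
  m[1:3, 1:3] <- rot3(p[4:6])
  m[1:3, 4] <- p[1:3]
  stopifnot(abs(det(m[1:3, 1:3]) - 1) <= 1e-9)
  structure(list(parameters = p, matrix = m), class = "rigid_transform")
}

#' Second-order polynomial deformation
#'
#' An additive displacement (mm) added to affine-mapped coordinates. For each
#' output axis the displacement is a linear combination of the 10 monomials
#' \{1, x, y, z, x^2, y^2, z^2, xy, xz, yz\} evaluated on template coordinates
#' normalized to \[-1, 1\] per axis over the stated domain.
#'
#' @param coefficients 3 x 10 matrix (rows = x, y, z displacement in mm).
#' @param domain List with `center` and `halfwidth` (length-3, mm) defining
#'   the normalization of template world coordinates.
#' @return Object of class `polynomial_transform`.
#' @export
polynomial_transform <- function(coefficients = matrix(0, 3, 10), domain) {
  co <- as.matrix(coefficients)
  if (!all(dim(co) == c(3L, 10L)))
    pct_error("polynomial transform needs a 3 x 10 coefficient matrix",
              "pct_value_error")
  if (missing(domain) || any(domain$halfwidth <= 0))
    pct_error("polynomial transform needs a valid normalization domain",
              "pct_value_error")
  structure(list(coefficients = co, domain = domain),
            class = "polynomial_transform")
}

#' Polynomial normalization domain spanning a volume's grid
#'
#' Computes the world-space bounding box of the grid and returns the
#' center/halfwidth pair used to normalize coordinates to \[-1, 1\].
#'
#' @param grid `pet_volume`.
#' @return List with `center` and `halfwidth` (length-3, mm).
#' @export
poly_domain_from_grid <- function(grid) {
  pts <- rbind(c(0, 0, 0), dim(grid$data) - 1)
  corners <- as.matrix(expand.grid(pts[, 1], pts[, 2], pts[, 3]))
  w <- corners %*% t(grid$affine[1:3, 1:3]) +
    matrix(grid$affine[1:3, 4], 8, 3, byrow = TRUE)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  list(center = (lo + hi) / 2, halfwidth = (hi - lo) / 2)
}

# N x 10 monomial basis on normalized coordinates
poly_basis <- function(pts, domain) {
  u <- sweep(sweep(pts, 2, domain$center), 2, domain$halfwidth, "/")
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  cbind(1, x, y, z, x^2, y^2, z^2, x * y, x * z, y * z)
}

#' Evaluate the displacement field of a polynomial transform
#'
#' @param poly `polynomial_transform`.
#' @param pts N x 3 matrix of world coordinates (mm).
#' @param basis Optional precomputed monomial basis.
#' @return N x 3 matrix of displacements (mm).
#' @export
poly_displacement <- function(poly, pts, basis = NULL) {
  if (is.null(basis)) basis <- poly_basis(pts, poly$domain)
  basis %*% t(poly$coefficients)
}

#' Full transform chain of the registration cascade
#'
#' Maps template world coordinates to subject world coordinates:
#' the global part G(x) = A x + d(x) (affine plus optional polynomial
#' displacement), optionally followed by a locally blended rigid refinement
#' y(x) = (1 - s(x)) G(x) + s(x) G(R(x)) where s is a smoothed mask in
#' \[0, 1\] on the template grid.
#'
#' @param affine `affine_transform`.
#' @param polynomial `polynomial_transform` or `NULL`.
#' @param local_rigid `NULL` or list with `rigid` (`rigid_transform`) and
#'   `blend` (`pet_volume` with values in \[0, 1\]).
#' @param weight Accepted template appearance weight w.
#' @param report Optional list of per-stage metric records.
#' @return Object of class `transform_chain`.
#' @export
transform_chain <- function(affine = affine_transform(), polynomial = NULL,
                            local_rigid = NULL, weight = 0, report = list()) {
  structure(list(affine = affine, polynomial = polynomial,
                 local_rigid = local_rigid, weight = weight, report = report),
            class = "transform_chain")
}

#' @export
print.transform_chain <- function(x, ...) {
  cat("<transform_chain>\n")
  cat("  accepted template weight w =", format(x$weight, digits = 4), "\n")
  cat("  affine parameters:", paste(format(x$affine$parameters, digits = 4),
                                    collapse = " "), "\n")
  cat("  polynomial stage:", if (is.null(x$polynomial)) "none" else "3 x 10", "\n")
  cat("  local rigid refinement:",
      if (is.null(x$local_rigid)) "none"
      else paste(format(x$local_rigid$rigid$parameters, digits = 4),
                 collapse = " "), "\n")
  invisible(x)
}

apply_global <- function(chain, pts, basis = NULL) {
  A <- chain$affine$matrix
  out <- pts %*% t(A[1:3, 1:3]) + matrix(A[1:3, 4], nrow(pts), 3, byrow = TRUE)
  if (!is.null(chain$polynomial))
    out <- out + poly_displacement(chain$polynomial, pts, basis)
  out
}

#' Apply a transform to world-coordinate points
#'
#' @param transform `NULL` (identity), 4x4 matrix, `affine_transform`,
#'   `rigid_transform`, or `transform_chain`.
#' @param pts N x 3 matrix of world coordinates (mm).
#' @return N x 3 matrix of mapped world coordinates.
#' @export
apply_transform <- function(transform, pts) {
  if (is.null(transform)) return(pts)
  if (is.matrix(transform)) {
    return(pts %*% t(transform[1:3, 1:3]) +
             matrix(transform[1:3, 4], nrow(pts), 3, byrow = TRUE))
  }
  if (inherits(transform, c("affine_transform", "rigid_transform")))
    return(apply_transform(transform$matrix, pts))
  if (inherits(transform, "transform_chain")) {
    g <- apply_global(transform, pts)
    lr <- transform$local_rigid
    if (is.null(lr)) return(g)
    s <- sample_at_world(lr$blend, pts, "trilinear", fill = 0)
    if (all(s == 0)) return(g)
    gr <- apply_global(transform, apply_transform(lr$rigid$matrix, pts))
    g + s * (gr - g)
  } else {
    pct_error("unsupported transform type", "pct_value_error")
  }
}

invert_affine <- function(tr) {
  m <- if (is.matrix(tr)) tr else tr$matrix
  solve(m)
}
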