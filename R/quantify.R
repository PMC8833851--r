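# SUVR quantification over the VOI atlas. Regions follow the usual amyloid
# quantification set: cerebellar gray (CG), whole cerebellum (WC), WC plus
# brain stem, pons, the high-uptake-thresholded pons subset (ThPons) and the
# global cortical target (CTX). The region statistic is the unweighted voxel
# mean.

REFERENCE_REGIONS <- c("CG", "WC", "WC_brainstem", "pons", "ThPons")

#' Construct a VOI atlas from per-region masks
#'
#' Regions may overlap (CG is inside WC, WC inside WC plus brain stem, ThPons
#' inside pons), so the atlas stores one logical mask per region rather than a
#' single integer coding. Nesting and disjointness invariants are checked.
#'
#' @param masks Named list of logical arrays for `CG`, `WC`, `WC_brainstem`,
#'   `pons`, `ThPons`, `CTX`.
#' @param grid `pet_volume` (or list with `affine`) defining the template grid.
#' @param aux Optional named list of auxiliary masks (e.g. `brain`,
#'   `brain_noventricles`, `gm`, `cereb_brainstem`).
#' @return Object of class `voi_atlas`.
#' @export
voi_atlas <- function(masks, grid, aux = list()) {
  need <- c(REFERENCE_REGIONS, "CTX")
  if (!all(need %in% names(masks)))
    pct_error(paste("atlas needs masks:", paste(need, collapse = ", ")),
              "pct_value_error")
  m <- lapply(masks, function(x) {
    if (inherits(x, "pet_volume")) x$data > 0 else x > 0
  })
  subset_of <- function(a, b) !any(m[[a]] & !m[[b]])
  if (!subset_of("CG", "WC") || !subset_of("WC", "WC_brainstem"))
    pct_error("atlas nesting violated: CG in WC in WC_brainstem",
              "pct_atlas_error")
  if (!subset_of("pons", "WC_brainstem"))
    pct_error("atlas nesting violated: pons in WC_brainstem", "pct_atlas_error")
  if (!subset_of("ThPons", "pons"))
    pct_error("atlas nesting violated: ThPons in pons", "pct_atlas_error")
  if (any(m$CTX & m$WC_brainstem))
    pct_error("CTX must be disjoint from cerebellum/brain-stem regions",
              "pct_atlas_error")
  structure(list(masks = m,
                 grid = list(shape = dim(m$CTX), affine = grid$affine),
                 aux = lapply(aux, function(x)
                   if (inherits(x, "pet_volume")) x$data > 0 else x > 0)),
            class = "voi_atlas")
}

region_mask <- function(atlas, region) {
  m <- atlas$masks[[region]]
  if (is.null(m)) m <- atlas$aux[[region]]
  if (is.null(m)) pct_error(sprintf("unknown region: %s", region),
                            "pct_value_error")
  m
}

region_mean <- function(v, atlas, region) {
  m <- region_mask(atlas, region)
  if (!all(dim(v$data) == dim(m)))
    pct_error("volume and atlas grids differ", "pct_grid_mismatch_error")
  if (!any(m)) pct_error(sprintf("empty region: %s", region),
                         "pct_empty_mask_error")
  mean(v$data[m])
}

#' Intensity-normalize a volume by a reference region
#'
#' Divides the volume by the mean intensity within the reference region, so
#' the reference mean of the output is exactly 1.
#'
#' @param v `pet_volume` on the atlas grid.
#' @param atlas `voi_atlas`.
#' @param reference Region name; default `"pons"`.
#' @return Normalized `pet_volume`.
#' @export
intensity_normalize <- function(v, atlas, reference = "pons") {
  mu <- region_mean(v, atlas, reference)
  if (mu <= 0)
    pct_error(sprintf("non-positive reference mean in %s: %g", reference, mu),
              "pct_value_error")
  as_volume(v$data / mu, v$affine)
}

#' High-uptake pons subset (ThPons)
#'
#' Selects the pons voxels whose intensity in the reference image (the
#' training mean image, so the VOI is fixed per template) lies at or above
#' the within-pons `fraction` quantile. Same quantile convention as
#' [subsample_high_uptake()].
#'
#' @param pons Logical array or `pet_volume` pons mask.
#' @param reference_image `pet_volume` (typically the model mean image).
#' @param fraction Quantile fraction; default 0.85.
#' @return Logical array mask, a subset of `pons`.
#' @export
make_thpons <- function(pons, reference_image, fraction = 0.85) {
  m <- if (inherits(pons, "pet_volume")) pons$data > 0 else pons > 0
  if (!any(m)) pct_error("empty pons mask", "pct_empty_mask_error")
  if (fraction <= 0) return(m)
  vals <- reference_image$data[m]
  thr <- stats::quantile(vals, fraction, names = FALSE, type = 7)
  eps <- 1e-6 * (max(vals) - min(vals))
  sel <- m & (reference_image$data >= thr - eps)
  if (!any(sel))
    pct_error(sprintf("empty ThPons at threshold %.6g", thr),
              "pct_empty_mask_error")
  sel
}

#' Compute an SUVR
#'
#' Mean intensity over the target region divided by mean intensity over the
#' reference region.
#'
#' @param normalized `pet_volume` on the atlas grid (any global intensity
#'   scaling cancels in the ratio).
#' @param atlas `voi_atlas`.
#' @param target Target region name (default `"CTX"`).
#' @param reference Reference region name.
#' @return Scalar SUVR.
#' @export
compute_suvr <- function(normalized, atlas, target = "CTX",
                         reference = "pons") {
  tm <- region_mean(normalized, atlas, target)
  rm_ <- region_mean(normalized, atlas, reference)
  if (rm_ == 0) pct_error("zero reference mean", "pct_value_error")
  tm / rm_
}

#' Quantify a registered subject
#'
#' Resamples the subject through the transform chain onto the template grid,
#' intensity-normalizes by the pons, and reports the cortical SUVR against
#' each reference region, together with region means, voxel counts and the
#' accepted template weight.
#'
#' @param subject `pet_volume` in subject space.
#' @param chain Complete `transform_chain`.
#' @param atlas `voi_atlas` on the template grid.
#' @param model `pc_model` supplying the template grid.
#' @param id Subject identifier for the report.
#' @return Object of class `suvr_report`.
#' @export
quantify_subject <- function(subject, chain, atlas, model, id = "subject") {
  grid <- as_volume(array(0, atlas$grid$shape), atlas$grid$affine)
  resampled <- resample(subject, chain, grid, "trilinear")
  normalized <- intensity_normalize(resampled, atlas, "pons")
  regions <- c(REFERENCE_REGIONS, "CTX")
  means <- vapply(regions, function(r) region_mean(normalized, atlas, r),
                  numeric(1))
  counts <- vapply(regions, function(r) sum(region_mask(atlas, r)),
                   numeric(1))
  suvr <- vapply(REFERENCE_REGIONS, function(r)
    compute_suvr(normalized, atlas, "CTX", r), numeric(1))
  warnings <- as.character(chain$report$warnings %||% character())
  structure(list(id = id, weight = chain$weight, suvr = suvr,
                 region_means = means, voxel_counts = counts,
                 warnings = warnings),
            class = "suvr_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.suvr_report <- function(x, ...) {
  cat(sprintf("<suvr_report> subject %s (accepted w = %.3f)\n",
              x$id, x$weight))
  for (r in names(x$suvr))
    cat(sprintf("  SUVR CTX / %-12s = %.4f\n", r, x$suvr[[r]]))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.suvr_report <- function(x, ...) {
  data.frame(id = x$id, w = x$weight,
             suvr_cg = x$suvr[["CG"]], suvr_wc = x$suvr[["WC"]],
             suvr_wc_bs = x$suvr[["WC_brainstem"]],
             suvr_pons = x$suvr[["pons"]],
             suvr_thpons = x$suvr[["ThPons"]],
             warnings = paste(x$warnings, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Write an SUVR report as JSON and one-row CSV
#'
#' @param report `suvr_report`.
#' @param json_path Optional JSON output path.
#' @param csv_path Optional CSV output path.
#' @return The report, invisibly.
#' @export
write_suvr_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  invisible(report)
}
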