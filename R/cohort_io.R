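# Directory persistence for phantom cohorts, used by the command-line
# interface: NIfTI images plus a JSON ground-truth table.

#' Rebuild a phantom anatomy object from a label volume
#'
#' @param labels `pet_volume` holding the integer anatomy labels.
#' @return `phantom_anatomy`.
#' @export
anatomy_from_labels <- function(labels) {
  lab <- array(as.integer(round(labels$data)), dim(labels$data))
  structure(list(labels = lab, affine = labels$affine,
                 shape = dim(lab),
                 voxel_mm = mean(voxel_size(labels))),
            class = "phantom_anatomy")
}

serialize_truth <- function(t) {
  list(burden = t$burden,
       affine_parameters = t$affine$parameters,
       local_shift_parameters = if (!is.null(t$local_shift))
         t$local_shift$parameters,
       noise_sigma = t$noise_sigma, seed = t$seed,
       wm_level = t$wm_level %||% 1)
}

deserialize_truth <- function(o) {
  phantom_truth(as.numeric(o$burden),
                affine_transform(as.numeric(o$affine_parameters)),
                local_shift = if (!is.null(o$local_shift_parameters))
                  rigid_transform(as.numeric(o$local_shift_parameters)),
                noise_sigma = as.numeric(o$noise_sigma),
                seed = as.integer(o$seed),
                wm_level = as.numeric(o$wm_level))
}

#' Write a phantom cohort to a directory
#'
#' Writes the anatomy labels, the pons-normalized template-space images, the
#' warped subject-space images (when present) and the ground-truth table.
#'
#' @param cohort `phantom_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
save_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(label_volume(cohort$anatomy), file.path(dir, "labels.nii.gz"))
  for (i in seq_along(cohort$stack$volumes))
    write_volume(cohort$stack$volumes[[i]],
                 file.path(dir, sprintf("tmpl%02d.nii.gz", i)))
  if (!is.null(cohort$subjects))
    for (i in seq_along(cohort$subjects))
      write_volume(cohort$subjects[[i]],
                   file.path(dir, sprintf("subj%02d.nii.gz", i)))
  jsonlite::write_json(lapply(cohort$truths, serialize_truth),
                       file.path(dir, "truths.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a phantom cohort saved by [save_cohort()]
#'
#' @param dir Cohort directory.
#' @return `phantom_cohort`.
#' @export
load_cohort <- function(dir) {
  truths_raw <- jsonlite::read_json(file.path(dir, "truths.json"))
  n <- length(truths_raw)
  anat <- anatomy_from_labels(load_volume(file.path(dir, "labels.nii.gz")))
  vols <- lapply(seq_len(n), function(i)
    load_volume(file.path(dir, sprintf("tmpl%02d.nii.gz", i))))
  subjects <- NULL
  if (file.exists(file.path(dir, "subj01.nii.gz")))
    subjects <- lapply(seq_len(n), function(i)
      load_volume(file.path(dir, sprintf("subj%02d.nii.gz", i))))
  truths <- lapply(truths_raw, deserialize_truth)
  structure(list(stack = image_stack(vols), truths = truths,
                 subjects = subjects, anatomy = anat,
                 burdens = vapply(truths, `[[`, numeric(1), "burden"),
                 seed = NA_integer_),
            class = "phantom_cohort")
}
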