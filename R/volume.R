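#' PET volume container
#'
#' A 3-D grid of either activity concentration (Bq/ml) or standardized uptake
#' values (SUV, unitless), with voxel spacing in mm and a calibration flag.
#'
#' @param values numeric 3-D array.
#' @param spacing numeric length-3, mm per axis (all > 0).
#' @param units `"Bq/ml"` or `"SUV"`.
#' @param patient_id optional identifier.
#' @return a `pet_volume` object.
#' @export
pet_volume <- function(values, spacing, units = c("Bq/ml", "SUV"),
                       patient_id = NA_character_) {
  units <- match.arg(units)
  stopifnot(length(dim(values)) == 3, all(is.finite(values)),
            length(spacing) == 3, all(spacing > 0))
  structure(list(values = values, spacing = as.numeric(spacing),
                 units = units, patient_id = patient_id),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("<pet_volume %s> %s, grid %s, spacing %s mm, range [%.3g, %.3g]\n",
              x$patient_id, x$units, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Tumor mask container
#'
#' Binary segmentation aligned to a [pet_volume()] grid, tagged with the
#' segmentation method that produced it.
#'
#' @param mask logical 3-D array.
#' @param spacing voxel spacing in mm.
#' @param method one of `"fixed_fraction"`, `"fuzzy_adaptive"`, `"ground_truth"`.
#' @param patient_id optional identifier.
#' @param degenerate flag set by segmenters on degenerate inputs.
#' @return a `tumor_mask` object.
#' @export
tumor_mask <- function(mask, spacing,
                       method = c("ground_truth", "fixed_fraction", "fuzzy_adaptive"),
                       patient_id = NA_character_, degenerate = FALSE) {
  method <- match.arg(method)
  stopifnot(length(dim(mask)) == 3, length(spacing) == 3, all(spacing > 0))
  structure(list(mask = array(as.logical(mask), dim(mask)),
                 spacing = as.numeric(spacing), method = method,
                 patient_id = patient_id, degenerate = isTRUE(degenerate)),
            class = "tumor_mask")
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat(sprintf("<tumor_mask %s> method=%s, %d voxels (%.2f ml)%s\n",
              x$patient_id, x$method, sum(x$mask), mask_volume_ml(x),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Mask volume in ml (cm^3)
#' @param mask a [tumor_mask()].
#' @return volume in ml.
#' @export
mask_volume_ml <- function(mask) {
  sum(mask$mask) * prod(mask$spacing) / 1000
}

#' Convert an activity volume to SUV
#'
#' SUV = activity \[Bq/ml\] x body weight \[g\] / injected dose \[Bq\];
#' decay correction is assumed to have been applied upstream.
#'
#' @param volume a [pet_volume()] in Bq/ml.
#' @param injected_dose_bq injected dose in Bq (> 0).
#' @param body_weight_kg patient body weight in kg (> 0).
#' @return a [pet_volume()] in SUV units.
#' @export
compute_suv <- function(volume, injected_dose_bq, body_weight_kg) {
  stopifnot(inherits(volume, "pet_volume"))
  if (volume$units != "Bq/ml") stop("volume is already calibrated to SUV")
  if (!isTRUE(injected_dose_bq > 0)) stop("injected_dose_bq must be > 0")
  if (!isTRUE(body_weight_kg > 0)) stop("body_weight_kg must be > 0")
  suv <- volume$values * (body_weight_kg * 1000) / injected_dose_bq
  pet_volume(suv, volume$spacing, "SUV", volume$patient_id)
}

#' Read / write volumes and masks as NIfTI
#'
#' Thin wrappers over RNifti. Spacing is taken from (written to) the NIfTI
#' pixdim field. `read_pet_volume` does not guess calibration: state the units.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param units units of the stored values.
#' @param patient_id optional identifier.
#' @return a [pet_volume()] / [tumor_mask()]; writers return `path` invisibly.
#' @export
read_pet_volume <- function(path, units = c("Bq/ml", "SUV"),
                            patient_id = NA_character_) {
  units <- match.arg(units)
  img <- RNifti::readNifti(path)
  pet_volume(array(as.numeric(img), dim(img)[1:3]),
             RNifti::pixdim(img)[1:3], units, patient_id)
}

#' @rdname read_pet_volume
#' @param volume a [pet_volume()] to write.
#' @export
write_pet_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_pet_volume
#' @param method provenance tag for the mask being read.
#' @export
read_tumor_mask <- function(path, method = "ground_truth",
                            patient_id = NA_character_) {
  img <- RNifti::readNifti(path)
  tumor_mask(array(as.numeric(img), dim(img)[1:3]) > 0.5,
             RNifti::pixdim(img)[1:3], method, patient_id)
}

#' @rdname read_pet_volume
#' @param mask a [tumor_mask()] to write.
#' @export
write_tumor_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$mask), dim(mask$mask)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
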