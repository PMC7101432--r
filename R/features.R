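#' The default 28-feature radiomics battery
#'
#' Five intensity features, seven shape features, seven co-occurrence
#' (heterogeneity) features and nine size-zone (heterogeneity) features.
#'
#' @return character vector of 28 feature names, in battery order.
#' @export
radiomics_battery <- function() {
  c("SUVmax", "SUVmean", "SUV_COV", "TLG", "MATV",
    "sphericity", "compactness_v1", "compactness_v2",
    "spherical_disproportion", "surface_to_volume_ratio", "irregularity",
    "max_distance_to_background",
    "angular_second_moment", "inverse_difference_moment", "homogeneity",
    "dissimilarity", "inertia", "entropy", "correlation",
    "zone_percentage", "small_area_emphasis", "large_area_emphasis",
    "intensity_variability", "size_zone_variability",
    "high_intensity_emphasis", "low_intensity_emphasis",
    "high_intensity_large_area_emphasis", "low_intensity_large_area_emphasis")
}

#' Extract the radiomics battery for one tumor
#'
#' Composes [intensity_features()], [shape_features()] (coarea surface),
#' [discretize_fbn()] + [cooc_features()] (13-direction merged GLCM) and
#' [build_szm()] + [szm_features()] into one named row of 28 values.
#'
#' @param volume a [pet_volume()] in SUV units.
#' @param mask a [tumor_mask()] on the same grid.
#' @param n_bins fixed bin number for texture discretization (default 64).
#' @param surface surface-area method for shape features.
#' @return named numeric vector of length 28.
#' @export
extract_features <- function(volume, mask, n_bins = 64L,
                             surface = c("coarea", "voxel_faces")) {
  disc <- discretize_fbn(volume, mask, n_bins)
  disc_surface <- match.arg(surface)
  out <- c(intensity_features(volume, mask),
           shape_features(mask, disc_surface),
           cooc_features(build_cooc_merged(disc, mask)),
           szm_features(build_szm(disc, mask)))
  stopifnot(identical(names(out), radiomics_battery()), all(is.finite(out)))
  out
}

#' Extract features for a cohort
#'
#' @param volumes list of [pet_volume()] in SUV units.
#' @param masks list of [tumor_mask()] paired with `volumes`.
#' @param n_bins fixed bin number.
#' @param patient_ids row names; defaults to the volumes' patient ids.
#' @return data.frame, patients x 28 features, with `patient_id` row names.
#' @export
extract_cohort_features <- function(volumes, masks, n_bins = 64L,
                                    patient_ids = NULL) {
  stopifnot(length(volumes) == length(masks))
  rows <- lapply(seq_along(volumes), function(i) {
    extract_features(volumes[[i]], masks[[i]], n_bins)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  ids <- patient_ids %||%
    vapply(volumes, function(v) v$patient_id, character(1))
  if (any(is.na(ids))) ids <- sprintf("P%02d", seq_along(volumes))
  rownames(tab) <- ids
  tab
}

#' Min-max normalize cohort features to \[0, 1\]
#'
#' Each feature is rescaled to `(x - min) / (max - min)` across the cohort,
#' so thresholds learned on the normalized scale read directly as
#' percentages of the cohort range. Features constant across the cohort are
#' dropped with a warning (they cannot act as regulators).
#'
#' @param features data.frame or matrix, patients x features (>= 2 patients).
#' @return data.frame of normalized features with attributes `feature_min`
#'   and `feature_max` holding the original per-feature ranges.
#' @export
normalize_cohort_features <- function(features) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) >= 2)
  lo <- vapply(features, min, numeric(1))
  hi <- vapply(features, max, numeric(1))
  constant <- hi == lo
  if (any(constant)) {
    warning("dropping constant feature(s): ",
            paste(names(features)[constant], collapse = ", "))
    features <- features[, !constant, drop = FALSE]
    lo <- lo[!constant]; hi <- hi[!constant]
  }
  out <- as.data.frame(mapply(function(x, l, h) (x - l) / (h - l),
                              features, lo, hi, SIMPLIFY = FALSE))
  rownames(out) <- rownames(features)
  attr(out, "feature_min") <- lo
  attr(out, "feature_max") <- hi
  out
}
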