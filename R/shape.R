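## Voxel-face surface area: count exposed faces, weighted by face area.
voxel_face_area <- function(mask, spacing) {
  d <- dim(mask)
  m <- array(FALSE, d + 2L)
  m[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
            spacing[1] * spacing[2])
  total <- 0
  for (ax in 1:3) {
    sh <- function(off) {
      i <- 2:(d[1] + 1) + if (ax == 1) off else 0
      j <- 2:(d[2] + 1) + if (ax == 2) off else 0
      k <- 2:(d[3] + 1) + if (ax == 3) off else 0
      m[i, j, k]
    }
    core <- m[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
    total <- total + face[ax] * (sum(core & !sh(1)) + sum(core & !sh(-1)))
  }
  total
}

## Coarea surface area: smooth the binary indicator with a small Gaussian
## (sigma in voxels) and integrate the gradient magnitude; by the coarea
## formula this equals the level-set area averaged over levels. Central
## differences and a per-axis-equal sigma make the estimate exactly
## symmetric under 90-degree grid rotations.
coarea_surface <- function(mask, spacing, sigma_vox = 0.6) {
  d <- dim(mask)
  pad <- max(4L, as.integer(ceiling(3 * sigma_vox)) + 2L)
  f <- array(0, d + 2L * pad)
  f[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]),
    (pad + 1):(pad + d[3])] <- as.numeric(mask)
  f <- gaussian_smooth_3d(f, sigma_vox)
  dp <- dim(f)
  gx <- array(0, dp); gy <- array(0, dp); gz <- array(0, dp)
  gx[2:(dp[1] - 1), , ] <- (f[3:dp[1], , ] - f[1:(dp[1] - 2), , ]) /
    (2 * spacing[1])
  gy[, 2:(dp[2] - 1), ] <- (f[, 3:dp[2], ] - f[, 1:(dp[2] - 2), ]) /
    (2 * spacing[2])
  gz[, , 2:(dp[3] - 1)] <- (f[, , 3:dp[3]] - f[, , 1:(dp[3] - 2)]) /
    (2 * spacing[3])
  sum(sqrt(gx^2 + gy^2 + gz^2)) * prod(spacing)
}

#' Mask surface area (mm^2)
#'
#' The default estimator anti-aliases the binary mask with a small
#' Gaussian (sigma 0.6 voxel) and integrates the gradient magnitude of
#' the resulting field (the coarea formula: the integral equals the
#' iso-surface area averaged over levels). Measuring the stair-step voxel
#' boundary directly overestimates curved surfaces by 25-50%; the coarea
#' estimate is within about 1% for digitized spheres of realistic size,
#' and is exactly invariant under 90-degree grid rotations. A plain
#' voxel-face count is available for sensitivity checks (and is exact for
#' axis-aligned boxes).
#'
#' @param mask a [tumor_mask()], not touching the grid edge.
#' @param method `"coarea"` (default) or `"voxel_faces"`.
#' @return surface area in mm^2.
#' @export
surface_area <- function(mask, method = c("coarea", "voxel_faces")) {
  method <- match.arg(method)
  if (method == "voxel_faces") {
    voxel_face_area(mask$mask, mask$spacing)
  } else {
    coarea_surface(mask$mask, mask$spacing)
  }
}

touches_edge <- function(mask) {
  d <- dim(mask)
  any(mask[c(1, d[1]), , ]) || any(mask[, c(1, d[2]), ]) ||
    any(mask[, , c(1, d[3])])
}

#' Shape features
#'
#' Surface/volume shape descriptors of a tumor mask. With `V` the voxel
#' volume (mm^3), `A` the surface area (mm^2) and
#' `R = (3V / 4 pi)^(1/3)` the radius of the equal-volume sphere:
#' sphericity `pi^(1/3) (6V)^(2/3) / A`, compactness v1
#' `V / (sqrt(pi) A^(3/2))`, compactness v2 `36 pi V^2 / A^3`
#' (= sphericity^3), spherical disproportion `A / (4 pi R^2)`,
#' surface-to-volume ratio `A/V` (1/mm), irregularity `1 - sphericity`
#' (0 for a perfect sphere), and maximum distance to background: the
#' largest Euclidean distance (mm) from a tumor voxel to the nearest
#' background voxel (depth of the lesion core).
#'
#' @param mask a [tumor_mask()], nonempty and not touching the grid edge.
#' @param surface one of `"coarea"`, `"voxel_faces"` (see
#'   [surface_area()]).
#' @return named numeric vector of 7 features.
#' @export
shape_features <- function(mask, surface = c("coarea", "voxel_faces")) {
  stopifnot(inherits(mask, "tumor_mask"), sum(mask$mask) > 0)
  if (touches_edge(mask$mask)) {
    stop("mask touches the grid boundary; shape features would be truncated")
  }
  V <- sum(mask$mask) * prod(mask$spacing)      # mm^3
  A <- surface_area(mask, match.arg(surface))   # mm^2
  sph <- pi^(1 / 3) * (6 * V)^(2 / 3) / A
  R <- (3 * V / (4 * pi))^(1 / 3)
  dt <- distance_to_background(mask$mask, mask$spacing)
  c(sphericity = sph,
    compactness_v1 = V / (sqrt(pi) * A^(3 / 2)),
    compactness_v2 = 36 * pi * V^2 / A^3,
    spherical_disproportion = A / (4 * pi * R^2),
    surface_to_volume_ratio = A / V,
    irregularity = 1 - sph,
    max_distance_to_background = max(dt$distance))
}

#' Intensity features
#'
#' First-order SUV statistics over the mask: SUVmax, SUVmean, SUV
#' coefficient of variation (population SD / mean), metabolically active
#' tumor volume MATV (ml) and total lesion glycolysis
#' TLG = SUVmean x MATV.
#'
#' @param volume a [pet_volume()] in SUV units.
#' @param mask a [tumor_mask()] on the same grid (nonempty).
#' @return named numeric vector of 5 features.
#' @export
intensity_features <- function(volume, mask) {
  stopifnot(identical(dim(volume$values), dim(mask$mask)))
  x <- volume$values[mask$mask]
  if (length(x) == 0) stop("mask is empty")
  m <- mean(x)
  if (m == 0) stop("SUVmean is 0; SUV_COV undefined")
  sd_pop <- sqrt(mean((x - m)^2))
  matv <- mask_volume_ml(mask)
  c(SUVmax = max(x), SUVmean = m, SUV_COV = sd_pop / m,
    TLG = m * matv, MATV = matv)
}
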