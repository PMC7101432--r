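#' Fixed-bin-number discretization
#'
#' Maps ROI intensities into `n_bins` equal-width bins between the ROI
#' minimum and maximum: `bin(x) = floor(n_bins * (x - min) / (max - min)) + 1`,
#' with `x = max` mapped to bin `n_bins`. A constant ROI maps every voxel to
#' bin 1 and is flagged degenerate.
#'
#' @param volume a [pet_volume()].
#' @param mask a [tumor_mask()] on the same grid (nonempty).
#' @param n_bins number of bins (>= 2), default 64.
#' @return list: `bins` (integer array, 0 outside mask), `n_bins`,
#'   `degenerate` flag.
#' @export
discretize_fbn <- function(volume, mask, n_bins = 64L) {
  stopifnot(inherits(volume, "pet_volume"), inherits(mask, "tumor_mask"),
            identical(dim(volume$values), dim(mask$mask)), n_bins >= 2)
  idx <- which(mask$mask)
  if (length(idx) == 0) stop("mask is empty")
  x <- volume$values[idx]
  lo <- min(x); hi <- max(x)
  bins <- array(0L, dim(volume$values))
  if (hi == lo) {
    bins[idx] <- 1L
    return(list(bins = bins, n_bins = as.integer(n_bins), degenerate = TRUE))
  }
  b <- floor(n_bins * (x - lo) / (hi - lo)) + 1L
  b[b > n_bins] <- as.integer(n_bins)  # x == max
  bins[idx] <- as.integer(b)
  list(bins = bins, n_bins = as.integer(n_bins), degenerate = FALSE)
}

#' Merged-direction co-occurrence matrix
#'
#' Builds a single symmetric gray-level co-occurrence matrix by counting
#' bin transitions between grid-adjacent in-mask voxels along all 13 unique
#' displacement directions of the 26-neighbourhood, symmetrizing, summing
#' over directions and normalizing to total 1 (the "merging" strategy).
#' Voxel adjacency is in grid steps; spacing anisotropy is ignored for
#' texture, by design.
#'
#' @param disc result of [discretize_fbn()].
#' @param mask the [tumor_mask()] used for discretization.
#' @return list of class `cooc_matrix`: `p` (n_bins x n_bins), `n_bins`,
#'   `n_directions`, `n_pairs`, `degenerate` (TRUE for a single-voxel mask,
#'   where no pair exists and `p` is all zero).
#' @export
build_cooc_merged <- function(disc, mask) {
  bins <- disc$bins
  d <- dim(bins)
  nb <- disc$n_bins
  dirs <- unique_directions_13()
  idx <- which(mask$mask)
  co <- matrix(0, nb, nb)
  npairs <- 0
  cc <- arrayInd(idx, d)
  for (o in seq_len(nrow(dirs))) {
    nc <- cc + matrix(dirs[o, ], nrow(cc), 3, byrow = TRUE)
    ok <- nc[, 1] >= 1 & nc[, 1] <= d[1] &
      nc[, 2] >= 1 & nc[, 2] <= d[2] &
      nc[, 3] >= 1 & nc[, 3] <= d[3]
    if (!any(ok)) next
    lin <- nc[ok, 1] + (nc[ok, 2] - 1L) * d[1] + (nc[ok, 3] - 1L) * d[1] * d[2]
    src <- idx[ok]
    both <- mask$mask[lin]
    if (!any(both)) next
    bi <- bins[src[both]]; bj <- bins[lin[both]]
    tab <- table(factor(bi, levels = 1:nb), factor(bj, levels = 1:nb))
    co <- co + tab + t(tab)
    npairs <- npairs + sum(tab)
  }
  degenerate <- npairs == 0
  p <- if (degenerate) co else co / sum(co)
  structure(list(p = unname(p), n_bins = nb, n_directions = nrow(dirs),
                 n_pairs = npairs, degenerate = degenerate),
            class = "cooc_matrix")
}

#' Co-occurrence texture features
#'
#' Standard merged-GLCM statistics: angular second moment `sum p^2`, inverse
#' difference moment `sum p/(1+(i-j)^2)`, homogeneity `sum p/(1+|i-j|)`,
#' dissimilarity `sum p|i-j|`, inertia (contrast) `sum p(i-j)^2`, entropy
#' `-sum p log2 p`, and correlation `(sum p*i*j - mu^2)/sigma^2` from the
#' (symmetric) marginals. A degenerate matrix (single-voxel mask) follows
#' the stated convention ASM = 1, everything else 0; correlation is set to 0
#' whenever the marginal variance vanishes.
#'
#' @param M a `cooc_matrix` from [build_cooc_merged()].
#' @return named numeric vector of 7 features.
#' @export
cooc_features <- function(M) {
  stopifnot(inherits(M, "cooc_matrix"))
  out <- c(angular_second_moment = 1, inverse_difference_moment = 0,
           homogeneity = 0, dissimilarity = 0, inertia = 0, entropy = 0,
           correlation = 0)
  if (M$degenerate) return(out)
  p <- M$p
  nb <- M$n_bins
  i <- matrix(seq_len(nb), nb, nb)
  j <- t(i)
  dd <- i - j
  out["angular_second_moment"] <- sum(p^2)
  out["inverse_difference_moment"] <- sum(p / (1 + dd^2))
  out["homogeneity"] <- sum(p / (1 + abs(dd)))
  out["dissimilarity"] <- sum(p * abs(dd))
  out["inertia"] <- sum(p * dd^2)
  nz <- p > 0
  out["entropy"] <- -sum(p[nz] * log2(p[nz]))
  pi_marg <- rowSums(p)
  mu <- sum(seq_len(nb) * pi_marg)
  s2 <- sum((seq_len(nb) - mu)^2 * pi_marg)
  out["correlation"] <- if (s2 > 0) (sum(p * i * j) - mu^2) / s2 else 0
  out
}

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal-bin voxels inside the mask;
#' `n(i, s)` counts zones of bin `i` and size `s` voxels.
#'
#' @param disc result of [discretize_fbn()].
#' @param mask the [tumor_mask()] used for discretization.
#' @return list of class `szm_matrix`: `counts` (n_bins x max zone size),
#'   `n_zones`, `n_voxels`, `n_bins`.
#' @export
build_szm <- function(disc, mask) {
  bins <- disc$bins
  nb <- disc$n_bins
  nv <- sum(mask$mask)
  stopifnot(nv > 0)
  zone_bin <- integer(0)
  zone_size <- integer(0)
  for (b in sort(unique(bins[mask$mask]))) {
    lab <- label_components(bins == b & mask$mask, 26L)
    if (max(lab) == 0) next
    sz <- tabulate(lab[lab > 0])
    zone_bin <- c(zone_bin, rep.int(b, length(sz)))
    zone_size <- c(zone_size, sz)
  }
  smax <- max(zone_size)
  counts <- matrix(0, nb, smax)
  for (z in seq_along(zone_bin)) {
    counts[zone_bin[z], zone_size[z]] <- counts[zone_bin[z], zone_size[z]] + 1
  }
  structure(list(counts = counts, n_zones = length(zone_bin),
                 n_voxels = nv, n_bins = nb),
            class = "szm_matrix")
}

#' Size-zone texture features
#'
#' With `n(i,s)` the zone counts, `Nz` total zones and `Nv` masked voxels:
#' zone percentage `Nz/Nv`, small/large area emphasis `(1/Nz) sum n/s^2` and
#' `(1/Nz) sum n s^2`, intensity variability `(1/Nz) sum_i (sum_s n)^2`,
#' size-zone variability `(1/Nz) sum_s (sum_i n)^2`, high/low intensity
#' emphasis `(1/Nz) sum n i^2` and `(1/Nz) sum n/i^2`, and the
#' high/low-intensity large-area combinations.
#'
#' @param Z a `szm_matrix` from [build_szm()].
#' @return named numeric vector of 9 features.
#' @export
szm_features <- function(Z) {
  stopifnot(inherits(Z, "szm_matrix"))
  if (Z$n_zones < 1) stop("size-zone matrix has no zones")
  n <- Z$counts
  nb <- nrow(n); smax <- ncol(n)
  i2 <- matrix(seq_len(nb)^2, nb, smax)
  s2 <- matrix(rep(seq_len(smax)^2, each = nb), nb, smax)
  Nz <- Z$n_zones
  c(zone_percentage = Nz / Z$n_voxels,
    small_area_emphasis = sum(n / s2) / Nz,
    large_area_emphasis = sum(n * s2) / Nz,
    intensity_variability = sum(rowSums(n)^2) / Nz,
    size_zone_variability = sum(colSums(n)^2) / Nz,
    high_intensity_emphasis = sum(n * i2) / Nz,
    low_intensity_emphasis = sum(n / i2) / Nz,
    high_intensity_large_area_emphasis = sum(n * i2 * s2) / Nz,
    low_intensity_large_area_emphasis = sum(n / (i2 * s2)) / Nz)
}
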