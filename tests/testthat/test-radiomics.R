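whole_mask <- function(dim3, spacing = c(1, 1, 1)) {
  tumor_mask(array(TRUE, dim3), spacing, "ground_truth")
}

test_that("fixed-bin-number discretization follows the floor formula", {
  vol <- pet_volume(array(seq(0, 64, length.out = 64), c(4, 4, 4)),
                    c(1, 1, 1), "SUV")
  vol$values[1] <- 0; vol$values[64] <- 64
  vol$values[30] <- 32
  d <- discretize_fbn(vol, whole_mask(c(4, 4, 4)), 64)
  expect_equal(d$bins[30], floor(64 * 32 / 64) + 1)  # bin 33
  expect_equal(d$bins[64], 64)                       # max maps to n_bins
  expect_false(d$degenerate)
  dc <- discretize_fbn(pet_volume(array(5, c(3, 3, 3)), c(1, 1, 1), "SUV"),
                       whole_mask(c(3, 3, 3)), 64)
  expect_true(dc$degenerate)
  expect_true(all(dc$bins == 1))
})

test_that("tiny co-occurrence matrices match hand computation", {
  vol <- pet_volume(array(c(0, 1), c(1, 1, 2)), c(1, 1, 1), "SUV")
  mask <- whole_mask(c(1, 1, 2))
  M <- build_cooc_merged(discretize_fbn(vol, mask, 2), mask)
  expect_equal(M$p[1, 2], 0.5)
  expect_equal(M$p[2, 1], 0.5)
  expect_equal(sum(M$p), 1)
  expect_equal(M$n_directions, 13)

  volc <- pet_volume(array(3, c(2, 2, 2)), c(1, 1, 1), "SUV")
  maskc <- whole_mask(c(2, 2, 2))
  Mc <- build_cooc_merged(discretize_fbn(volc, maskc, 2), maskc)
  expect_equal(Mc$p[1, 1], 1)

  # single voxel: no pairs, stated degenerate convention
  m1 <- tumor_mask(array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)), c(1, 1, 1),
                   "ground_truth")
  v1 <- pet_volume(array(1, c(2, 2, 2)), c(1, 1, 1), "SUV")
  M1 <- build_cooc_merged(discretize_fbn(v1, m1, 2), m1)
  expect_true(M1$degenerate)
  f1 <- cooc_features(M1)
  expect_equal(unname(f1["angular_second_moment"]), 1)
  expect_equal(unname(f1["entropy"]), 0)
})

test_that("co-occurrence features match hand values and a double-loop oracle", {
  M <- structure(list(p = matrix(c(0, 0.5, 0.5, 0), 2, 2), n_bins = 2L,
                      n_directions = 13L, n_pairs = 1, degenerate = FALSE),
                 class = "cooc_matrix")
  f <- cooc_features(M)
  expect_equal(unname(f["angular_second_moment"]), 0.5)
  expect_equal(unname(f["dissimilarity"]), 1)
  expect_equal(unname(f["inertia"]), 1)
  expect_equal(unname(f["inverse_difference_moment"]), 0.5)
  expect_equal(unname(f["homogeneity"]), 0.5)

  Mc <- structure(list(p = matrix(c(1, 0, 0, 0), 2, 2), n_bins = 2L,
                       n_directions = 13L, n_pairs = 4, degenerate = FALSE),
                  class = "cooc_matrix")
  fc <- cooc_features(Mc)
  expect_equal(unname(fc["angular_second_moment"]), 1)
  expect_equal(unname(fc["inertia"]), 0)
  expect_equal(unname(fc["entropy"]), 0)

  set.seed(7)
  p <- matrix(stats::runif(16), 4, 4)
  p <- (p + t(p)) / 2
  p <- p / sum(p)
  Mr <- structure(list(p = p, n_bins = 4L, n_directions = 13L, n_pairs = 10,
                       degenerate = FALSE), class = "cooc_matrix")
  fr <- cooc_features(Mr)
  # naive double loop
  asm <- 0; idm <- 0; hom <- 0; dis <- 0; ine <- 0; ent <- 0
  mu <- 0; s2 <- 0; cross <- 0
  for (i in 1:4) mu <- mu + i * sum(p[i, ])
  for (i in 1:4) s2 <- s2 + (i - mu)^2 * sum(p[i, ])
  for (i in 1:4) for (j in 1:4) {
    asm <- asm + p[i, j]^2
    idm <- idm + p[i, j] / (1 + (i - j)^2)
    hom <- hom + p[i, j] / (1 + abs(i - j))
    dis <- dis + p[i, j] * abs(i - j)
    ine <- ine + p[i, j] * (i - j)^2
    if (p[i, j] > 0) ent <- ent - p[i, j] * log2(p[i, j])
    cross <- cross + p[i, j] * i * j
  }
  expect_equal(unname(fr["angular_second_moment"]), asm, tolerance = 1e-12)
  expect_equal(unname(fr["inverse_difference_moment"]), idm, tolerance = 1e-12)
  expect_equal(unname(fr["homogeneity"]), hom, tolerance = 1e-12)
  expect_equal(unname(fr["dissimilarity"]), dis, tolerance = 1e-12)
  expect_equal(unname(fr["inertia"]), ine, tolerance = 1e-12)
  expect_equal(unname(fr["entropy"]), ent, tolerance = 1e-12)
  expect_equal(unname(fr["correlation"]), (cross - mu^2) / s2,
               tolerance = 1e-12)
})

test_that("size-zone matrices match hand cases", {
  volc <- pet_volume(array(3, c(2, 2, 2)), c(1, 1, 1), "SUV")
  maskc <- whole_mask(c(2, 2, 2))
  Z <- build_szm(discretize_fbn(volc, maskc, 2), maskc)
  expect_equal(Z$n_zones, 1)
  expect_equal(Z$counts[1, 8], 1)

  # 2-D checkerboard slab: diagonal contacts join same-bin cells -> 2 zones
  v <- array(0, c(4, 4, 1))
  v[] <- (outer(1:4, 1:4, `+`) %% 2)
  vol <- pet_volume(v, c(1, 1, 1), "SUV")
  mask <- whole_mask(c(4, 4, 1))
  Z2 <- build_szm(discretize_fbn(vol, mask, 2), mask)
  expect_equal(Z2$n_zones, 2)
})

test_that("size-zone features match hand values and a naive oracle", {
  Z <- structure(list(counts = {
    m <- matrix(0, 1, 8); m[1, 8] <- 1; m
  }, n_zones = 1L, n_voxels = 8L, n_bins = 1L), class = "szm_matrix")
  f <- szm_features(Z)
  expect_equal(unname(f["zone_percentage"]), 1 / 8)
  expect_equal(unname(f["large_area_emphasis"]), 64)
  expect_equal(unname(f["high_intensity_large_area_emphasis"]), 64)
  expect_equal(unname(f["intensity_variability"]), 1)
  expect_equal(unname(f["size_zone_variability"]), 1)

  # every voxel its own zone
  Zi <- structure(list(counts = {
    m <- matrix(0, 8, 1); m[, 1] <- 1; m
  }, n_zones = 8L, n_voxels = 8L, n_bins = 8L), class = "szm_matrix")
  fi <- szm_features(Zi)
  expect_equal(unname(fi["zone_percentage"]), 1)
  expect_equal(unname(fi["large_area_emphasis"]), 1)

  g <- rand_grid(42)
  Zr <- build_szm(g$disc, g$mask)
  n <- Zr$counts
  Nz <- Zr$n_zones
  sae <- 0; lae <- 0; hie <- 0; lie <- 0; hilae <- 0; lilae <- 0
  for (i in seq_len(nrow(n))) for (s in seq_len(ncol(n))) {
    sae <- sae + n[i, s] / s^2; lae <- lae + n[i, s] * s^2
    hie <- hie + n[i, s] * i^2; lie <- lie + n[i, s] / i^2
    hilae <- hilae + n[i, s] * i^2 * s^2
    lilae <- lilae + n[i, s] / (i^2 * s^2)
  }
  fr <- szm_features(Zr)
  expect_equal(unname(fr["small_area_emphasis"]), sae / Nz, tolerance = 1e-12)
  expect_equal(unname(fr["large_area_emphasis"]), lae / Nz, tolerance = 1e-12)
  expect_equal(unname(fr["high_intensity_emphasis"]), hie / Nz,
               tolerance = 1e-12)
  expect_equal(unname(fr["low_intensity_emphasis"]), lie / Nz,
               tolerance = 1e-12)
  expect_equal(unname(fr["high_intensity_large_area_emphasis"]), hilae / Nz,
               tolerance = 1e-12)
  expect_equal(unname(fr["low_intensity_large_area_emphasis"]), lilae / Nz,
               tolerance = 1e-12)
  expect_equal(unname(fr["intensity_variability"]), sum(rowSums(n)^2) / Nz)
  expect_equal(unname(fr["size_zone_variability"]), sum(colSums(n)^2) / Nz)
})

test_that("texture matrices equal brute-force oracles on random grids", {
  for (seed in 1:25) {
    g <- rand_grid(seed)
    M <- build_cooc_merged(g$disc, g$mask)
    if (!M$degenerate) {
      expect_equal(M$p, oracle_cooc(g$disc$bins, g$mask$mask, g$nb),
                   tolerance = 1e-12)
    }
    Z <- build_szm(g$disc, g$mask)
    oz <- oracle_szm(g$disc$bins, g$mask$mask, g$nb)
    expect_equal(Z$counts[, seq_len(ncol(oz)), drop = FALSE], oz,
                 ignore_attr = TRUE)
  }
})

test_that("shape formulas are exact on a cube with analytic surfaces", {
  cube <- tumor_mask({
    m <- array(FALSE, c(14, 14, 14)); m[3:12, 3:12, 3:12] <- TRUE; m
  }, c(1, 1, 1), "ground_truth")
  # voxel-face counting is exact for an axis-aligned cube: A = 6 L^2
  f <- shape_features(cube, surface = "voxel_faces")
  L <- 10
  expect_equal(unname(f["sphericity"]), pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-12)
  expect_equal(unname(f["sphericity"]), 0.80600, tolerance = 1e-4)
  expect_equal(unname(f["surface_to_volume_ratio"]), 6 / L)
  expect_equal(unname(f["compactness_v2"]),
               unname(f["sphericity"])^3, tolerance = 1e-9)
})

test_that("a digitized sphere is near-spherical with mesh surfaces", {
  sph <- sphere_mask(10)
  f <- shape_features(sph)
  expect_gte(unname(f["sphericity"]), 0.95)
  expect_lte(unname(f["sphericity"]), 1.02)
  expect_gte(unname(f["compactness_v2"]), 0.95^3)
  expect_equal(unname(f["compactness_v2"]), unname(f["sphericity"])^3,
               tolerance = 1e-9)
  expect_gte(unname(f["spherical_disproportion"]), 1 - 0.05)
  expect_equal(unname(f["max_distance_to_background"]), 10, tolerance = 1.5)
  expect_equal(unname(f["irregularity"]), 1 - unname(f["sphericity"]))
})

test_that("masks touching the grid edge are rejected for shape analysis", {
  m <- array(FALSE, c(5, 5, 5)); m[1, 3, 3] <- TRUE; m[2, 3, 3] <- TRUE
  expect_error(shape_features(tumor_mask(m, c(1, 1, 1), "ground_truth")),
               "boundary")
})

test_that("intensity features follow their definitions", {
  m <- array(FALSE, c(4, 4, 4)); m[1:10] <- TRUE
  mask <- tumor_mask(m, c(2, 2, 2), "ground_truth")
  vol <- pet_volume(array(5, c(4, 4, 4)), c(2, 2, 2), "SUV")
  f <- intensity_features(vol, mask)
  expect_equal(unname(f["SUVmax"]), 5)
  expect_equal(unname(f["SUV_COV"]), 0)
  expect_equal(unname(f["MATV"]), 10 * 8 / 1000)
  expect_equal(unname(f["TLG"]), 5 * 0.08)

  v2 <- pet_volume(array(rep(c(2, 4), 32), c(4, 4, 4)), c(2, 2, 2), "SUV")
  f2 <- intensity_features(v2, whole_mask(c(4, 4, 4), c(2, 2, 2)))
  expect_equal(unname(f2["SUV_COV"]), 1 / 3)  # population SD 1, mean 3

  g <- rand_grid(11, spacing = c(2, 2, 2))
  x <- g$vol$values[g$mask$mask]
  fo <- intensity_features(g$vol, g$mask)
  expect_equal(unname(fo["SUVmean"]), mean(x))
  expect_equal(unname(fo["SUV_COV"]), sqrt(mean((x - mean(x))^2)) / mean(x))
  expect_error(intensity_features(
    pet_volume(array(0, c(4, 4, 4)), c(1, 1, 1), "SUV"),
    whole_mask(c(4, 4, 4))), "SUV_COV")
})

test_that("the battery emits 28 finite features, reproducibly, even degenerate", {
  ph <- get_small_cohort()[[2]]
  f <- extract_features(ph$volume, ph$mask)
  expect_length(f, 28)
  expect_identical(names(f), radiomics_battery())
  expect_true(all(is.finite(f)))
  expect_identical(f, extract_features(ph$volume, ph$mask))
  # constant ROI: degenerate conventions, still no NaN
  m <- array(FALSE, c(8, 8, 8)); m[3:6, 3:6, 3:6] <- TRUE
  vol <- pet_volume(array(4, c(8, 8, 8)), c(1, 1, 1), "SUV")
  fd <- extract_features(vol, tumor_mask(m, c(1, 1, 1), "ground_truth"))
  expect_true(all(is.finite(fd)))
})

test_that("features are invariant to 90-degree grid rotations", {
  ph <- make_tumor_phantom(phantom_spec(eccentricity = c(1, 0.8, 1.2),
                                        seed = 3))
  f0 <- extract_features(ph$volume, ph$mask)
  for (axis in 1:3) {
    vol_r <- pet_volume(rot90_3d(ph$volume$values, axis), ph$volume$spacing,
                        "SUV")
    mask_r <- tumor_mask(rot90_3d(ph$mask$mask, axis), ph$mask$spacing,
                         "ground_truth")
    fr <- extract_features(vol_r, mask_r)
    expect_equal(fr, f0, tolerance = 1e-8)
  }
})

test_that("texture features are invariant to affine intensity rescaling", {
  ph <- make_tumor_phantom(phantom_spec(seed = 6))
  f0 <- extract_features(ph$volume, ph$mask)
  vol2 <- pet_volume(3.7 * ph$volume$values + 1.2, ph$volume$spacing, "SUV")
  f2 <- extract_features(vol2, ph$mask)
  texture <- c("angular_second_moment", "inverse_difference_moment",
               "homogeneity", "dissimilarity", "inertia", "entropy",
               "correlation", "zone_percentage", "small_area_emphasis",
               "large_area_emphasis", "intensity_variability",
               "size_zone_variability", "high_intensity_emphasis",
               "low_intensity_emphasis", "high_intensity_large_area_emphasis",
               "low_intensity_large_area_emphasis")
  expect_equal(f2[texture], f0[texture], tolerance = 1e-9)
})

test_that("cohort normalization maps ranges onto [0, 1] exactly", {
  tab <- data.frame(a = c(2, 4, 6), b = c(1, 3, 2), c = c(5, 5, 5))
  expect_warning(nt <- normalize_cohort_features(tab), "constant")
  expect_equal(nt$a, c(0, 0.5, 1))
  expect_equal(range(nt$b), c(0, 1))
  expect_null(nt$c)
  # threshold/percent round trip at the display convention
  tr <- regulator_tree(list(feature = "a", threshold = 0.792))
  disp <- thresholds_to_percent(tr, attr(nt, "feature_min"),
                                attr(nt, "feature_max"))
  expect_equal(disp$root$percent, 79.2)
  expect_equal(disp$root$raw, 2 + 0.792 * 4)
})
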