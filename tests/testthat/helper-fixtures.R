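# Shared fixtures, built once per test run and memoized (the full synthetic
# study takes ~20 s to generate).

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

get_study_fixture <- function() {
  memo("study", make_radiogenomic_fixture(seed = 1))
}

get_study_dir <- function() {
  memo("study_dir", {
    dir <- file.path(tempdir(), "petmodnet-study")
    cfg <- write_fixture(get_study_fixture(), dir, seed = 1)
    list(dir = dir, config = cfg)
  })
}

get_pipeline_result <- function() {
  memo("pipeline", run_pipeline(get_study_dir()$config, quiet = TRUE))
}

get_small_cohort <- function() {
  memo("small_cohort", make_cohort(6, seed = 3))
}

# Small random SUV grid + mask + discretization, for texture oracles.
rand_grid <- function(seed, n = 4, nb = 4, spacing = c(1, 1, 1)) {
  set.seed(seed)
  vol <- pet_volume(array(stats::runif(n^3), rep(n, 3)), spacing, "SUV")
  mask <- tumor_mask(array(stats::runif(n^3) > 0.25, rep(n, 3)), spacing,
                     "ground_truth")
  if (!any(mask$mask)) mask$mask[1] <- TRUE
  disc <- discretize_fbn(vol, mask, nb)
  list(vol = vol, mask = mask, disc = disc, nb = nb)
}

# A digitized sphere mask of radius r voxels (isotropic 1 mm spacing).
sphere_mask <- function(r, pad = 4) {
  n <- 2 * r + 2 * pad + 1
  ctr <- (n + 1) / 2
  g <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  m <- array((g$i - ctr)^2 + (g$j - ctr)^2 + (g$k - ctr)^2 <= r^2,
             c(n, n, n))
  tumor_mask(m, c(1, 1, 1), "ground_truth")
}

# Planted module-network simulation: three modules with distinct
# single-split trees over synthetic normalized features.
planted_modnet_sim <- function(n_patients = 45, probes_per_module = 100,
                               probe_sd = 0.3, seed = 0) {
  set.seed(seed + 1000)
  feats <- as.data.frame(matrix(stats::runif(n_patients * 5), n_patients, 5))
  names(feats) <- c("SUV_COV", "irregularity", "large_area_emphasis",
                    "inertia", "MATV")
  feats <- as.data.frame(lapply(feats, function(v) {
    (v - min(v)) / (max(v) - min(v))
  }))
  rownames(feats) <- sprintf("P%02d", seq_len(n_patients))
  planted <- list(
    list(feature = "SUV_COV", q = 0.4, means = c(2, 0)),
    list(feature = "irregularity", q = 0.5, means = c(0, 2)),
    list(feature = "large_area_emphasis", q = 0.6, means = c(2, 0)))
  trees <- lapply(planted, function(p) {
    v <- sort(feats[[p$feature]])
    k <- round(p$q * n_patients)
    regulator_tree(list(feature = p$feature,
                        threshold = (v[k] + v[k + 1]) / 2))
  })
  G <- 3 * probes_per_module
  truth <- rep(1:3, each = probes_per_module)
  E <- matrix(0, G, n_patients)
  for (m in 1:3) {
    ls <- tree_leaves(trees[[m]], feats)
    for (l in seq_along(ls)) {
      E[truth == m, ls[[l]]] <- planted[[m]]$means[l]
    }
  }
  E <- E + matrix(stats::rnorm(G * n_patients, 0, probe_sd), G, n_patients)
  E <- sweep(E, 1, rowMeans(E))
  list(E = E, feats = feats, trees = trees, truth = truth,
       planted = planted)
}

# Adjusted Rand index between two labelings (standard pair-counting form).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_i * sum_j / comb2(n)
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}
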