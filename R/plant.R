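#' Specification of planted expression structure
#'
#' The generative mirror of the module-network model: each planted module
#' carries a regulator tree over named (normalized) radiomic features and
#' per-leaf mean log2 tumor/normal offsets; probes in a module share the
#' leaf offsets, null probes have none.
#'
#' @param planted_trees list, one element per module:
#'   `list(tree = regulator_tree, leaf_means = numeric)` with one mean
#'   (log2 units) per tree leaf.
#' @param probes_per_module probes planted per module (>= 1).
#' @param n_null_probes probes with no planted offset.
#' @param probe_sd residual log2 sd per probe value.
#' @param baseline_mean,baseline_sd per-probe baseline log2 level
#'   (defaults N(8, 1), a typical single-channel array scale).
#' @param array_background_mean,array_background_sd additive intensity
#'   background (exercises normexp); the mean should exceed 5 sd so
#'   foregrounds stay positive.
#' @param replicate_multiplicity copies of each probe, with independent
#'   noise.
#' @return a `plant_spec` object.
#' @export
plant_spec <- function(planted_trees, probes_per_module = 100L,
                       n_null_probes = 500L, probe_sd = 0.3,
                       baseline_mean = 8, baseline_sd = 1,
                       array_background_mean = 80,
                       array_background_sd = 10,
                       replicate_multiplicity = 1L) {
  stopifnot(length(planted_trees) >= 1, probes_per_module >= 1,
            n_null_probes >= 0, probe_sd >= 0,
            replicate_multiplicity >= 1,
            array_background_mean > 5 * array_background_sd)
  for (pt in planted_trees) {
    stopifnot(inherits(pt$tree, "regulator_tree"),
              all(is.finite(pt$leaf_means)))
  }
  structure(list(planted_trees = planted_trees,
                 n_modules = length(planted_trees),
                 probes_per_module = as.integer(probes_per_module),
                 n_null_probes = as.integer(n_null_probes),
                 probe_sd = probe_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 array_background_mean = array_background_mean,
                 array_background_sd = array_background_sd,
                 replicate_multiplicity = as.integer(replicate_multiplicity)),
            class = "plant_spec")
}

#' Plant module-structured expression over a feature table
#'
#' For probe `g` in module `m` and patient `p` in leaf `l` of the module's
#' tree, the tumor log2 signal is `baseline_g + mu_{m,l} + N(0,
#' probe_sd^2)`; the normal signal is `baseline_g + N(0, probe_sd^2)`;
#' null probes carry no offset. Raw foreground is `2^signal` plus an
#' additive `N(bg_mean, bg_sd^2)` optical background, and each probe is
#' replicated `replicate_multiplicity` times with independent noise.
#' Deterministic given `seed`.
#'
#' @param features normalized (0-1) feature data.frame, patients x
#'   features; every planted tree regulator must be a column.
#' @param plant a [plant_spec()].
#' @param seed integer seed.
#' @return list: `tumor` and `normal` ([raw_array_set()]s), and `truth`
#'   (probe-to-module assignment with 0 = null, the planted trees, leaf
#'   patient sets and per-probe baselines).
#' @export
plant_expression <- function(features, plant, seed = 1L) {
  stopifnot(inherits(plant, "plant_spec"),
            all(unlist(features) >= 0), all(unlist(features) <= 1))
  P <- nrow(features)
  pats <- rownames(features) %||% sprintf("P%02d", seq_len(P))
  leaf_sets <- lapply(plant$planted_trees, function(pt) {
    ls <- tree_leaves(pt$tree, features)
    if (any(vapply(ls, length, integer(1)) == 0)) {
      stop("planted tree has a leaf with zero patients")
    }
    stopifnot(length(pt$leaf_means) == length(ls))
    ls
  })
  set.seed(seed)
  M <- plant$n_modules
  G <- M * plant$probes_per_module + plant$n_null_probes
  module_of <- c(rep(seq_len(M), each = plant$probes_per_module),
                 rep(0L, plant$n_null_probes))
  probe_ids <- sprintf("probe_%05d", seq_len(G))
  baseline <- stats::rnorm(G, plant$baseline_mean, plant$baseline_sd)
  offset <- matrix(0, G, P)
  for (m in seq_len(M)) {
    rows <- which(module_of == m)
    mus <- plant$planted_trees[[m]]$leaf_means
    for (l in seq_along(leaf_sets[[m]])) {
      offset[rows, leaf_sets[[m]][[l]]] <- mus[l]
    }
  }
  R <- plant$replicate_multiplicity
  rep_rows <- rep(seq_len(G), each = R)
  nrow_raw <- G * R
  signal_t <- baseline[rep_rows] + offset[rep_rows, , drop = FALSE] +
    matrix(stats::rnorm(nrow_raw * P, 0, plant$probe_sd), nrow_raw, P)
  signal_n <- baseline[rep_rows] +
    matrix(stats::rnorm(nrow_raw * P, 0, plant$probe_sd), nrow_raw, P)
  bg <- function() matrix(stats::rnorm(nrow_raw * P,
                                       plant$array_background_mean,
                                       plant$array_background_sd),
                          nrow_raw, P)
  fg_t <- 2^signal_t + bg()
  fg_n <- 2^signal_n + bg()
  bg_obs_t <- bg()
  bg_obs_n <- bg()
  mk_targets <- function(tissue) data.frame(
    array_id = sprintf("%s_%s", pats, substr(tissue, 1, 1)),
    patient_id = pats, tissue = tissue)
  truth <- list(module_of = stats::setNames(module_of, probe_ids),
                planted_trees = plant$planted_trees,
                leaf_sets = leaf_sets,
                baseline = stats::setNames(baseline, probe_ids))
  list(tumor = raw_array_set(probe_ids[rep_rows], fg_t, bg_obs_t,
                             mk_targets("tumor")),
       normal = raw_array_set(probe_ids[rep_rows], fg_n, bg_obs_n,
                              mk_targets("normal")),
       truth = truth)
}
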