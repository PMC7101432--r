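## Midpoint threshold between the two patients bracketing quantile q of v:
## planted thresholds always sit inside an inter-patient gap.
threshold_in_gap <- function(v, q) {
  s <- sort(unique(v))
  k <- max(1L, min(length(s) - 1L, round(q * length(s))))
  (s[k] + s[k + 1]) / 2
}

#' Generate a complete synthetic radiogenomic study
#'
#' Builds, in memory, everything the pipeline consumes: a phantom cohort,
#' its ground-truth radiomic feature table (normalized), planted
#' single-split regulator trees over real extracted features, paired
#' tumor/normal raw arrays with the planted module structure, a synthetic
#' pathway database with 24 top-level families and a probe annotation in
#' which each planted module draws most of its genes from one family.
#'
#' Planted thresholds are placed at midpoints between consecutive
#' patient feature values (quantiles 0.35-0.65), so threshold recovery
#' "within one inter-patient gap" is well defined; leaf mean offsets are
#' large enough (|mean effect| > 1 log2 unit) for planted probes to
#' survive the fold-change filter.
#'
#' @param n_patients cohort size, default 45.
#' @param n_modules planted modules, default 3.
#' @param probes_per_module,n_null_probes probe counts; defaults keep the
#'   differentially expressed fraction near 20% so quantile normalization
#'   does not materially attenuate the planted fold-changes.
#' @param probe_sd residual log2 sd.
#' @param regulator_features features carrying the planted splits;
#'   defaults to `SUV_COV`, `irregularity`, `large_area_emphasis`
#'   (recycled as needed).
#' @param seed integer master seed.
#' @return list with `cohort` (phantoms), `features_raw`, `features`
#'   (normalized), `plant`, `expression` (from [plant_expression()]),
#'   `pathways` (db + family genes), `annotation`, `module_families`,
#'   `dose_bq`, `weight_kg`.
#' @export
make_radiogenomic_fixture <- function(n_patients = 45L, n_modules = 3L,
                                      probes_per_module = 60L,
                                      n_null_probes = 600L,
                                      probe_sd = 0.3,
                                      regulator_features = c(
                                        "SUV_COV", "irregularity",
                                        "large_area_emphasis"),
                                      seed = 1L) {
  cohort <- make_cohort(n_patients, seed = seed)
  vols <- lapply(cohort, `[[`, "volume")
  masks <- lapply(cohort, `[[`, "mask")
  feats_raw <- extract_cohort_features(vols, masks)
  feats <- normalize_cohort_features(feats_raw)
  regf <- rep(regulator_features, length.out = n_modules)
  set.seed(seed + 1L)
  trees <- lapply(seq_len(n_modules), function(m) {
    v <- feats[[regf[m]]]
    q <- 0.35 + 0.3 * (m - 1) / max(1, n_modules - 1)
    thr <- threshold_in_gap(v, q)
    # both leaves past the |log2FC| > 1 filter, contrast 1.4 log2 units
    # between leaves; direction alternates across modules
    mus <- if (m %% 2 == 1) c(2.6, 1.2) else c(-1.2, -2.6)
    list(tree = regulator_tree(root = list(feature = regf[m],
                                           threshold = thr)),
         leaf_means = mus)
  })
  plant <- plant_spec(trees, probes_per_module = probes_per_module,
                      n_null_probes = n_null_probes, probe_sd = probe_sd)
  expression <- plant_expression(feats, plant, seed = seed + 2L)
  pw <- make_synthetic_pathway_db(seed = seed + 3L)
  module_families <- names(pw$family_genes)[seq_len(n_modules)]
  annotation <- make_probe_annotation(expression$truth, pw$family_genes,
                                      module_families, seed = seed + 4L)
  set.seed(seed + 5L)
  weight <- stats::rnorm(n_patients, 75, 10)
  dose <- 5e6 * weight * stats::runif(n_patients, 0.9, 1.1)  # ~5 MBq/kg
  list(cohort = cohort, features_raw = feats_raw, features = feats,
       plant = plant, expression = expression, pathways = pw,
       annotation = annotation, module_families = module_families,
       dose_bq = dose, weight_kg = weight)
}

#' Write a synthetic study to disk in pipeline input formats
#'
#' NIfTI volumes (converted from SUV to Bq/ml using the per-patient dose
#' and weight, so the pipeline exercises SUV calibration) and ground-truth
#' masks, a manifest TSV (`patient_id`, `dose_Bq`, `weight_kg`, file
#' paths), long-format raw array TSV (`probe_id`, `array_id`,
#' `foreground`, `background`), annotation TSV, GMT + hierarchy TSV,
#' ground truth JSON, and a ready-to-run pipeline config YAML.
#'
#' @param fixture result of [make_radiogenomic_fixture()].
#' @param dir output directory (created).
#' @param seed seed recorded in the config for the module-network stage.
#' @return path to the written config file.
#' @export
write_fixture <- function(fixture, dir, seed = 1L) {
  dir.create(file.path(dir, "volumes"), recursive = TRUE,
             showWarnings = FALSE)
  n <- length(fixture$cohort)
  man <- data.frame(patient_id = character(n), dose_Bq = fixture$dose_bq,
                    weight_kg = fixture$weight_kg,
                    volume = character(n), mask = character(n))
  for (i in seq_len(n)) {
    v <- fixture$cohort[[i]]$volume
    m <- fixture$cohort[[i]]$mask
    pid <- v$patient_id
    act <- v$values * fixture$dose_bq[i] / (fixture$weight_kg[i] * 1000)
    vol_bq <- pet_volume(act, v$spacing, "Bq/ml", pid)
    vp <- file.path(dir, "volumes", paste0(pid, "_pet.nii.gz"))
    mp <- file.path(dir, "volumes", paste0(pid, "_gt_mask.nii.gz"))
    write_pet_volume(vol_bq, vp)
    write_tumor_mask(m, mp)
    man$patient_id[i] <- pid
    man$volume[i] <- vp
    man$mask[i] <- mp
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  arr <- function(s) {
    data.frame(probe_id = rep(s$probe_id, ncol(s$foreground)),
               array_id = rep(s$targets$array_id,
                              each = length(s$probe_id)),
               foreground = as.vector(s$foreground),
               background = as.vector(s$background))
  }
  both <- rbind(arr(fixture$expression$tumor),
                arr(fixture$expression$normal))
  utils::write.table(both, file.path(dir, "arrays.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  tg <- rbind(fixture$expression$tumor$targets,
              fixture$expression$normal$targets)
  utils::write.table(tg, file.path(dir, "targets.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(fixture$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_gmt(fixture$pathways$db$sets, file.path(dir, "pathways.gmt"))
  utils::write.table(
    data.frame(pathway_id = names(fixture$pathways$db$hierarchy),
               top_level_id = unname(fixture$pathways$db$hierarchy)),
    file.path(dir, "hierarchy.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  truth <- fixture$expression$truth
  jsonlite::write_json(
    list(module_of = as.list(truth$module_of),
         module_families = fixture$module_families,
         planted_trees = lapply(truth$planted_trees, function(pt) {
           list(feature = pt$tree$root$feature,
                threshold = pt$tree$root$threshold,
                leaf_means = pt$leaf_means)
         })),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = 10)
  cfg <- list(
    paths = list(manifest = file.path(dir, "manifest.tsv"),
                 arrays = file.path(dir, "arrays.tsv"),
                 targets = file.path(dir, "targets.tsv"),
                 annotation = file.path(dir, "annotation.tsv"),
                 gmt = file.path(dir, "pathways.gmt"),
                 hierarchy = file.path(dir, "hierarchy.tsv"),
                 out_dir = file.path(dir, "out")),
    segmentation = list(method = "fuzzy"),
    discretization = list(bins = 64L),
    de = list(alpha = 0.01, fc = 2),
    modnet = list(K = 6L, max_iter = 30L, max_depth = 2L, min_leaf = 4L,
                  seed = seed),
    enrichment = list(alpha = 0.05))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_path
}
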