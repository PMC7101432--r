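pipeline_defaults <- function() {
  list(segmentation = list(method = "fuzzy"),
       discretization = list(bins = 64L),
       de = list(alpha = 0.01, fc = 2),
       modnet = list(K = 50L, max_iter = 30L, max_depth = 2L,
                     min_leaf = 4L, seed = 1L,
                     prior = list(mu0 = 0, lambda0 = 1, alpha0 = 1,
                                  beta0 = 0.1)),
       enrichment = list(alpha = 0.05))
}

merge_defaults <- function(cfg, def) {
  for (k in names(def)) {
    if (is.null(cfg[[k]])) {
      cfg[[k]] <- def[[k]]
    } else if (is.list(def[[k]])) {
      cfg[[k]] <- merge_defaults(cfg[[k]], def[[k]])
    }
  }
  cfg
}

#' Validate a pipeline configuration
#'
#' Reads a YAML config, fills defaults (64 texture bins, DE at
#' `p_BH < 0.01` and fold-change > 2, module network with `max_iter 30`,
#' `max_depth 2`, `min_leaf 4`), and checks every referenced input file
#' and every threshold range. All violations are reported together.
#'
#' @param path YAML config file.
#' @return the resolved config (class `pipeline_config`).
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- merge_defaults(yaml::read_yaml(path), pipeline_defaults())
  errs <- character(0)
  need <- c("manifest", "arrays", "targets", "annotation", "gmt",
            "hierarchy", "out_dir")
  for (k in need) {
    if (is.null(cfg$paths[[k]])) {
      errs <- c(errs, sprintf("paths$%s is missing", k))
    } else if (k != "out_dir" && !file.exists(cfg$paths[[k]])) {
      errs <- c(errs, sprintf("paths$%s does not exist: %s", k,
                              cfg$paths[[k]]))
    }
  }
  if (!cfg$segmentation$method %in% c("fixed41", "fuzzy")) {
    errs <- c(errs, "segmentation$method must be 'fixed41' or 'fuzzy'")
  }
  if (!isTRUE(cfg$discretization$bins >= 2)) {
    errs <- c(errs, "discretization$bins must be >= 2")
  }
  if (!isTRUE(cfg$de$alpha > 0 && cfg$de$alpha <= 1)) {
    errs <- c(errs, "de$alpha must be in (0, 1]")
  }
  if (!isTRUE(cfg$de$fc >= 1)) errs <- c(errs, "de$fc must be >= 1")
  if (!isTRUE(cfg$modnet$K >= 1)) errs <- c(errs, "modnet$K must be >= 1")
  if (!cfg$modnet$max_depth %in% 1:2) {
    errs <- c(errs, "modnet$max_depth must be 1 or 2")
  }
  if (!isTRUE(cfg$modnet$min_leaf >= 1)) {
    errs <- c(errs, "modnet$min_leaf must be >= 1")
  }
  if (!isTRUE(cfg$enrichment$alpha > 0 && cfg$enrichment$alpha <= 1)) {
    errs <- c(errs, "enrichment$alpha must be in (0, 1]")
  }
  if (length(errs)) {
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg, section) {
  digest::digest(cfg[[section]], algo = "md5")
}

stage_cached <- function(out_files, hash_file, hash) {
  all(file.exists(out_files)) && file.exists(hash_file) &&
    identical(readLines(hash_file, warn = FALSE)[1], hash)
}

read_arrays_tsv <- function(arrays_path, targets_path) {
  long <- utils::read.delim(arrays_path, stringsAsFactors = FALSE)
  tg <- utils::read.delim(targets_path, stringsAsFactors = FALSE)
  probes <- long$probe_id[long$array_id == long$array_id[1]]
  arrays <- unique(long$array_id)
  fg <- matrix(NA_real_, length(probes), length(arrays),
               dimnames = list(NULL, arrays))
  bg <- fg
  for (a in arrays) {
    sel <- long$array_id == a
    fg[, a] <- long$foreground[sel]
    bg[, a] <- long$background[sel]
  }
  tg <- tg[match(arrays, tg$array_id), ]
  raw_array_set(probes, fg, bg, tg)
}

#' Run the full pipeline
#'
#' Orchestrates the four workflow stages from one validated config:
#' (1) imaging — SUV calibration, tumor segmentation and the 28-feature
#' radiomics battery with 0-1 cohort normalization; (2) differential
#' expression — the paired normexp/quantile/avereps/moderated-t/BH
#' filter; (3) module network — EM fit of regulator trees over the
#' normalized features; (4) annotation — per-module pathway
#' over-representation and top-level roll-up. Stage outputs are written
#' under `paths$out_dir` with config-hash sidecars; a stage whose outputs
#' already match its hash is skipped on rerun.
#'
#' @param cfg a `pipeline_config` from [validate_config()] (or a path to
#'   one).
#' @param quiet suppress progress messages.
#' @return list: `features`, `features_norm`, `de`, `model`,
#'   `module_table`, `annotation` (module summaries), `paths` of written
#'   outputs, `log`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- validate_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$paths$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  log <- list(started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              package_version = as.character(utils::packageVersion("petmodnet")),
              seed = cfg$modnet$seed)

  ## stage 1: imaging -> features
  f_feat <- file.path(out, "features.tsv")
  f_featn <- file.path(out, "features_norm.tsv")
  h1 <- digest::digest(list(cfg$segmentation, cfg$discretization,
                            cfg$paths$manifest), algo = "md5")
  h1f <- file.path(out, "stage_imaging.hash")
  if (stage_cached(c(f_feat, f_featn), h1f, h1)) {
    say("imaging stage cached; skipping")
    feats_raw <- utils::read.delim(f_feat, row.names = 1, check.names = FALSE)
    feats <- utils::read.delim(f_featn, row.names = 1, check.names = FALSE)
    fmin <- vapply(feats_raw, min, numeric(1))
    fmax <- vapply(feats_raw, max, numeric(1))
    keep <- fmax > fmin
    attr(feats, "feature_min") <- fmin[keep][names(feats)]
    attr(feats, "feature_max") <- fmax[keep][names(feats)]
    log$imaging <- "cached"
  } else {
    say("imaging: segmenting and extracting features")
    man <- utils::read.delim(cfg$paths$manifest, stringsAsFactors = FALSE)
    vols <- list(); masks <- list()
    for (i in seq_len(nrow(man))) {
      v <- read_pet_volume(man$volume[i], "Bq/ml", man$patient_id[i])
      suv <- compute_suv(v, man$dose_Bq[i], man$weight_kg[i])
      m <- if (cfg$segmentation$method == "fixed41") {
        segment_fixed_fraction(suv, fraction = 0.41)
      } else {
        segment_fuzzy_adaptive(suv, n_classes = 2L, seed = cfg$modnet$seed)
      }
      vols[[i]] <- suv; masks[[i]] <- m
    }
    feats_raw <- extract_cohort_features(vols, masks,
                                         n_bins = cfg$discretization$bins,
                                         patient_ids = man$patient_id)
    feats <- normalize_cohort_features(feats_raw)
    utils::write.table(feats_raw, f_feat, sep = "\t", quote = FALSE,
                       col.names = NA)
    utils::write.table(feats, f_featn, sep = "\t", quote = FALSE,
                       col.names = NA)
    writeLines(h1, h1f)
    log$imaging <- sprintf("%d patients segmented (%s)", nrow(man),
                           cfg$segmentation$method)
  }

  ## stage 2: differential expression
  say("diffexpr: paired tumor/normal filter")
  raw <- read_arrays_tsv(cfg$paths$arrays, cfg$paths$targets)
  de <- run_diffexpr(raw, alpha = cfg$de$alpha, fc = cfg$de$fc)
  f_de <- file.path(out, "de_result.tsv")
  utils::write.table(de$table, f_de, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log$diffexpr <- sprintf("%d/%d probes retained", de$counts["n_retained"],
                          de$counts["n_probes_unique"])

  ## stage 3: module network
  say("modnet: fitting module network (K = %d)", cfg$modnet$K)
  E <- module_expression(de)
  prior <- do.call(score_prior, cfg$modnet$prior)
  model <- fit_module_network(E, feats, K = cfg$modnet$K,
                              max_iter = cfg$modnet$max_iter,
                              max_depth = cfg$modnet$max_depth,
                              min_leaf = cfg$modnet$min_leaf,
                              seed = cfg$modnet$seed, prior = prior)
  f_model <- file.path(out, "module_network.json")
  write_module_network(model, feats, f_model)
  mt <- module_table(model, feats)
  f_mt <- file.path(out, "module_table.tsv")
  utils::write.table(mt, f_mt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log$modnet <- sprintf("%d modules, score %.2f", length(model$trees),
                        model$score)

  ## stage 4: functional annotation
  say("annotate: pathway over-representation and roll-up")
  annotation <- utils::read.delim(cfg$paths$annotation,
                                  stringsAsFactors = FALSE)
  db <- pathway_db(load_gmt(cfg$paths$gmt),
                   load_hierarchy(cfg$paths$hierarchy))
  ann <- annotate_modules(model, annotation, db,
                          alpha = cfg$enrichment$alpha)
  f_sum <- file.path(out, "module_summary.tsv")
  utils::write.table(ann$summary, f_sum, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log$annotate <- sprintf("%d modules annotated", nrow(ann$summary))
  log$config_hash <- digest::digest(unclass(cfg), algo = "md5")
  jsonlite::write_json(log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE)

  list(features = feats_raw, features_norm = feats, de = de,
       model = model, module_table = mt, annotation = ann,
       paths = list(features = f_feat, features_norm = f_featn, de = f_de,
                    model = f_model, module_table = f_mt,
                    module_summary = f_sum),
       log = log)
}
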