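#' Load a GMT gene-set file
#'
#' Parses GMT (one set per line: name, description, genes...) via
#' `fgsea::gmtPathways`, with validation: duplicate pathway names and
#' empty gene lists are rejected. Gene symbols are uppercased.
#'
#' @param path GMT file.
#' @return named list of character vectors (gene sets).
#' @export
load_gmt <- function(path) {
  lines <- readLines(path)
  nm <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  if (anyDuplicated(nm)) stop("duplicate pathway names in GMT: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- fgsea::gmtPathways(path)
  if (any(vapply(sets, length, integer(1)) == 0)) {
    stop("GMT contains pathway with empty gene list")
  }
  lapply(sets, function(g) unique(toupper(g)))
}

#' Write gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n) {
    paste(c(n, "na", sets[[n]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Load a pathway-to-top-level hierarchy table
#'
#' Two-column TSV (`pathway_id`, `top_level_id`) mapping every pathway to
#' exactly one top-level (main) pathway.
#'
#' @param path TSV file.
#' @return named character vector `pathway_id -> top_level_id`.
#' @export
load_hierarchy <- function(path) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pathway_id", "top_level_id") %in% names(h)))
  if (anyDuplicated(h$pathway_id)) {
    stop("pathway mapped to more than one top-level pathway")
  }
  stats::setNames(h$top_level_id, h$pathway_id)
}

#' Assemble a pathway database
#'
#' Combines gene sets and hierarchy into one object, checking that every
#' pathway maps to exactly one top-level pathway and that the hierarchy
#' does not reference unknown pathways.
#'
#' @param sets named list of gene sets (see [load_gmt()]).
#' @param hierarchy named vector `pathway_id -> top_level_id`.
#' @return a `pathway_db` object: `sets`, `hierarchy`, `top_levels`,
#'   `genes` (the union of all set members).
#' @export
pathway_db <- function(sets, hierarchy) {
  unknown <- setdiff(names(hierarchy), names(sets))
  if (length(unknown)) stop("hierarchy references unknown pathways: ",
                            paste(unknown, collapse = ", "))
  missing <- setdiff(names(sets), names(hierarchy))
  if (length(missing)) stop("pathways missing from hierarchy: ",
                            paste(missing, collapse = ", "))
  structure(list(sets = sets, hierarchy = hierarchy,
                 top_levels = sort(unique(unname(hierarchy))),
                 genes = sort(unique(unlist(sets)))),
            class = "pathway_db")
}

#' Map probes to gene symbols
#'
#' @param probes character vector of probe ids.
#' @param annotation data.frame with columns `probe_id`, `gene_symbol`
#'   (empty/NA symbol = unannotated).
#' @return list: `genes` (unique mapped symbols, uppercased), `coverage`
#'   (mapped probes / total probes).
#' @export
map_probes_to_genes <- function(probes, annotation) {
  stopifnot(all(c("probe_id", "gene_symbol") %in% names(annotation)))
  sym <- annotation$gene_symbol[match(probes, annotation$probe_id)]
  mapped <- !is.na(sym) & sym != ""
  list(genes = sort(unique(toupper(sym[mapped]))),
       coverage = if (length(probes)) mean(mapped) else 0)
}

#' Pathway over-representation for one module
#'
#' Hypergeometric upper-tail test per pathway: with `N` universe genes,
#' `K` of them in the pathway and `n` module genes, the p-value is the
#' probability of an overlap at least as large as observed. P-values are
#' BH-adjusted across pathways; a pathway is called altered when
#' `p_BH < alpha` and the overlap is at least `min_overlap`.
#'
#' @param module_genes character vector of module gene symbols.
#' @param db a [pathway_db()].
#' @param universe character vector of background genes (must contain the
#'   module's in-database genes).
#' @param alpha BH threshold, default 0.05.
#' @param min_overlap minimum overlap to call altered, default 2.
#' @return data.frame per pathway: `pathway`, `overlap`, `size_pathway`,
#'   `p`, `p_BH`, `altered`.
#' @export
enrich_module <- function(module_genes, db, universe, alpha = 0.05,
                          min_overlap = 2L) {
  stopifnot(inherits(db, "pathway_db"))
  universe <- unique(toupper(universe))
  if (length(universe) == 0) stop("empty universe")
  module_genes <- intersect(unique(toupper(module_genes)), universe)
  N <- length(universe)
  n <- length(module_genes)
  rows <- lapply(names(db$sets), function(pw) {
    set <- intersect(db$sets[[pw]], universe)
    K <- length(set)
    ov <- length(intersect(module_genes, set))
    p <- if (K == 0) 1 else
      stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, overlap = ov, size_pathway = K, p = p)
  })
  res <- do.call(rbind, rows)
  res$p_BH <- bh_adjust(res$p)
  res$altered <- res$p_BH < alpha & res$overlap >= min_overlap
  res
}

#' Roll altered pathways up to top-level pathways
#'
#' Percentage of a module's significantly altered pathways that fall
#' under each top-level (main) pathway; percentages sum to 100 whenever
#' there is at least one altered pathway. Also reports the module's
#' dominant top-level pathway and the reporting flags used downstream
#' (> 10 altered pathways; dominance above 50% / 30%).
#'
#' @param enrichment result of [enrich_module()] (or a character vector
#'   of altered pathway ids).
#' @param db a [pathway_db()].
#' @return list: `table` (top_level, count, percent), `n_altered`,
#'   `dominant`, `dominant_percent`, `over_10_altered`, `over_50`,
#'   `over_30`.
#' @export
rollup_top_level <- function(enrichment, db) {
  altered <- if (is.character(enrichment)) enrichment else
    enrichment$pathway[enrichment$altered]
  unknown <- setdiff(altered, names(db$hierarchy))
  if (length(unknown)) stop("altered pathways missing from hierarchy: ",
                            paste(unknown, collapse = ", "))
  n_alt <- length(altered)
  if (n_alt == 0) {
    return(list(table = data.frame(top_level = character(0),
                                   count = integer(0),
                                   percent = numeric(0)),
                n_altered = 0L, dominant = NA_character_,
                dominant_percent = NA_real_, over_10_altered = FALSE,
                over_50 = FALSE, over_30 = FALSE))
  }
  tops <- db$hierarchy[altered]
  tab <- sort(table(tops), decreasing = TRUE)
  out <- data.frame(top_level = names(tab), count = as.integer(tab),
                    percent = 100 * as.integer(tab) / n_alt)
  list(table = out, n_altered = n_alt,
       dominant = out$top_level[1], dominant_percent = out$percent[1],
       over_10_altered = n_alt > 10,
       over_50 = out$percent[1] > 50, over_30 = out$percent[1] > 30)
}

#' Annotate every module of a fitted network
#'
#' Maps each module's probes to genes, runs over-representation and the
#' top-level roll-up, and returns the per-module summary table.
#'
#' @param model a `module_network_model`.
#' @param annotation probe-to-gene data.frame.
#' @param db a [pathway_db()].
#' @param universe background genes; default: all annotated array genes
#'   with a database mapping.
#' @param alpha enrichment BH threshold.
#' @return list: `summary` data.frame (module, n_probes, n_genes,
#'   coverage, n_altered, dominant top-level and percent, flags) and
#'   `details` (per-module enrichment and roll-up).
#' @export
annotate_modules <- function(model, annotation, db, universe = NULL,
                             alpha = 0.05) {
  universe <- universe %||% intersect(
    unique(toupper(annotation$gene_symbol[!is.na(annotation$gene_symbol) &
                                            annotation$gene_symbol != ""])),
    db$genes)
  details <- lapply(seq_along(model$trees), function(m) {
    probes <- names(model$assignment)[model$assignment == m]
    mg <- map_probes_to_genes(probes, annotation)
    enr <- enrich_module(mg$genes, db, universe, alpha)
    roll <- rollup_top_level(enr, db)
    list(module = m, genes = mg, enrichment = enr, rollup = roll)
  })
  summary <- do.call(rbind, lapply(details, function(d) {
    data.frame(module = d$module,
               n_probes = sum(model$assignment == d$module),
               n_genes = length(d$genes$genes),
               coverage = d$genes$coverage,
               n_altered = d$rollup$n_altered,
               dominant = d$rollup$dominant,
               dominant_percent = d$rollup$dominant_percent,
               over_10_altered = d$rollup$over_10_altered,
               over_50 = d$rollup$over_50, over_30 = d$rollup$over_30)
  }))
  list(summary = summary, details = details)
}

#' Synthetic pathway database
#'
#' Builds a pathway database with `n_top` top-level families (default 24,
#' the main-pathway count of the usual hierarchy), each holding
#' `pathways_per_top` pathways of random size over a synthetic gene
#' universe. Gene membership is drawn family-first so that genes of one
#' family co-occur across its pathways, which is what makes family-level
#' roll-up recoverable from planted modules.
#'
#' @param n_top top-level families (default 24).
#' @param pathways_per_top pathways per family.
#' @param genes_per_family genes private to each family.
#' @param set_size_range pathway size range.
#' @param seed integer seed.
#' @return list: `db` (a [pathway_db()]), `family_genes` (named list).
#' @export
make_synthetic_pathway_db <- function(n_top = 24L, pathways_per_top = 5L,
                                      genes_per_family = 40L,
                                      set_size_range = c(10L, 25L),
                                      seed = 1L) {
  set.seed(seed)
  tops <- sprintf("TOP_%02d", seq_len(n_top))
  family_genes <- stats::setNames(lapply(seq_len(n_top), function(f) {
    sprintf("G%02d_%03d", f, seq_len(genes_per_family))
  }), tops)
  sets <- list()
  hierarchy <- character(0)
  for (f in seq_len(n_top)) {
    for (w in seq_len(pathways_per_top)) {
      nm <- sprintf("PW_%02d_%02d", f, w)
      sz <- sample(set_size_range[1]:set_size_range[2], 1)
      sets[[nm]] <- sample(family_genes[[f]], min(sz, genes_per_family))
      hierarchy[nm] <- tops[f]
    }
  }
  list(db = pathway_db(sets, hierarchy), family_genes = family_genes)
}

#' Synthetic probe annotation
#'
#' Assigns gene symbols to probe ids: probes of each planted module draw
#' `family_fraction` of their genes from one pathway family (module
#' `m` maps to family `module_families[m]`), the rest (and null probes)
#' from the whole gene pool; a fraction of probes is left unannotated.
#'
#' @param truth ground truth from [plant_expression()].
#' @param family_genes named list from [make_synthetic_pathway_db()].
#' @param module_families character vector: family (top-level id) per
#'   planted module.
#' @param family_fraction fraction of each module's probes annotated into
#'   its family (default 0.8).
#' @param unannotated_fraction fraction of probes with no gene symbol.
#' @param seed integer seed.
#' @return data.frame `probe_id`, `gene_symbol`.
#' @export
make_probe_annotation <- function(truth, family_genes, module_families,
                                  family_fraction = 0.8,
                                  unannotated_fraction = 0.2, seed = 1L) {
  set.seed(seed)
  probes <- names(truth$module_of)
  pool <- unlist(family_genes, use.names = FALSE)
  sym <- character(length(probes))
  for (i in seq_along(probes)) {
    m <- truth$module_of[i]
    sym[i] <- if (m > 0 && stats::runif(1) < family_fraction) {
      sample(family_genes[[module_families[m]]], 1)
    } else {
      sample(pool, 1)
    }
  }
  drop <- stats::runif(length(probes)) < unannotated_fraction
  sym[drop] <- NA_character_
  data.frame(probe_id = probes, gene_symbol = sym,
             stringsAsFactors = FALSE)
}
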