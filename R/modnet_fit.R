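## Leaf bookkeeping for a set of module trees: indicator matrix
## (patients x total leaves), each leaf's module, and per-leaf patient counts.
build_leaf_index <- function(trees, regulators) {
  P <- nrow(regulators)
  leaves <- list()
  leaf_module <- integer(0)
  for (m in seq_along(trees)) {
    ls <- tree_leaves(trees[[m]], regulators)
    leaves <- c(leaves, ls)
    leaf_module <- c(leaf_module, rep.int(m, length(ls)))
  }
  L <- length(leaves)
  Lmat <- matrix(0, P, L)
  for (l in seq_len(L)) Lmat[leaves[[l]], l] <- 1
  list(Lmat = Lmat, leaf_module = leaf_module,
       leaf_n = colSums(Lmat), n_leaves = L)
}

## Per-leaf pooled sufficient statistics for the current assignment.
leaf_aggregates <- function(E, assign, li) {
  K <- max(li$leaf_module)
  s1m <- matrix(0, K, ncol(E)); s2m <- matrix(0, K, ncol(E))
  for (m in seq_len(K)) {
    rows <- assign == m
    if (any(rows)) {
      s1m[m, ] <- colSums(E[rows, , drop = FALSE])
      s2m[m, ] <- colSums(E[rows, , drop = FALSE]^2)
    }
  }
  nm <- tabulate(assign, nbins = K)
  A1 <- s1m %*% li$Lmat
  A2 <- s2m %*% li$Lmat
  sel <- cbind(li$leaf_module, seq_len(li$n_leaves))
  list(N = nm[li$leaf_module] * li$leaf_n, S1 = A1[sel], S2 = A2[sel])
}

#' Reassign probes to modules (E-step)
#'
#' One sequential sweep of the EM E-step: each probe in turn is removed
#' from its module and reassigned to the module whose regulator tree gives
#' it the highest log posterior-predictive density (sum over leaves of the
#' marginal-likelihood increment of adding the probe's leaf values to the
#' module's pooled leaf posterior, computed without that probe). Ties go
#' to the lowest module index. Sequential single-probe moves make the
#' total Bayesian score non-decreasing.
#'
#' @param E numeric matrix, probes x patients.
#' @param trees list of [regulator_tree()], one per module.
#' @param regulators data.frame, patients x normalized features.
#' @param assign integer vector: current module of each probe.
#' @param prior a [score_prior()].
#' @return integer vector of updated module assignments.
#' @export
assign_genes <- function(E, trees, regulators, assign,
                         prior = score_prior()) {
  stopifnot(nrow(E) == length(assign), ncol(E) == nrow(regulators),
            all(assign >= 1), all(assign <= length(trees)))
  li <- build_leaf_index(trees, regulators)
  ag <- leaf_aggregates(E, assign, li)
  N <- ag$N; S1 <- ag$S1; S2 <- ag$S2
  K <- length(trees)
  Esq <- E^2
  for (g in seq_len(nrow(E))) {
    xs1 <- as.numeric(E[g, , drop = FALSE] %*% li$Lmat)
    xs2 <- as.numeric(Esq[g, , drop = FALSE] %*% li$Lmat)
    m0 <- assign[g]
    own <- li$leaf_module == m0
    N[own] <- N[own] - li$leaf_n[own]
    S1[own] <- S1[own] - xs1[own]
    S2[own] <- S2[own] - xs2[own]
    pred_leaf <- leaf_log_marginal_ss(N + li$leaf_n, S1 + xs1, S2 + xs2,
                                      prior) -
      leaf_log_marginal_ss(N, S1, S2, prior)
    pred <- as.numeric(rowsum(pred_leaf, li$leaf_module,
                              reorder = TRUE))
    m1 <- which(pred >= max(pred) - 1e-12)[1]  # tie -> lowest index
    tgt <- li$leaf_module == m1
    N[tgt] <- N[tgt] + li$leaf_n[tgt]
    S1[tgt] <- S1[tgt] + xs1[tgt]
    S2[tgt] <- S2[tgt] + xs2[tgt]
    assign[g] <- m1
  }
  assign
}

total_score <- function(E, assign, trees, regulators, prior) {
  li <- build_leaf_index(trees, regulators)
  ag <- leaf_aggregates(E, assign, li)
  sum(leaf_log_marginal_ss(ag$N, ag$S1, ag$S2, prior))
}

## Greedy module merging: repeatedly merge the pair of modules whose
## pooled score (under the better of the two existing trees) exceeds the
## sum of their separate scores. Escapes the local optima where one true
## module sits split across modules with equivalent trees, which
## single-probe E-step moves cannot repair (each move is score-neutral).
## Only score-increasing merges are accepted, so monotonicity holds.
merge_modules <- function(E, assign, trees, regulators, prior,
                          max_depth = 2L, min_leaf = 4L) {
  repeat {
    occupied <- sort(unique(assign))
    if (length(occupied) < 2) break
    # with few modules, also consider a freshly learned tree for the
    # pooled pair (catches splits whose halves carry different trees)
    relearn <- length(occupied) <= 15L
    msc <- vapply(occupied, function(m) {
      tree_score(E[assign == m, , drop = FALSE], trees[[m]], regulators,
                 prior)
    }, numeric(1))
    best <- NULL
    for (a in seq_along(occupied)) for (b in seq_len(a - 1)) {
      m1 <- occupied[b]; m2 <- occupied[a]
      rows <- assign == m1 | assign == m2
      Em <- E[rows, , drop = FALSE]
      cands <- list(trees[[m1]], trees[[m2]])
      if (relearn) {
        cands <- c(cands, list(learn_regulator_tree(Em, regulators,
                                                    max_depth, min_leaf,
                                                    prior)))
      }
      sc <- vapply(cands, function(tr) tree_score(Em, tr, regulators, prior),
                   numeric(1))
      delta <- max(sc) - msc[b] - msc[a]
      if (delta > 1e-9 && (is.null(best) || delta > best$delta)) {
        best <- list(m1 = m1, m2 = m2, delta = delta,
                     tree = cands[[which.max(sc)]])
      }
    }
    if (is.null(best)) break
    assign[assign == best$m2] <- best$m1
    trees[[best$m1]] <- best$tree
    trees[[best$m2]] <- regulator_tree()
  }
  list(assign = assign, trees = trees)
}

#' Fit a module network
#'
#' Learns gene modules whose expression variation across patients is
#' explained by threshold trees over normalized PET radiomic features.
#' Probes are initialized into `K` modules by seeded k-means on their
#' expression profiles, then EM alternates tree learning
#' ([learn_regulator_tree()]; the previous tree is kept when the fresh
#' greedy tree does not improve the module score) with sequential probe
#' reassignment ([assign_genes()]) followed by score-guided module
#' merging (pairs of modules are pooled when that raises the total
#' score, emptying redundant modules left over from initialization),
#' until no assignment changes or `max_iter` iterations. The total Bayesian score is non-decreasing
#' across iterations; empty modules are pruned from the output.
#'
#' @param E numeric matrix, probes x patients (rows named by probe id);
#'   typically per-probe-centered paired log2 tumor/normal ratios.
#' @param regulators data.frame, patients x normalized (0-1) features.
#' @param K initial number of modules (>= 1), default 50.
#' @param max_iter maximum EM iterations, default 30.
#' @param max_depth,min_leaf tree constraints (defaults 2 and 4).
#' @param seed integer seed for the k-means initialization.
#' @param prior a [score_prior()].
#' @return a `module_network_model`: `assignment` (named integer vector,
#'   module ids 1..M over nonempty modules), `trees`, `module_sizes`,
#'   `leaf_stats` (per module/leaf count, mean, variance), `score`,
#'   `iteration_log`, plus the fitting parameters.
#' @export
fit_module_network <- function(E, regulators, K = 50L, max_iter = 30L,
                               max_depth = 2L, min_leaf = 4L, seed = 1L,
                               prior = score_prior()) {
  E <- as.matrix(E)
  stopifnot(ncol(E) == nrow(regulators), max_iter >= 1)
  if (K < 1) stop("K must be >= 1")
  G <- nrow(E)
  K <- min(as.integer(K), G)
  if (is.null(rownames(E))) rownames(E) <- sprintf("probe_%05d", seq_len(G))
  set.seed(seed)
  assign <- if (K == 1L) rep(1L, G) else {
    km <- tryCatch(stats::kmeans(E, centers = K, nstart = 3, iter.max = 50),
                   error = function(e) NULL)
    if (is.null(km)) ((seq_len(G) - 1L) %% K) + 1L else km$cluster
  }
  trees <- replicate(K, regulator_tree(), simplify = FALSE)
  log <- data.frame(iteration = integer(0), score = numeric(0),
                    n_changed = integer(0))
  score_prev <- -Inf
  for (it in seq_len(max_iter)) {
    # M-step: (re)learn each nonempty module's tree; keep the old tree
    # when the new one does not improve that module's score
    for (m in seq_len(K)) {
      rows <- which(assign == m)
      if (length(rows) == 0) { trees[[m]] <- regulator_tree(); next }
      Em <- E[rows, , drop = FALSE]
      cand <- learn_regulator_tree(Em, regulators, max_depth, min_leaf, prior)
      s_new <- tree_score(Em, cand, regulators, prior)
      s_old <- tree_score(Em, trees[[m]], regulators, prior)
      if (s_new > s_old) trees[[m]] <- cand
    }
    # merge redundant modules while their contents are still exchangeable
    # (before E-step sweeps can segregate duplicates), then reassign
    old_assign <- assign
    mg <- merge_modules(E, assign, trees, regulators, prior, max_depth, min_leaf)
    assign <- mg$assign; trees <- mg$trees
    assign <- assign_genes(E, trees, regulators, assign, prior)
    mg <- merge_modules(E, assign, trees, regulators, prior, max_depth, min_leaf)
    assign <- mg$assign; trees <- mg$trees
    sc <- total_score(E, assign, trees, regulators, prior)
    changed <- sum(assign != old_assign)
    log <- rbind(log, data.frame(iteration = it, score = sc,
                                 n_changed = changed))
    if (sc < score_prev - 1e-6) {
      stop(sprintf("internal error: score decreased at iteration %d", it))
    }
    score_prev <- sc
    if (changed == 0 && it > 1) break
  }
  # prune empty modules, renumber in original order
  nonempty <- sort(unique(assign))
  remap <- integer(K); remap[nonempty] <- seq_along(nonempty)
  final_assign <- stats::setNames(remap[assign], rownames(E))
  final_trees <- trees[nonempty]
  leaf_stats <- lapply(seq_along(final_trees), function(m) {
    rows <- which(final_assign == m)
    ls <- tree_leaves(final_trees[[m]], regulators)
    do.call(rbind, lapply(seq_along(ls), function(l) {
      vals <- as.numeric(E[rows, ls[[l]], drop = FALSE])
      data.frame(module = m, leaf = l, n_patients = length(ls[[l]]),
                 n_values = length(vals),
                 mean = mean(vals), var = stats::var(vals))
    }))
  })
  structure(list(assignment = final_assign, trees = final_trees,
                 module_sizes = as.integer(table(final_assign)),
                 leaf_stats = do.call(rbind, leaf_stats),
                 score = score_prev, iteration_log = log,
                 K = K, max_depth = max_depth, min_leaf = min_leaf,
                 seed = seed, prior = prior),
            class = "module_network_model")
}

#' @export
print.module_network_model <- function(x, ...) {
  cat(sprintf("<module_network_model> %d modules over %d probes, score %.2f (%d iterations)\n",
              length(x$trees), length(x$assignment), x$score,
              nrow(x$iteration_log)))
  invisible(x)
}

#' Module table (regulators and group sizes per module)
#'
#' Renders the fitted model as a per-module table: probe count, up to
#' three regulators with percent thresholds (and raw units when the
#' feature ranges are attached to `regulators`), and the leaf group-size
#' string.
#'
#' @param model a `module_network_model`.
#' @param regulators the normalized regulator matrix used for fitting.
#' @return data.frame with one row per module.
#' @export
module_table <- function(model, regulators) {
  rows <- lapply(seq_along(model$trees), function(m) {
    f <- format_tree(model$trees[[m]], regulators)
    data.frame(module = m, n_probes = model$module_sizes[m],
               regulator1 = f$regulator1, regulator2 = f$regulator2,
               regulator3 = f$regulator3, groups = f$groups)
  })
  do.call(rbind, rows)
}

#' Serialize a fitted module network to JSON
#'
#' Writes assignments, trees (with normalized, percent and raw-unit
#' thresholds), leaf patient ids, module sizes and the score, in a stable
#' key order so identical fits produce byte-identical files.
#'
#' @param model a `module_network_model`.
#' @param regulators the normalized regulator matrix used for fitting.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_module_network <- function(model, regulators, path) {
  fmin <- attr(regulators, "feature_min")
  fmax <- attr(regulators, "feature_max")
  pid <- rownames(regulators) %||% sprintf("P%02d", seq_len(nrow(regulators)))
  trees <- lapply(seq_along(model$trees), function(m) {
    tr <- model$trees[[m]]
    th <- thresholds_to_percent(tr, fmin, fmax)
    leaves <- tree_leaves(tr, regulators)
    list(module = m, n_probes = model$module_sizes[m], splits = th,
         leaf_patients = lapply(leaves, function(l) pid[l]))
  })
  obj <- list(n_modules = length(model$trees),
              score = model$score,
              module_sizes = model$module_sizes,
              assignment = as.list(model$assignment),
              trees = trees,
              iterations = nrow(model$iteration_log),
              seed = model$seed,
              prior = unclass(model$prior))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}
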