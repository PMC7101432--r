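test_that("the leaf marginal matches quadrature and chain-rule oracles", {
  pr <- score_prior()
  expect_equal(leaf_log_marginal(numeric(0), pr), 0)
  expect_equal(leaf_log_marginal(0, pr),
               oracle_ng_marginal_log(0, 0, 1, 1, 0.1), tolerance = 1e-8)
  set.seed(1)
  for (r in 1:10) {
    x <- stats::rnorm(sample(1:6, 1), sample(-1:1, 1), 0.8)
    expect_equal(leaf_log_marginal(x, pr),
                 oracle_ng_chain_log(x, 0, 1, 1, 0.1), tolerance = 1e-10)
    expect_equal(leaf_log_marginal(x, pr),
                 oracle_ng_marginal_log(x, 0, 1, 1, 0.1), tolerance = 1e-8)
  }
  # non-default hyperparameters exercise every term
  pr2 <- score_prior(mu0 = 0.5, lambda0 = 2, alpha0 = 1.5, beta0 = 0.3)
  x <- c(-0.4, 0.2, 0.9)
  expect_equal(leaf_log_marginal(x, pr2),
               oracle_ng_chain_log(x, 0.5, 2, 1.5, 0.3), tolerance = 1e-10)
})

test_that("tree scores decompose over leaves and penalize spurious splits", {
  sim <- planted_modnet_sim(probes_per_module = 30, seed = 2)
  E1 <- sim$E[sim$truth == 1, , drop = FALSE]
  pr <- score_prior()
  trivial <- regulator_tree()
  expect_equal(tree_score(E1, trivial, sim$feats, pr),
               leaf_log_marginal(as.numeric(E1), pr))
  # planted shift: the true split tree must beat the trivial tree
  expect_gt(tree_score(E1, sim$trees[[1]], sim$feats, pr),
            tree_score(E1, trivial, sim$feats, pr))
  # i.i.d. data: a fixed split wins at best rarely, and not in expectation
  set.seed(3)
  deltas <- replicate(100, {
    Ei <- matrix(stats::rnorm(5 * 45), 5, 45)
    tree_score(Ei, sim$trees[[1]], sim$feats, pr) -
      tree_score(Ei, trivial, sim$feats, pr)
  })
  expect_lt(mean(deltas), 0)
  # malformed regulators break the partition and are caught
  bad <- sim$feats
  bad$SUV_COV[3] <- NA
  expect_error(tree_score(E1, sim$trees[[1]], bad, pr), "partition")
})

test_that("greedy tree learning recovers a planted single split", {
  set.seed(4)
  n <- 45
  f <- data.frame(f1 = stats::runif(n), f2 = stats::runif(n))
  E <- matrix(stats::rnorm(40 * n, 0, 0.3), 40, n)
  E[, f$f1 < 0.4] <- E[, f$f1 < 0.4] + 2
  tree <- learn_regulator_tree(E, f)
  expect_equal(tree$root$feature, "f1")
  sorted <- sort(f$f1)
  below <- max(sorted[sorted < 0.4])
  above <- min(sorted[sorted >= 0.4])
  expect_gt(tree$root$threshold, below)
  expect_lt(tree$root$threshold, above)
  # exhaustive split-search oracle agrees on the root choice
  pr <- score_prior()
  best <- -Inf; best_split <- NULL
  for (feat in names(f)) {
    v <- sort(unique(f[[feat]]))
    for (k in seq_len(length(v) - 1)) {
      thr <- (v[k] + v[k + 1]) / 2
      cand <- regulator_tree(list(feature = feat, threshold = thr))
      lv <- tree_leaves(cand, f)
      if (min(lengths(lv)) < 4) next
      s <- tree_score(E, cand, f, pr)
      if (s > best) { best <- s; best_split <- c(feat, thr) }
    }
  }
  expect_equal(tree$root$feature, best_split[1])
  expect_equal(tree$root$threshold, as.numeric(best_split[2]))
  # constant expression: nothing to explain
  expect_equal(tree_depth(learn_regulator_tree(matrix(1, 10, n), f)), 0)
})

test_that("trees respect depth, leaf-count and minimum-leaf constraints", {
  sim <- planted_modnet_sim(seed = 5)
  fit <- fit_module_network(sim$E, sim$feats, K = 6, seed = 0)
  for (tr in fit$trees) {
    expect_lte(petmodnet:::tree_depth(tr), 2)
    leaves <- tree_leaves(tr, sim$feats)
    expect_lte(length(leaves), 4)
    expect_gte(min(lengths(leaves)), 4)
    expect_lte(length(petmodnet:::tree_features(tr)), 3)
    # leaves partition the cohort
    expect_setequal(unlist(leaves), seq_len(nrow(sim$feats)))
  }
})

test_that("module-table rendering of a depth-2 tree round-trips", {
  # engineered cohort reproducing a [15|24][06] group-size layout
  n <- 45
  f <- data.frame(
    SUV_COV = c(seq(0.0, 0.78, length.out = 39), seq(0.8, 1, length.out = 6)),
    max_distance_to_background = c(rep(0.02, 15), rep(0.4, 24),
                                   seq(0, 1, length.out = 6)))
  tr <- regulator_tree(
    root = list(feature = "SUV_COV", threshold = 0.792),
    left = list(feature = "max_distance_to_background", threshold = 0.057))
  row <- format_tree(tr, f)
  expect_equal(row$regulator1, "SUV_COV 79.2%")
  expect_equal(row$regulator2, "max_distance_to_background 5.7%")
  expect_equal(row$regulator3, "-")
  expect_equal(row$groups, "[15|24][06]")
  back <- parse_tree(row)
  expect_equal(back$root$feature, "SUV_COV")
  expect_equal(back$root$threshold, 0.792)
  expect_equal(back$left$threshold, 0.057)
  expect_null(back$right)
})

test_that("percent display is a fixed rescaling, not a patient quantile", {
  tr <- regulator_tree(list(feature = "f", threshold = 0.05))
  disp <- thresholds_to_percent(tr)
  expect_equal(disp$root$percent, 5.0)
  expect_equal(thresholds_to_percent(
    regulator_tree(list(feature = "f", threshold = 0)))$root$percent, 0.0)
  # skewed feature: a 5%-of-range cut does not isolate 5% of patients
  v <- (exp(seq(0, 5, length.out = 40)) - 1) / (exp(5) - 1)
  expect_gt(mean(v < 0.05), 0.4)
})

test_that("gene reassignment is exact on well-separated planted modules", {
  set.seed(6)
  n <- 30
  f <- data.frame(f1 = stats::runif(n))
  rownames(f) <- sprintf("P%02d", 1:n)
  t1 <- regulator_tree(list(feature = "f1", threshold = 0.5))
  E <- matrix(stats::rnorm(60 * n, 0, 0.2), 60, n)
  hot <- f$f1 >= 0.5
  E[1:30, hot] <- E[1:30, hot] + 3
  E[31:60, hot] <- E[31:60, hot] - 3
  E <- sweep(E, 1, rowMeans(E))
  trees <- list(t1, t1)
  start <- rep(c(1L, 2L), 30)  # scrambled start
  out <- assign_genes(E, trees, f, start)
  expect_equal(length(unique(out[1:30])), 1)
  expect_equal(length(unique(out[31:60])), 1)
  expect_false(out[1] == out[31])
  # single module: nothing can move
  expect_equal(assign_genes(E, list(t1), f, rep(1L, 60)), rep(1L, 60))
})

test_that("exact predictive ties resolve to the lowest module index", {
  f <- data.frame(f1 = seq(0, 1, length.out = 10))
  E <- matrix(stats::rnorm(10, 0, 1), 1, 10)
  trees <- list(regulator_tree(), regulator_tree())  # identical empty modules
  out <- assign_genes(E, trees, f, 2L)
  expect_equal(out, 1L)
})

test_that("module-network fitting recovers planted structure deterministically", {
  sim <- planted_modnet_sim(probes_per_module = 40, seed = 7)
  fit <- fit_module_network(sim$E, sim$feats, K = 5, seed = 0)
  expect_gte(ari(fit$assignment, sim$truth), 0.9)
  expect_false(is.unsorted(fit$iteration_log$score))
  fit2 <- fit_module_network(sim$E, sim$feats, K = 5, seed = 0)
  expect_identical(fit$assignment, fit2$assignment)
  expect_identical(fit$score, fit2$score)
  # K = 1: everything in one module under the best single tree
  fit1 <- fit_module_network(sim$E, sim$feats, K = 1, seed = 0)
  expect_equal(length(fit1$trees), 1)
  expect_equal(unname(fit1$module_sizes), nrow(sim$E))
  expect_error(fit_module_network(sim$E, sim$feats, K = 0), "K")
})

test_that("fitting is invariant to patient order", {
  sim <- planted_modnet_sim(probes_per_module = 25, seed = 8)
  fit <- fit_module_network(sim$E, sim$feats, K = 4, seed = 0)
  set.seed(9)
  perm <- sample(ncol(sim$E))
  fp <- sim$feats[perm, , drop = FALSE]
  rownames(fp) <- rownames(sim$feats)[perm]
  fit_p <- fit_module_network(sim$E[, perm], fp, K = 4, seed = 0)
  expect_identical(fit$assignment, fit_p$assignment)
  roots <- function(m) lapply(m$trees, function(t) t$root)
  expect_equal(roots(fit), roots(fit_p))
  expect_equal(fit$score, fit_p$score, tolerance = 1e-9)
})

test_that("serialized models are stable and loadable", {
  sim <- planted_modnet_sim(probes_per_module = 20, seed = 10)
  fit <- fit_module_network(sim$E, sim$feats, K = 3, seed = 0)
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  write_module_network(fit, sim$feats, p1)
  write_module_network(fit, sim$feats, p2)
  expect_identical(readLines(p1), readLines(p2))
  obj <- jsonlite::read_json(p1)
  expect_equal(obj$n_modules, length(fit$trees))
  expect_equal(length(obj$assignment), nrow(sim$E))
})
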