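test_that("normexp conditional mean matches quadrature and is monotone", {
  mu <- 100; sigma <- 10; alpha <- 1000
  got <- normexp_signal(mu, sigma, alpha, 120)
  expect_equal(got, oracle_normexp_signal(mu, sigma, alpha, 120),
               tolerance = 1e-6)
  for (x in c(-50, 0, 90, 150, 500)) {
    expect_equal(normexp_signal(mu, sigma, alpha, x),
                 oracle_normexp_signal(mu, sigma, alpha, x),
                 tolerance = 1e-5)
  }
  xs <- seq(-200, 400, by = 7)
  ys <- normexp_signal(mu, sigma, alpha, xs)
  expect_true(all(diff(ys) > 0))
  expect_true(all(ys > 0))
  # vanishing-noise limit: corrected -> max(x - mu, floor)
  expect_equal(normexp_signal(mu, 1e-6, alpha, 150), 50, tolerance = 1e-3)
})

test_that("normexp correction of raw arrays is positive and monotone", {
  set.seed(1)
  fg <- matrix(2^stats::rnorm(600, 8, 1) + stats::rnorm(600, 80, 10),
               300, 2)
  bg <- matrix(stats::rnorm(600, 80, 10), 300, 2)
  out <- normexp_correct(fg, bg)
  expect_true(all(out > 0))
  for (a in 1:2) {
    o <- order(fg[, a] - bg[, a])
    expect_true(all(diff(out[o, a]) > 0))
  }
})

test_that("quantile normalization equalizes distributions", {
  m <- cbind(c(1, 2, 3), c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(qn[, 1], c(2.5, 3.5, 4.5))
  expect_equal(qn[, 2], c(2.5, 3.5, 4.5))
  ident <- cbind(c(3, 1, 2), c(3, 1, 2))
  expect_equal(quantile_normalize(ident), ident)
  set.seed(2)
  r <- matrix(stats::rnorm(200), 50, 4)
  qr <- quantile_normalize(r)
  sorted <- apply(qr, 2, sort)
  expect_equal(sorted[, 1], sorted[, 2])
  expect_equal(sorted[, 1], sorted[, 4])
  expect_equal(quantile_normalize(qr), qr)  # idempotent
})

test_that("replicate averaging means duplicates in first-occurrence order", {
  m <- rbind(c(1, 3), c(3, 5), c(7, 7))
  out <- average_replicates(m, c("P1", "P1", "P2"))
  expect_equal(unname(out["P1", ]), c(2, 4))
  expect_equal(unname(out["P2", ]), c(7, 7))
  expect_equal(rownames(out), c("P1", "P2"))
  u <- matrix(1:6, 3, 2, dimnames = list(NULL, NULL))
  expect_equal(unname(average_replicates(u, c("a", "b", "c"))), unname(u))
  # random replicate structure vs a group-by-mean oracle
  set.seed(3)
  ids <- sample(sprintf("g%02d", 1:20), 100, replace = TRUE)
  r <- matrix(stats::rnorm(300), 100, 3)
  got <- average_replicates(r, ids)
  want <- rowsum(r, ids) / as.vector(table(ids)[rownames(rowsum(r, ids))])
  expect_equal(got[sort(rownames(got)), ], want[sort(rownames(want)), ])
})

test_that("moderated t reduces to the ordinary paired t when d0 = 0", {
  tumor <- rbind(c(2, 3, 4), c(1, 1.5, 0.5), c(0, 1, 2))
  normal <- rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))
  rownames(tumor) <- rownames(normal) <- c("a", "b", "c")
  res <- paired_moderated_t(tumor, normal, prior_df = 0)
  # probe "a": diffs 1,2,3 -> t = 2 / (1/sqrt(3)), p on 2 df
  expect_equal(res$t[1], 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(res$p[1], 2 * stats::pt(-2 * sqrt(3), df = 2),
               tolerance = 1e-6)
  expect_equal(res$p[1], 0.0742, tolerance = 1e-3)
  expect_equal(res$log2FC[1], 2)
})

test_that("infinite prior df shrinks every variance to the common value", {
  set.seed(4)
  tumor <- matrix(stats::rnorm(50 * 6, 0, c(0.2, 2)), 50, 6)
  normal <- matrix(stats::rnorm(50 * 6), 50, 6)
  res <- paired_moderated_t(tumor, normal, prior_df = Inf)
  d <- tumor - normal
  s0 <- attr(res, "prior_var")
  expect_equal(res$t, rowMeans(d) / sqrt(s0 / 6), tolerance = 1e-10)
})

test_that("moderated t agrees with the limma route", {
  set.seed(5)
  n <- 8
  tumor <- matrix(stats::rnorm(200 * n, 0.2, 1), 200, n)
  normal <- matrix(stats::rnorm(200 * n, 0, 1), 200, n)
  res <- paired_moderated_t(tumor, normal)
  fit <- limma::eBayes(limma::lmFit(tumor - normal,
                                    design = matrix(1, n, 1)))
  expect_equal(res$t, as.vector(fit$t), tolerance = 1e-8)
  expect_equal(res$p, as.vector(fit$p.value), tolerance = 1e-8)
})

test_that("null simulation holds its nominal type-I error", {
  set.seed(6)
  n <- 10
  tumor <- matrix(stats::rnorm(5000 * n), 5000, n)
  normal <- matrix(stats::rnorm(5000 * n), 5000, n)
  res <- paired_moderated_t(tumor, normal)
  frac <- mean(res$p < 0.05)
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.06)
})

test_that("moderated t outperforms the ordinary t on heteroscedastic probes", {
  set.seed(7)
  n <- 5
  sds <- sqrt(1 / stats::rgamma(400, 4, 4))
  alt <- matrix(stats::rnorm(400 * n, 0.9, sds), 400, n)
  null <- matrix(stats::rnorm(2000 * n, 0, sqrt(1 / stats::rgamma(2000, 4, 4))),
                 2000, n)
  zeros <- matrix(0, 400, n); zeros_n <- matrix(0, 2000, n)
  mod_alt <- paired_moderated_t(rbind(alt, null), rbind(zeros, zeros_n))
  ord_alt <- paired_moderated_t(rbind(alt, null), rbind(zeros, zeros_n),
                                prior_df = 0)
  is_alt <- c(rep(TRUE, 400), rep(FALSE, 2000))
  thr <- 0.01
  # comparable type-I, higher power for the moderated statistic
  expect_lte(abs(mean(mod_alt$p[!is_alt] < thr) -
                   mean(ord_alt$p[!is_alt] < thr)), 0.01)
  expect_gt(mean(mod_alt$p[is_alt] < thr), mean(ord_alt$p[is_alt] < thr))
})

test_that("BH adjustment executes the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(8)
  for (len in 1:8) {
    for (rep in 1:5) {
      p <- round(stats::runif(len), 3)
      expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    }
  }
})

test_that("DE selection applies strict FDR and fold-change rules", {
  de <- data.frame(probe_id = c("a", "b", "c"),
                   log2FC = log2(c(2.5, 1.5, 3)),
                   p_BH = c(0.005, 0.005, 0.02))
  expect_equal(select_de_probes(de), "a")
  de2 <- data.frame(probe_id = c("a", "b"), log2FC = c(0.5, -0.2),
                    p_BH = c(0.5, 0.9))
  expect_equal(select_de_probes(de2, alpha = 1, fc = 1), c("a", "b"))
})

test_that("planted probes survive the DE filter and null probes do not", {
  feats <- data.frame(f = seq(0, 1, length.out = 12))
  rownames(feats) <- sprintf("P%02d", 1:12)
  plant <- plant_spec(
    list(list(tree = regulator_tree(list(feature = "f", threshold = 0.5)),
              leaf_means = c(2, 2))),
    probes_per_module = 30, n_null_probes = 400, probe_sd = 0.25)
  ex <- plant_expression(feats, plant, seed = 9)
  de <- run_diffexpr(bind_array_sets(ex$tumor, ex$normal))
  truth <- ex$truth$module_of
  planted <- names(truth)[truth > 0]
  nulls <- names(truth)[truth == 0]
  # quantile normalization maps each array's extreme ranks onto the
  # cross-array mean, which can crush the fold-change of the one planted
  # probe that tops the intensity ranking; everything else survives
  expect_gte(mean(planted %in% de$retained), 0.96)
  expect_lte(mean(nulls %in% de$retained), 0.01)
  # DE table invariants
  expect_true(all(de$table$p_BH >= de$table$p))
  expect_identical(de$table$retained,
                   de$table$p_BH < 0.01 & abs(de$table$log2FC) > 1)
})

test_that("an all-null array set keeps roughly no probes", {
  feats <- data.frame(f = seq(0, 1, length.out = 10))
  rownames(feats) <- sprintf("P%02d", 1:10)
  plant <- plant_spec(
    list(list(tree = regulator_tree(), leaf_means = 0)),
    probes_per_module = 1, n_null_probes = 1999, probe_sd = 0.3)
  ex <- plant_expression(feats, plant, seed = 10)
  de <- run_diffexpr(bind_array_sets(ex$tumor, ex$normal))
  expect_lte(length(de$retained) / 2000, 0.01)
})

test_that("unpaired designs are rejected", {
  feats <- data.frame(f = c(0, 0.5, 1))
  rownames(feats) <- c("P1", "P2", "P3")
  plant <- plant_spec(list(list(tree = regulator_tree(), leaf_means = 1)),
                      probes_per_module = 5, n_null_probes = 5)
  ex <- plant_expression(feats, plant, seed = 11)
  broken <- ex$tumor
  broken$targets$patient_id[1] <- "P9"
  expect_error(run_diffexpr(bind_array_sets(broken, ex$normal)),
               "exactly one tumor")
})
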