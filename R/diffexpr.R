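#' Raw single-channel array set
#'
#' Probe-level foreground/background intensities for a set of arrays,
#' with the array-to-sample map. Replicate probes appear as repeated
#' `probe_id` rows.
#'
#' @param probe_id character vector (may contain replicates).
#' @param foreground,background numeric matrices, probes x arrays,
#'   strictly positive.
#' @param targets data.frame with columns `array_id`, `patient_id`,
#'   `tissue` (`"tumor"` or `"normal"`); one row per array column.
#' @return a `raw_array_set` object.
#' @export
raw_array_set <- function(probe_id, foreground, background, targets) {
  stopifnot(nrow(foreground) == length(probe_id),
            identical(dim(foreground), dim(background)),
            all(foreground > 0), all(background > 0),
            nrow(targets) == ncol(foreground),
            all(c("array_id", "patient_id", "tissue") %in% names(targets)),
            all(targets$tissue %in% c("tumor", "normal")))
  colnames(foreground) <- targets$array_id
  colnames(background) <- targets$array_id
  structure(list(probe_id = as.character(probe_id),
                 foreground = foreground, background = background,
                 targets = targets),
            class = "raw_array_set")
}

#' Combine tumor and normal array sets
#' @param ... `raw_array_set` objects sharing the same probe list.
#' @return a single `raw_array_set`.
#' @export
bind_array_sets <- function(...) {
  sets <- list(...)
  p0 <- sets[[1]]$probe_id
  stopifnot(all(vapply(sets, function(s) identical(s$probe_id, p0),
                       logical(1))))
  raw_array_set(p0,
                do.call(cbind, lapply(sets, `[[`, "foreground")),
                do.call(cbind, lapply(sets, `[[`, "background")),
                do.call(rbind, lapply(sets, `[[`, "targets")))
}

#' Normexp background correction
#'
#' Models the background-subtracted intensity as `X = S + B` with signal
#' `S ~ Exponential(alpha)` and noise `B ~ Normal(mu, sigma^2)`; parameters
#' are fitted per array by maximum likelihood and the corrected value is
#' the posterior mean `E[S | X = x] = mu_sx + sigma *
#' phi(mu_sx/sigma) / Phi(mu_sx/sigma)` with `mu_sx = x - mu - sigma^2 /
#' alpha`. Output is strictly positive and monotone in `x`. Parameter
#' estimation is delegated to `limma::normexp.fit(method = "mle")`; the
#' conditional expectation is evaluated in closed form here.
#'
#' @param foreground,background numeric matrices, probes x arrays.
#' @return matrix of corrected intensities (same shape).
#' @export
normexp_correct <- function(foreground, background) {
  stopifnot(identical(dim(foreground), dim(background)),
            all(is.finite(foreground)), all(is.finite(background)))
  x <- foreground - background
  out <- x
  for (a in seq_len(ncol(x))) {
    par <- limma::normexp.fit(x[, a], method = "mle")$par
    out[, a] <- normexp_signal(par[1], exp(par[2]), exp(par[3]), x[, a])
  }
  out
}

#' @rdname normexp_correct
#' @param mu,sigma,alpha normexp parameters (Gaussian mean/sd, exponential
#'   mean).
#' @param x observed (background-subtracted) intensities.
#' @export
normexp_signal <- function(mu, sigma, alpha, x) {
  mu_sx <- x - mu - sigma^2 / alpha
  # log-space Mills ratio for numerical stability far below the mean
  log_phi <- stats::dnorm(mu_sx / sigma, log = TRUE)
  log_Phi <- stats::pnorm(mu_sx / sigma, log.p = TRUE)
  val <- mu_sx + sigma * exp(log_phi - log_Phi)
  pmax(val, 1e-10)
}

#' Quantile normalization between arrays
#'
#' Each array's sorted values are replaced by the across-array mean of the
#' order statistics; ties receive the mean of the values they would have
#' been given. Delegates to `limma::normalizeQuantiles(ties = TRUE)`.
#'
#' @param m numeric matrix, probes x arrays, no missing values.
#' @return normalized matrix.
#' @export
quantile_normalize <- function(m) {
  stopifnot(!anyNA(m))
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Average replicate probes
#'
#' Arithmetic mean per `probe_id` per array (log2 scale); output probe
#' order is first occurrence. Delegates to `limma::avereps`.
#'
#' @param m numeric matrix, probes x arrays.
#' @param probe_id character vector of probe ids (with replicates).
#' @return matrix with one row per unique probe.
#' @export
average_replicates <- function(m, probe_id) {
  stopifnot(nrow(m) == length(probe_id))
  out <- limma::avereps(m, ID = probe_id)
  out[unique(probe_id), , drop = FALSE]
}

#' Paired moderated t-statistics
#'
#' Per probe, the paired differences `d = tumor - normal` give a mean
#' log2 fold-change and a sample variance `s^2` on `n - 1` degrees of
#' freedom. Variances are shrunk towards a common value with the
#' empirical-Bayes estimator `(d0, s0^2)` obtained by moment matching of
#' the scaled-F distribution of the `s^2` (via `limma::fitFDist`):
#' `s~^2 = (d0 s0^2 + (n-1) s^2) / (d0 + n - 1)`, and the moderated
#' statistic `t~ = mean(d) / (s~ / sqrt(n))` is referred to a t
#' distribution on `n - 1 + d0` degrees of freedom.
#'
#' @param tumor,normal numeric matrices, probes x patients, aligned
#'   columns (same patients) and rows; `n >= 3` patients.
#' @param prior_df `"estimate"` (default), or a forced prior df: `0`
#'   recovers the ordinary paired t, `Inf` fully shrinks every variance to
#'   `s0^2`.
#' @return data.frame: `probe_id`, `log2FC`, `t`, `p`, plus attributes
#'   `prior_df` and `prior_var`.
#' @export
paired_moderated_t <- function(tumor, normal, prior_df = "estimate") {
  stopifnot(identical(dim(tumor), dim(normal)))
  n <- ncol(tumor)
  if (n < 3) stop("need at least 3 patients")
  d <- tumor - normal
  mean_d <- rowMeans(d)
  s2 <- apply(d, 1, stats::var)
  if (all(s2 == 0)) stop("zero variance in every probe")
  df <- n - 1
  if (identical(prior_df, "estimate") || is.numeric(prior_df)) {
    fd <- limma::fitFDist(pmax(s2, 1e-12), df1 = df)
    d0 <- if (identical(prior_df, "estimate")) fd$df2 else as.numeric(prior_df)
    s02 <- fd$scale
  } else stop("prior_df must be \"estimate\" or numeric")
  df_pooled <- nrow(d) * df  # cap: no more information than all probes pooled
  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
    df_total <- df_pooled
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- df
  } else {
    s2_post <- (d0 * s02 + df * s2) / (d0 + df)
    df_total <- min(df + d0, df_pooled)
  }
  tmod <- mean_d / sqrt(s2_post / n)
  p <- 2 * stats::pt(-abs(tmod), df = df_total)
  res <- data.frame(probe_id = rownames(tumor) %||%
                      sprintf("probe_%05d", seq_len(nrow(tumor))),
                    log2FC = mean_d, t = tmod, p = p)
  attr(res, "prior_df") <- d0
  attr(res, "prior_var") <- s02
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`stats::p.adjust(method = "BH")`): sort
#' ascending, multiply by `m/i`, enforce monotonicity by a cumulative
#' minimum from the largest, cap at 1, restore input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed probes
#'
#' Retains probes with `p_BH < alpha` and `|log2FC| > log2(fc)` (strict
#' inequalities).
#'
#' @param de data.frame with columns `probe_id`, `log2FC`, `p_BH`.
#' @param alpha FDR level, default 0.01.
#' @param fc fold-change threshold (linear scale), default 2.
#' @return character vector of retained probe ids.
#' @export
select_de_probes <- function(de, alpha = 0.01, fc = 2) {
  de$probe_id[de$p_BH < alpha & abs(de$log2FC) > log2(fc)]
}

#' Full paired differential-expression pipeline
#'
#' Fixed stage order: normexp background correction, log2, quantile
#' between-array normalization, replicate-probe averaging, paired
#' moderated t, BH adjustment, FC/FDR selection.
#'
#' @param raw a `raw_array_set` containing one tumor and one normal array
#'   per patient.
#' @param alpha,fc selection thresholds (defaults 0.01 and 2).
#' @param prior_df passed to [paired_moderated_t()].
#' @return list of class `de_result`: `table` (per unique probe:
#'   `probe_id`, `log2FC`, `t`, `p`, `p_BH`, `retained`), `retained`
#'   (probe ids), `log_ratios` (retained probes x patients paired log2
#'   tumor/normal differences), `expr_tumor`, `expr_normal` (normalized
#'   unique-probe matrices), and `counts`.
#' @export
run_diffexpr <- function(raw, alpha = 0.01, fc = 2, prior_df = "estimate") {
  stopifnot(inherits(raw, "raw_array_set"))
  tg <- raw$targets
  pats <- sort(unique(tg$patient_id))
  for (p in pats) {
    if (sum(tg$patient_id == p & tg$tissue == "tumor") != 1 ||
        sum(tg$patient_id == p & tg$tissue == "normal") != 1) {
      stop("each patient needs exactly one tumor and one normal array")
    }
  }
  corrected <- normexp_correct(raw$foreground, raw$background)
  logged <- log2(corrected)
  normed <- quantile_normalize(logged)
  avg <- average_replicates(normed, raw$probe_id)
  tum_ids <- vapply(pats, function(p) tg$array_id[tg$patient_id == p & tg$tissue == "tumor"], character(1))
  nor_ids <- vapply(pats, function(p) tg$array_id[tg$patient_id == p & tg$tissue == "normal"], character(1))
  tu <- avg[, tum_ids, drop = FALSE]
  no <- avg[, nor_ids, drop = FALSE]
  colnames(tu) <- pats; colnames(no) <- pats
  mt <- paired_moderated_t(tu, no, prior_df)
  tab <- data.frame(probe_id = rownames(avg), log2FC = mt$log2FC,
                    t = mt$t, p = mt$p, p_BH = bh_adjust(mt$p))
  tab$retained <- tab$p_BH < alpha & abs(tab$log2FC) > log2(fc)
  retained <- tab$probe_id[tab$retained]
  lr <- (tu - no)[retained, , drop = FALSE]
  structure(list(table = tab, retained = retained, log_ratios = lr,
                 expr_tumor = tu, expr_normal = no,
                 counts = c(n_probes_raw = length(raw$probe_id),
                            n_probes_unique = nrow(avg),
                            n_retained = length(retained)),
                 alpha = alpha, fc = fc),
            class = "de_result")
}

#' Centered paired log-ratios for the module-network learner
#'
#' Per-probe-centered paired log2 tumor/normal differences of the
#' retained probes — the expression representation handed to
#' [fit_module_network()].
#'
#' @param de a `de_result` from [run_diffexpr()].
#' @return numeric matrix, retained probes x patients, rows centered.
#' @export
module_expression <- function(de) {
  stopifnot(inherits(de, "de_result"))
  lr <- de$log_ratios
  sweep(lr, 1, rowMeans(lr))
}
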