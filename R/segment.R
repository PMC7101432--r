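#' Fixed-fraction SUV thresholding
#'
#' Segments the metabolically active tumor volume as the 26-connected
#' component, containing the box's maximum-SUV voxel, of all box voxels with
#' SUV at or above `fraction * SUVmax(box)` (default 41% of SUVmax). Ties for
#' the maximum are broken at the lowest linear (row-major) index.
#'
#' @param volume a [pet_volume()] in SUV units.
#' @param box a [voxel_box()] search region; default is the whole grid.
#' @param fraction threshold fraction of the box SUV maximum, in (0, 1].
#' @return a [tumor_mask()]; if all box voxels are equal the mask is the whole
#'   box, flagged degenerate, with a warning.
#' @export
segment_fixed_fraction <- function(volume, box = NULL, fraction = 0.41) {
  stopifnot(inherits(volume, "pet_volume"))
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  d <- dim(volume$values)
  box <- box %||% full_box(d)
  bm <- box_mask(box, d)
  vals <- volume$values
  inbox <- which(bm)
  vmax <- max(vals[inbox])
  if (min(vals[inbox]) == vmax) {
    warning("all box voxels equal; returning whole box (degenerate)")
    return(tumor_mask(bm, volume$spacing, "fixed_fraction",
                      volume$patient_id, degenerate = TRUE))
  }
  thr <- fraction * vmax
  above <- bm & (vals >= thr)
  argmax <- inbox[which(vals[inbox] == vmax)[1]]  # lowest linear index tie-break
  labels <- label_components(above, 26L)
  keep <- labels == labels[argmax]
  tumor_mask(keep, volume$spacing, "fixed_fraction", volume$patient_id)
}

## 1-D Gaussian mixture EM. Means initialize at evenly spaced positions of
## the data range (deterministic; quantile init collapses when one mode
## dominates). Class variances are floored at 1e-3 * sd(x) so hard class
## plateaus (noiseless data) do not collapse; an empty or non-finite class
## still counts as degenerate and triggers the caller's jittered restart.
fit_gmm_1d <- function(x, k, max_iter = 200, tol = 1e-8, jitter = 0,
                       seed = NULL) {
  n <- length(x)
  sx <- stats::sd(x)
  if (!isTRUE(sx > 0)) return(NULL)
  floor_sd <- 1e-3 * sx
  mu <- min(x) + (seq_len(k) - 0.5) / k * (max(x) - min(x))
  if (jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    mu <- mu + stats::rnorm(k, 0, jitter)
  }
  sigma <- rep(sx / k + 1e-8, k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sigma[j]),
                   numeric(n))
    tot <- rowSums(dens)
    if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
    r <- dens / tot
    nk <- colSums(r)
    if (any(nk < 1e-8)) return(NULL)  # degenerate: empty class
    mu <- colSums(r * x) / nk
    sigma <- pmax(sqrt(colSums(r * (x - rep(mu, each = n))^2) / nk),
                  floor_sd)
    w <- nk / n
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(mu = mu[ord], sigma = sigma[ord], w = w[ord],
       resp = r[, ord, drop = FALSE])
}

#' Fuzzy adaptive segmentation (Gaussian-mixture stand-in)
#'
#' Delineates the tumor with a fuzzy Gaussian-mixture model fitted by EM to
#' the SUVs inside the search box: voxels whose membership in the
#' highest-mean class (union of the two highest for `n_classes = 3`) exceeds
#' 0.5 are kept, and the largest 26-connected component is returned. This is
#' a documented stand-in for locally adaptive Bayesian delineation
#' algorithms; provenance is tagged `"fuzzy_adaptive"`.
#'
#' Initialization is deterministic (class means at quantiles); if EM
#' degenerates (a class collapses to zero variance) it is restarted with
#' seeded jitter, at most 5 times, before erroring.
#'
#' @param volume a [pet_volume()] in SUV units.
#' @param box a [voxel_box()] with at least 50 voxels; default whole grid.
#' @param n_classes 2 or 3 mixture classes.
#' @param seed integer seed for restart jitter.
#' @return a [tumor_mask()].
#' @export
segment_fuzzy_adaptive <- function(volume, box = NULL, n_classes = 2L,
                                   seed = 1L) {
  stopifnot(inherits(volume, "pet_volume"), n_classes %in% c(2L, 3L))
  d <- dim(volume$values)
  box <- box %||% full_box(d)
  bm <- box_mask(box, d)
  inbox <- which(bm)
  if (length(inbox) < 50) stop("search box must contain at least 50 voxels")
  x <- volume$values[inbox]
  fit <- fit_gmm_1d(x, n_classes)
  restart <- 0L
  while (is.null(fit) && restart < 5L) {
    restart <- restart + 1L
    fit <- fit_gmm_1d(x, n_classes, jitter = stats::sd(x) / 4,
                      seed = seed + restart)
  }
  if (is.null(fit)) stop("EM degenerate after 5 jittered restarts")
  hot <- if (n_classes == 2L) 2L else 2:3
  membership <- rowSums(fit$resp[, hot, drop = FALSE])
  sel <- array(FALSE, d)
  sel[inbox[membership > 0.5]] <- TRUE
  if (!any(sel)) stop("no voxel exceeds 0.5 membership in the hot class")
  labels <- label_components(sel, 26L)
  sizes <- tabulate(labels[labels > 0])
  keep <- labels == which.max(sizes)
  tumor_mask(keep, volume$spacing, "fuzzy_adaptive", volume$patient_id)
}

#' Compare paired MATVs from two segmentation methods
#'
#' Volumes are converted to cm^3 (voxel count x voxel volume / 1000) and
#' compared with a two-sided Wilcoxon signed-rank test on the paired per-
#' patient volumes (exact distribution for n <= 15 when there are no ties or
#' zero differences).
#'
#' @param masks_a,masks_b equal-length lists of [tumor_mask()], paired by
#'   position (patient ids must agree where present).
#' @return list with `mean_cm3_a`, `mean_cm3_b`, `p_value`, and the paired
#'   per-patient volumes.
#' @export
compare_matv <- function(masks_a, masks_b) {
  if (length(masks_a) != length(masks_b)) stop("mask lists differ in length")
  if (length(masks_a) < 5) stop("need at least 5 pairs")
  ids_a <- vapply(masks_a, function(m) m$patient_id, character(1))
  ids_b <- vapply(masks_b, function(m) m$patient_id, character(1))
  if (!all(is.na(ids_a)) && !identical(ids_a, ids_b)) {
    stop("patient_id pairing mismatch between mask lists")
  }
  va <- vapply(masks_a, mask_volume_ml, numeric(1))
  vb <- vapply(masks_b, mask_volume_ml, numeric(1))
  p <- if (all(va == vb)) 1.0 else {
    exact <- length(va) <= 15 && !any(va == vb) &&
      !anyDuplicated(abs(va - vb))
    suppressWarnings(
      stats::wilcox.test(va, vb, paired = TRUE, exact = exact)$p.value)
  }
  list(mean_cm3_a = mean(va), mean_cm3_b = mean(vb), p_value = p,
       volumes_a = va, volumes_b = vb)
}
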