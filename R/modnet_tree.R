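#' Regulator tree
#'
#' A depth-at-most-2 threshold tree over normalized (0-1) radiomic
#' features. The root split sends patients with feature value `<
#' threshold` to the left child and `>= threshold` to the right child;
#' each child may carry one further split, giving at most 4 leaves (and at
#' most 3 regulator features). A tree with `root = NULL` is the trivial
#' (single-leaf) tree.
#'
#' @param root `NULL` or `list(feature =, threshold =)`.
#' @param left,right `NULL` (leaf) or `list(feature =, threshold =)`;
#'   ignored when `root` is `NULL`.
#' @return a `regulator_tree` object.
#' @export
regulator_tree <- function(root = NULL, left = NULL, right = NULL) {
  chk <- function(s) {
    if (is.null(s)) return(NULL)
    stopifnot(is.character(s$feature), is.numeric(s$threshold),
              s$threshold >= 0, s$threshold <= 1)
    list(feature = s$feature, threshold = as.numeric(s$threshold))
  }
  if (is.null(root)) {
    left <- NULL; right <- NULL
  }
  structure(list(root = chk(root), left = chk(left), right = chk(right)),
            class = "regulator_tree")
}

#' @export
print.regulator_tree <- function(x, ...) {
  cat(format_tree(x), "\n")
  invisible(x)
}

tree_depth <- function(tree) {
  if (is.null(tree$root)) return(0L)
  if (is.null(tree$left) && is.null(tree$right)) return(1L)
  2L
}

tree_features <- function(tree) {
  unique(unlist(lapply(list(tree$root, tree$left, tree$right),
                       function(s) s$feature)))
}

#' Leaf patient groups of a regulator tree
#'
#' Applies the tree's threshold splits to the regulator matrix and returns
#' the leaf patient index sets, ordered left-to-right (for a split child:
#' `< threshold` first). The leaves partition the cohort.
#'
#' @param tree a [regulator_tree()].
#' @param regulators data.frame, patients x normalized features.
#' @return list of integer vectors of patient indices.
#' @export
tree_leaves <- function(tree, regulators) {
  n <- nrow(regulators)
  if (is.null(tree$root)) return(list(seq_len(n)))
  v <- regulators[[tree$root$feature]]
  lt <- which(v < tree$root$threshold)
  ge <- which(v >= tree$root$threshold)
  expand <- function(side, split) {
    if (is.null(split)) return(list(side))
    sv <- regulators[[split$feature]][side]
    list(side[sv < split$threshold], side[sv >= split$threshold])
  }
  c(expand(lt, tree$left), expand(ge, tree$right))
}

## Per-patient sufficient statistics of a module's expression block.
module_patient_stats <- function(E) {
  list(n = nrow(E), s1 = colSums(E), s2 = colSums(E^2))
}

stats_over <- function(ps, patients) {
  c(n = ps$n * length(patients),
    s1 = sum(ps$s1[patients]), s2 = sum(ps$s2[patients]))
}

#' Bayesian score of a regulator tree for a module
#'
#' Sum over the tree's leaves of the leaf log marginal likelihood of all
#' (probe, patient-in-leaf) expression values pooled. Errors if the leaves
#' do not partition the cohort.
#'
#' @param E numeric matrix, module probes x patients.
#' @param tree a [regulator_tree()].
#' @param regulators data.frame, patients x normalized features.
#' @param prior a [score_prior()].
#' @return scalar score (log marginal likelihood).
#' @export
tree_score <- function(E, tree, regulators, prior = score_prior()) {
  E <- rbind(E)
  stopifnot(ncol(E) == nrow(regulators))
  leaves <- tree_leaves(tree, regulators)
  got <- sort(unlist(leaves))
  if (!identical(got, seq_len(nrow(regulators)))) {
    stop("tree leaves do not partition the cohort")
  }
  ps <- module_patient_stats(E)
  sum(vapply(leaves, function(l) {
    s <- stats_over(ps, l)
    leaf_log_marginal_ss(s["n"], s["s1"], s["s2"], prior)
  }, numeric(1)))
}

## Best single split of `patients` (indices) for one module:
## tries every feature x midpoint-of-consecutive-distinct-values
## threshold, honoring min_leaf on both sides. Vectorized over thresholds.
## Returns NULL when no split strictly improves `base_score`.
best_split <- function(ps, regulators, patients, min_leaf, prior,
                       base_score) {
  best <- NULL
  npat <- length(patients)
  if (npat < 2 * min_leaf) return(NULL)
  for (f in names(regulators)) {
    v <- regulators[[f]][patients]
    o <- order(v)
    vo <- v[o]
    po <- patients[o]
    cum_s1 <- cumsum(ps$s1[po])
    cum_s2 <- cumsum(ps$s2[po])
    tot_s1 <- cum_s1[npat]; tot_s2 <- cum_s2[npat]
    # candidate cut after position k (left = first k patients) where the
    # sorted value changes, and both sides have >= min_leaf patients
    ks <- which(diff(vo) > 0)
    ks <- ks[ks >= min_leaf & (npat - ks) >= min_leaf]
    if (length(ks) == 0) next
    sc <- leaf_log_marginal_ss(ps$n * ks, cum_s1[ks], cum_s2[ks], prior) +
      leaf_log_marginal_ss(ps$n * (npat - ks), tot_s1 - cum_s1[ks],
                           tot_s2 - cum_s2[ks], prior)
    k <- ks[which.max(sc)]
    if (max(sc) > base_score + 1e-9 &&
        (is.null(best) || max(sc) > best$score + 1e-12)) {
      best <- list(feature = f, threshold = (vo[k] + vo[k + 1]) / 2,
                   score = max(sc),
                   left = po[seq_len(k)], right = po[(k + 1):npat])
    }
  }
  best
}

#' Learn a regulator tree for one module (greedy M-step)
#'
#' Greedy top-down search: at the root, every feature and every candidate
#' threshold (midpoints of consecutive distinct sorted values) is scored;
#' the split maximizing the Bayesian score is kept if it strictly improves
#' on the unsplit score and leaves at least `min_leaf` patients on each
#' side. Each child is then split once more under the same rule
#' (`max_depth = 2`). With no improving split the trivial tree is
#' returned.
#'
#' @param E numeric matrix, module probes x patients.
#' @param regulators data.frame, patients x normalized features.
#' @param max_depth 1 or 2 (default 2).
#' @param min_leaf minimum patients per leaf (default 4).
#' @param prior a [score_prior()].
#' @return a [regulator_tree()].
#' @export
learn_regulator_tree <- function(E, regulators, max_depth = 2L,
                                 min_leaf = 4L, prior = score_prior()) {
  E <- rbind(E)
  stopifnot(ncol(E) == nrow(regulators), max_depth %in% 1:2,
            nrow(regulators) >= 2 * min_leaf)
  ps <- module_patient_stats(E)
  allp <- seq_len(nrow(regulators))
  s_all <- stats_over(ps, allp)
  base <- leaf_log_marginal_ss(s_all["n"], s_all["s1"], s_all["s2"], prior)
  rt <- best_split(ps, regulators, allp, min_leaf, prior, base)
  if (is.null(rt)) return(regulator_tree())
  child_split <- function(side) {
    if (max_depth < 2L) return(NULL)
    s <- stats_over(ps, side)
    b <- leaf_log_marginal_ss(s["n"], s["s1"], s["s2"], prior)
    sp <- best_split(ps, regulators, side, min_leaf, prior, b)
    if (is.null(sp)) NULL else list(feature = sp$feature,
                                    threshold = sp$threshold)
  }
  regulator_tree(root = list(feature = rt$feature, threshold = rt$threshold),
                 left = child_split(rt$left),
                 right = child_split(rt$right))
}

#' Express tree thresholds as cohort-range percentages
#'
#' Thresholds learned on 0-1 normalized features are displayed as
#' percentages of the cohort range (one decimal); when the original
#' per-feature ranges are supplied (attributes of
#' [normalize_cohort_features()] output), the raw-unit equivalent
#' `min + t * (max - min)` is reported too. A cut at x% of the range does
#' not imply the resulting group holds x% of the patients.
#'
#' @param tree a [regulator_tree()].
#' @param feature_min,feature_max named per-feature original minima and
#'   maxima; optional.
#' @return list with per-split `feature`, `threshold` (normalized),
#'   `percent` (display string value, numeric, one decimal) and `raw`
#'   (original units, `NA` when ranges are not supplied).
#' @export
thresholds_to_percent <- function(tree, feature_min = NULL,
                                  feature_max = NULL) {
  one <- function(s) {
    if (is.null(s)) return(NULL)
    raw <- if (!is.null(feature_min) && s$feature %in% names(feature_min)) {
      feature_min[[s$feature]] +
        s$threshold * (feature_max[[s$feature]] - feature_min[[s$feature]])
    } else NA_real_
    list(feature = s$feature, threshold = s$threshold,
         percent = round(100 * s$threshold, 1), raw = raw)
  }
  list(root = one(tree$root), left = one(tree$left), right = one(tree$right))
}

#' Render / parse a tree in module-table form
#'
#' `format_tree` renders a regulator tree the way module tables print
#' them: up to three "feature percent%" regulator columns (regulator 2
#' applies to the `< threshold` group of regulator 1, regulator 3 to the
#' `>= threshold` group) and a group-size string such as `"[15|24][06]"`
#' (split children bracketed as `[a|b]`, unsplit children as `[c]`).
#' `parse_tree` inverts the rendering back to a [regulator_tree()].
#'
#' @param tree a [regulator_tree()].
#' @param regulators optional regulator matrix; needed for group sizes.
#' @return `format_tree`: a list with `regulator1`, `regulator2`,
#'   `regulator3` (strings, `"-"` when absent) and `groups`;
#'   `parse_tree`: a [regulator_tree()].
#' @export
format_tree <- function(tree, regulators = NULL) {
  fmt <- function(s) {
    if (is.null(s)) "-" else sprintf("%s %.1f%%", s$feature,
                                     100 * s$threshold)
  }
  groups <- ""
  if (!is.null(regulators) && !is.null(tree$root)) {
    v <- regulators[[tree$root$feature]]
    sides <- list(which(v < tree$root$threshold),
                  which(v >= tree$root$threshold))
    part <- vapply(seq_len(2), function(i) {
      s <- if (i == 1) tree$left else tree$right
      side <- sides[[i]]
      if (is.null(s)) {
        sprintf("[%02d]", length(side))
      } else {
        sv <- regulators[[s$feature]][side]
        sprintf("[%02d|%02d]", sum(sv < s$threshold),
                sum(sv >= s$threshold))
      }
    }, character(1))
    groups <- paste0(part, collapse = "")
  }
  list(regulator1 = fmt(tree$root), regulator2 = fmt(tree$left),
       regulator3 = fmt(tree$right), groups = groups)
}

#' @rdname format_tree
#' @param row a list as returned by `format_tree`.
#' @export
parse_tree <- function(row) {
  one <- function(s) {
    if (is.null(s) || identical(s, "-")) return(NULL)
    m <- regmatches(s, regexec("^(.*) ([0-9]+(?:\\.[0-9]+)?)%$", s))[[1]]
    if (length(m) != 3) stop("cannot parse regulator string: ", s)
    list(feature = m[2], threshold = as.numeric(m[3]) / 100)
  }
  regulator_tree(root = one(row$regulator1), left = one(row$regulator2),
                 right = one(row$regulator3))
}
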