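#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## The 26-neighbourhood offsets, and the 13 unique (lexicographically
## positive) displacement directions used for merged co-occurrence.
neighbor_offsets_26 <- function() {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

unique_directions_13 <- function() {
  g <- neighbor_offsets_26()
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  g[keep, , drop = FALSE]
}

## Separable Gaussian filter in voxel units (sigma per axis, voxels).
## Kernel truncated at 3 sigma and renormalized (edge-renormalized too,
## via the row-normalized band matrix), so a constant field stays constant.
gaussian_smooth_3d <- function(vol, sigma_vox) {
  stopifnot(length(dim(vol)) == 3)
  sigma_vox <- rep(sigma_vox, length.out = 3)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    half <- max(1L, as.integer(ceiling(3 * s)))
    w <- stats::dnorm(-half:half, 0, s)
    w <- w / sum(w)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
    vp <- aperm(vol, perm)
    dp <- dim(vp)
    n <- dp[1]
    K <- matrix(0, n, n)
    for (o in -half:half) {
      rows <- pmin(pmax(seq_len(n) + o, 1L), n)
      K[cbind(rows, seq_len(n))] <- K[cbind(rows, seq_len(n))] + w[o + half + 1]
    }
    K <- t(K)  # rows = output position; clamped tails accumulate at edges
    res <- K %*% matrix(vp, nrow = n)
    vol <- aperm(array(res, dp), order(perm))
  }
  vol
}

## Connected-component labelling of a logical 3D array (26- or 6-connectivity).
## Breadth-first with a vectorized frontier expansion; labels assigned in
## ascending order of the component's smallest linear index, so output is
## deterministic.
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  d <- dim(mask)
  stopifnot(length(d) == 3)
  offs <- if (connectivity == 26L) {
    neighbor_offsets_26()
  } else if (connectivity == 6L) {
    m <- neighbor_offsets_26()
    m[rowSums(abs(m)) == 1, , drop = FALSE]
  } else stop("connectivity must be 6 or 26")
  labels <- array(0L, d)
  inside <- which(mask != 0)
  if (length(inside) == 0) return(labels)
  nlab <- 0L
  unvisited <- array(FALSE, d)
  unvisited[inside] <- TRUE
  for (seed in inside) {
    if (!unvisited[seed]) next
    nlab <- nlab + 1L
    frontier <- seed
    unvisited[seed] <- FALSE
    labels[seed] <- nlab
    while (length(frontier) > 0) {
      fc <- arrayInd(frontier, d)
      nxt <- integer(0)
      for (o in seq_len(nrow(offs))) {
        nc <- fc + matrix(offs[o, ], nrow(fc), 3, byrow = TRUE)
        ok <- nc[, 1] >= 1 & nc[, 1] <= d[1] &
          nc[, 2] >= 1 & nc[, 2] <= d[2] &
          nc[, 3] >= 1 & nc[, 3] <= d[3]
        if (!any(ok)) next
        lin <- nc[ok, 1] + (nc[ok, 2] - 1L) * d[1] + (nc[ok, 3] - 1L) * d[1] * d[2]
        lin <- lin[unvisited[lin]]
        if (length(lin)) {
          unvisited[lin] <- FALSE
          labels[lin] <- nlab
          nxt <- c(nxt, lin)
        }
      }
      frontier <- unique(nxt)
    }
  }
  labels
}

## Euclidean distance (mm) from every in-mask voxel to the nearest background
## voxel. The nearest background voxel to any tumor voxel is necessarily
## adjacent to the mask, so only the background shell needs to be scanned.
distance_to_background <- function(mask, spacing) {
  d <- dim(mask)
  inside <- which(mask != 0)
  stopifnot(length(inside) > 0)
  # background shell: background voxels 26-adjacent to the mask
  offs <- neighbor_offsets_26()
  mc <- arrayInd(inside, d)
  shell_idx <- integer(0)
  for (o in seq_len(nrow(offs))) {
    nc <- mc + matrix(offs[o, ], nrow(mc), 3, byrow = TRUE)
    ok <- nc[, 1] >= 1 & nc[, 1] <= d[1] &
      nc[, 2] >= 1 & nc[, 2] <= d[2] &
      nc[, 3] >= 1 & nc[, 3] <= d[3]
    lin <- nc[ok, 1] + (nc[ok, 2] - 1L) * d[1] + (nc[ok, 3] - 1L) * d[1] * d[2]
    shell_idx <- c(shell_idx, lin[mask[lin] == 0])
  }
  shell_idx <- unique(shell_idx)
  if (length(shell_idx) == 0) stop("mask has no background boundary (mask fills grid)")
  sc <- arrayInd(shell_idx, d)
  mpos <- sweep(mc, 2, spacing, `*`)
  spos <- sweep(sc, 2, spacing, `*`)
  # min distance per mask voxel, blockwise to bound memory
  nmask <- nrow(mpos)
  out <- numeric(nmask)
  block <- max(1L, as.integer(2e6 / nrow(spos)))
  for (start in seq(1L, nmask, by = block)) {
    idx <- start:min(nmask, start + block - 1L)
    d2 <- outer(mpos[idx, 1], spos[, 1], `-`)^2 +
      outer(mpos[idx, 2], spos[, 2], `-`)^2 +
      outer(mpos[idx, 3], spos[, 3], `-`)^2
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  list(index = inside, distance = out)
}

## Half-open 0-based voxel box, the coordinate convention used throughout.
#' Construct a search box
#'
#' Boxes are half-open and 0-based: voxel index `i` (0-based) along an axis is
#' inside when `lo[axis] <= i < hi[axis]`.
#'
#' @param lo,hi integer vectors of length 3 (0-based, half-open).
#' @return a `voxel_box` object.
#' @export
voxel_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(length(lo) == 3, length(hi) == 3, all(hi > lo), all(lo >= 0))
  structure(list(lo = lo, hi = hi), class = "voxel_box")
}

full_box <- function(dim3) voxel_box(c(0, 0, 0), dim3)

box_ranges <- function(box, dim3) {
  stopifnot(all(box$hi <= dim3))
  lapply(1:3, function(a) (box$lo[a] + 1L):box$hi[a])
}

box_mask <- function(box, dim3) {
  m <- array(FALSE, dim3)
  r <- box_ranges(box, dim3)
  m[r[[1]], r[[2]], r[[3]]] <- TRUE
  m
}
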