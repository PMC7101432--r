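# Independent brute-force / quadrature oracles. These deliberately share no
# code with the package implementations they check.

dice_coef <- function(a, b) {
  2 * sum(a$mask & b$mask) / (sum(a$mask) + sum(b$mask))
}

# All 26 neighbor offsets; the 13 lexicographically positive ones.
.oracle_dirs13 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  g[g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
      (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0), , drop = FALSE]
})

# O(N * 26) voxel-pair enumeration of the merged symmetric GLCM.
oracle_cooc <- function(bins, mask, nb) {
  d <- dim(bins)
  co <- matrix(0, nb, nb)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    for (o in seq_len(nrow(.oracle_dirs13))) {
      ii <- i + .oracle_dirs13[o, 1]
      jj <- j + .oracle_dirs13[o, 2]
      kk <- k + .oracle_dirs13[o, 3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
          kk < 1 || kk > d[3]) next
      if (!mask[ii, jj, kk]) next
      b1 <- bins[i, j, k]; b2 <- bins[ii, jj, kk]
      co[b1, b2] <- co[b1, b2] + 1
      co[b2, b1] <- co[b2, b1] + 1
    }
  }
  if (sum(co) == 0) co else co / sum(co)
}

# Stack-based flood fill over equal-bin 26-connected zones.
oracle_szm <- function(bins, mask, nb) {
  d <- dim(bins)
  visited <- array(FALSE, d)
  zone_bin <- integer(0); zone_size <- integer(0)
  for (lin in which(mask)) {
    if (visited[lin]) next
    b <- bins[lin]
    stack <- lin
    visited[lin] <- TRUE
    size <- 0L
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      cc <- arrayInd(cur, d)
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        ii <- cc[1] + di; jj <- cc[2] + dj; kk <- cc[3] + dk
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
            kk < 1 || kk > d[3]) next
        if (!mask[ii, jj, kk] || visited[ii, jj, kk] ||
            bins[ii, jj, kk] != b) next
        visited[ii, jj, kk] <- TRUE
        stack <- c(stack, ii + (jj - 1L) * d[1] + (kk - 1L) * d[1] * d[2])
      }
    }
    zone_bin <- c(zone_bin, b); zone_size <- c(zone_size, size)
  }
  counts <- matrix(0, nb, max(zone_size))
  for (r in seq_along(zone_bin)) {
    counts[zone_bin[r], zone_size[r]] <- counts[zone_bin[r], zone_size[r]] + 1
  }
  counts
}

# Threshold + flood fill segmentation oracle (6/26-connectivity BFS kept
# independent of the package's labelling code).
oracle_fixed_fraction <- function(vals, fraction) {
  d <- dim(vals)
  thr <- fraction * max(vals)
  above <- vals >= thr
  seed <- which(vals == max(vals))[1]
  keep <- array(FALSE, d)
  stack <- seed
  keep[seed] <- TRUE
  while (length(stack)) {
    cur <- stack[length(stack)]; stack <- stack[-length(stack)]
    cc <- arrayInd(cur, d)
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- cc[1] + di; jj <- cc[2] + dj; kk <- cc[3] + dk
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
          kk < 1 || kk > d[3]) next
      if (!above[ii, jj, kk] || keep[ii, jj, kk]) next
      keep[ii, jj, kk] <- TRUE
      stack <- c(stack, ii + (jj - 1L) * d[1] + (kk - 1L) * d[1] * d[2])
    }
  }
  keep
}

# 2-D quadrature of the normal-gamma marginal likelihood.
oracle_ng_marginal_log <- function(x, mu0 = 0, lambda0 = 1, alpha0 = 1,
                                   beta0 = 0.1) {
  inner <- function(tau) {
    vapply(tau, function(tt) {
      f <- function(mu) {
        exp(colSums(matrix(stats::dnorm(rep(x, length(mu)),
                                        rep(mu, each = length(x)),
                                        1 / sqrt(tt), log = TRUE),
                           nrow = length(x))) +
              stats::dnorm(mu, mu0, 1 / sqrt(lambda0 * tt), log = TRUE))
      }
      ctr <- (lambda0 * mu0 + sum(x)) / (lambda0 + length(x))
      wid <- 20 / sqrt((lambda0 + length(x)) * tt)
      stats::integrate(f, ctr - wid, ctr + wid, rel.tol = 1e-13,
                       abs.tol = 0)$value *
        stats::dgamma(tt, alpha0, rate = beta0)
    }, numeric(1))
  }
  v <- stats::integrate(inner, 0, Inf, rel.tol = 1e-12, abs.tol = 0,
                        subdivisions = 500L)$value
  log(v)
}

# Chain-rule oracle: product of one-point Student-t posterior predictives.
oracle_ng_chain_log <- function(x, mu0 = 0, lambda0 = 1, alpha0 = 1,
                                beta0 = 0.1) {
  mu <- mu0; lam <- lambda0; a <- alpha0; b <- beta0
  total <- 0
  for (xi in x) {
    scale <- sqrt(b * (lam + 1) / (a * lam))
    total <- total + stats::dt((xi - mu) / scale, df = 2 * a, log = TRUE) -
      log(scale)
    b <- b + lam * (xi - mu)^2 / (2 * (lam + 1))
    mu <- (lam * mu + xi) / (lam + 1)
    lam <- lam + 1
    a <- a + 0.5
  }
  total
}

# Quadrature oracle for the normexp conditional mean E[S | X = x].
# Integrands are shifted by their log maximum so the tails (x far below the
# background mean) do not underflow.
oracle_normexp_signal <- function(mu, sigma, alpha, x) {
  logf <- function(s) {
    stats::dexp(s, 1 / alpha, log = TRUE) +
      stats::dnorm(x - s, mu, sigma, log = TRUE)
  }
  hi <- max(x - mu, 0) + 12 * sigma + 12 * alpha
  shift <- stats::optimize(logf, c(0, hi), maximum = TRUE)$objective
  f0 <- function(s) exp(logf(s) - shift)
  f1 <- function(s) s * exp(logf(s) - shift)
  stats::integrate(f1, 0, hi, rel.tol = 1e-12)$value /
    stats::integrate(f0, 0, hi, rel.tol = 1e-12)$value
}

# Exhaustive-definition BH oracle: q_(i) = min_{j >= i} m p_(j) / j, capped.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    cands <- vapply(rank_i:m, function(j) m * p[o[j]] / j, numeric(1))
    q[i] <- min(1, cands)
  }
  q
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws.
oracle_hyper <- function(N, K, n, ov) {
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(s) sum(s <= K) >= ov)
  mean(hits)
}

# Rotate a 3-D array 90 degrees about the given axis.
rot90_3d <- function(a, axis = 3) {
  if (axis == 3) {
    b <- aperm(a, c(2, 1, 3)); b[dim(b)[1]:1, , , drop = FALSE]
  } else if (axis == 1) {
    b <- aperm(a, c(1, 3, 2)); b[, dim(b)[2]:1, , drop = FALSE]
  } else {
    b <- aperm(a, c(3, 2, 1)); b[, , dim(b)[3]:1, drop = FALSE]
  }
}
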