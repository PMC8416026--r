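# Independent brute-force oracles used to validate the package's
# implementations on small instances. These deliberately use the most
# direct formulation of each computation.

# tally pairs into a dense symmetric matrix by explicit iteration
oracle_dense_from_pairs <- function(chrom, pos1, pos2, len, bw) {
  n <- ceiling(len / bw)
  m <- matrix(0, n, n)
  for (i in seq_along(pos1)) {
    b1 <- floor((pos1[i] - 1) / bw) + 1
    b2 <- floor((pos2[i] - 1) / bw) + 1
    m[b1, b2] <- m[b1, b2] + 1
    if (b1 != b2) m[b2, b1] <- m[b2, b1] + 1
  }
  m
}

# P(s) by explicit enumeration of every matrix element pair
oracle_ps <- function(dense, bw, edges, n_masked = 1) {
  n <- nrow(dense)
  nb <- length(edges) - 1
  O <- numeric(nb)
  N <- numeric(nb)
  for (i in 1:n) {
    for (j in 1:n) {
      if (j <= i) next
      d <- j - i
      if (d < n_masked) next
      s <- d * bw
      for (k in 1:nb) {
        if (s >= edges[k] && s < edges[k + 1]) {
          O[k] <- O[k] + dense[i, j]
          N[k] <- N[k] + 1
          break
        }
      }
    }
  }
  list(O = O, N = N, p = ifelse(N > 0, O / N / max(sum(O), 1), NA))
}

# Otsu by exhaustive between-class variance maximization over histogram cuts
oracle_otsu <- function(x, n_bins = 256) {
  v <- as.numeric(x)
  edges <- seq(min(v), max(v), length.out = n_bins + 1)
  best <- -Inf
  best_t <- NA
  for (k in 1:(n_bins - 1)) {
    t <- edges[k + 1]
    # classify by histogram bin, as the histogram-based method does
    bin <- pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
    mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
    vals <- mids[bin]
    lo <- vals[bin <= k]
    hi <- vals[bin > k]
    if (!length(lo) || !length(hi)) next
    bcv <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (bcv > best) {
      best <- bcv
      best_t <- t
    }
  }
  best_t
}

# recursive flood fill labeling (8-connectivity in 2D, 26 in 3D)
oracle_flood_fill <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2) {
    mask <- array(mask, c(d, 1))
    d <- dim(mask)
  }
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(mask != 0)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      co <- arrayInd(v, d)
      for (dy in -1:1) {
        for (dx in -1:1) {
          for (dz in -1:1) {
            if (dy == 0 && dx == 0 && dz == 0) next
            y <- co[1] + dy
            x <- co[2] + dx
            z <- co[3] + dz
            if (y < 1 || y > d[1] || x < 1 || x > d[2] || z < 1 || z > d[3]) next
            if (mask[y, x, z] != 0 && lab[y, x, z] == 0L) {
              lab[y, x, z] <- cur
              queue <- c(queue, (z - 1) * d[1] * d[2] + (x - 1) * d[1] + y)
            }
          }
        }
      }
    }
  }
  lab[, , , drop = TRUE]
}

# Mann-Whitney U by pairwise win counting, exact p by enumerating all
# group assignments
oracle_mann_whitney <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  count_u <- function(x, y) {
    u <- 0
    for (xi in x) {
      for (yj in y) {
        if (xi > yj) u <- u + 1 else if (xi == yj) u <- u + 0.5
      }
    }
    u
  }
  ua <- count_u(a, b)
  u_obs <- min(ua, na * nb - ua)
  pooled <- c(a, b)
  idx <- utils::combn(na + nb, na)
  stats <- apply(idx, 2, function(ii) {
    uu <- count_u(pooled[ii], pooled[-ii])
    min(uu, na * nb - uu)
  })
  list(u = u_obs, p = mean(stats <= u_obs + 1e-9))
}

# label match helper: two labelings agree up to renaming
expect_same_partition <- function(lab1, lab2) {
  expect_equal(lab1 > 0, lab2 > 0)
  fg <- which(lab1 > 0)
  if (length(fg)) {
    map <- tapply(lab2[fg], lab1[fg], function(v) length(unique(v)))
    expect_true(all(map == 1))
    map2 <- tapply(lab1[fg], lab2[fg], function(v) length(unique(v)))
    expect_true(all(map2 == 1))
  }
}
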