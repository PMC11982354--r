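# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use the most literal formulation of
# each definition, not the package's code path.

# Benjamini-Hochberg step-up, computed directly from the definition:
# q_i = min over j with p_(j) >= p_(i) of m * p_(j) / rank_j, capped at 1.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(nx + ny, nx) group assignments (tie-free data assumed).
perm_wilcox_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  centre <- nx * ny / 2
  combs <- combn(nx + ny, nx)
  us <- apply(combs, 2, function(idx) {
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-9)
}

# Product-limit estimator computed as an explicit product over risk sets.
brute_km <- function(time, event) {
  ts <- sort(unique(time))
  s <- numeric(length(ts))
  cur <- 1
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    cur <- cur * (1 - d / at_risk)
    s[i] <- cur
  }
  data.frame(time = ts, surv = s)
}

# Exhaustive Otsu search: try every candidate threshold k/levels and
# compute the between-class variance directly from the pixel values.
brute_otsu <- function(x, levels = 256L) {
  x <- as.vector(x)
  best_t <- NA_real_; best_v <- -Inf
  for (k in seq_len(levels - 1)) {
    t <- k / levels
    fg <- x >= t
    w1 <- mean(fg); w0 <- 1 - w1
    if (w0 == 0 || w1 == 0) next
    v <- w0 * w1 * (mean(x[!fg]) - mean(x[fg]))^2
    if (v > best_v + 1e-15) {
      best_v <- v; best_t <- t
    }
  }
  best_t
}

# Multi-source shortest path by plain O(n^2) Dijkstra on the 8-connected
# grid, mirroring the propagation cost definition: a step of length s
# costs s * sqrt((lambda + dI^2) / (lambda + mdi2)) with mdi2 the mean
# squared axial intensity difference over in-mask neighbor pairs.
# Returns per-pixel distance and the label of the arg-min seed.
dijkstra_propagate <- function(intensity, seeds, mask, lambda) {
  nr <- nrow(intensity); nc <- ncol(intensity)
  ssq <- 0; npair <- 0
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      if (i < nr && mask[i + 1, j]) {
        ssq <- ssq + (intensity[i + 1, j] - intensity[i, j])^2
        npair <- npair + 1
      }
      if (j < nc && mask[i, j + 1]) {
        ssq <- ssq + (intensity[i, j + 1] - intensity[i, j])^2
        npair <- npair + 1
      }
    }
  }
  mdi2 <- if (npair > 0) ssq / npair else 0
  n <- nr * nc
  dist <- rep(Inf, n)
  lab <- integer(n)
  visited <- rep(FALSE, n)
  seed_idx <- which(seeds > 0 & mask)
  dist[seed_idx] <- 0
  lab[seed_idx] <- seeds[seed_idx]
  moves <- cbind(di = c(-1, 1, 0, 0, -1, -1, 1, 1),
                 dj = c(0, 0, -1, 1, -1, 1, -1, 1),
                 s = c(1, 1, 1, 1, sqrt(2), sqrt(2), sqrt(2), sqrt(2)))
  repeat {
    cand <- which(!visited & is.finite(dist))
    if (length(cand) == 0) break
    u <- cand[which.min(dist[cand])]
    visited[u] <- TRUE
    ui <- (u - 1) %% nr + 1
    uj <- (u - 1) %/% nr + 1
    for (k in seq_len(8)) {
      vi <- ui + moves[k, "di"]; vj <- uj + moves[k, "dj"]
      if (vi < 1 || vi > nr || vj < 1 || vj > nc) next
      if (!mask[vi, vj]) next
      v <- vi + (vj - 1) * nr
      if (visited[v]) next
      dI <- intensity[vi, vj] - intensity[ui, uj]
      w <- moves[k, "s"] * sqrt((lambda + dI^2) / (lambda + mdi2))
      if (dist[u] + w < dist[v]) {
        dist[v] <- dist[u] + w
        lab[v] <- lab[u]
      }
    }
  }
  list(dist = matrix(dist, nr, nc), labels = matrix(lab, nr, nc))
}

# Per-seed geodesic distance maps (one Dijkstra run per seed label).
per_seed_dists <- function(intensity, seeds, mask, lambda) {
  labs <- sort(unique(seeds[seeds > 0 & mask]))
  out <- lapply(labs, function(l) {
    s <- seeds
    s[s != l] <- 0L
    dijkstra_propagate(intensity, s, mask, lambda)$dist
  })
  names(out) <- labs
  out
}

# A propagation labeling is correct iff every labeled pixel's seed attains
# the minimum geodesic distance among all seeds (ties may go either way).
expect_valid_propagation <- function(labels, intensity, seeds, mask,
                                     lambda, tol = 1e-8) {
  dists <- per_seed_dists(intensity, seeds, mask, lambda)
  labs <- as.integer(names(dists))
  reachable <- Reduce(pmin, dists)
  idx <- which(mask & is.finite(reachable))
  expect_true(all(labels[idx] > 0))
  assigned <- vapply(idx, function(i) {
    dists[[match(labels[i], labs)]][i]
  }, numeric(1))
  expect_true(all(assigned <= reachable[idx] + tol))
  expect_true(all(labels[!mask] == 0))
}
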