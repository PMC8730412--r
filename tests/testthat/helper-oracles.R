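# Independent brute-force oracles. These deliberately share no code with
# the package: Floyd-Warshall instead of Dijkstra, explicit triangle and
# partition enumeration, direct hypergeometric / rank arrangement sums.

# all-pairs shortest paths on edge length 1/weight, Floyd-Warshall
fw_shortest_paths <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  d
}

ge_oracle <- function(w) {
  d <- fw_shortest_paths(w)
  v <- 1 / d[upper.tri(d)]
  v[!is.finite(v)] <- 0
  mean(v)
}

cpl_oracle <- function(w) {
  d <- fw_shortest_paths(w)
  v <- d[upper.tri(d)]
  mean(v[is.finite(v)])
}

# weighted transitivity by explicit enumeration of node triples
transitivity_oracle <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(0)
  ws <- w / mx
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (i != j && j != k && i != k &&
            w[i, j] > 0 && w[j, k] > 0 && w[k, i] > 0) {
          num <- num + (ws[i, j] * ws[j, k] * ws[k, i])^(1 / 3)
        }
      }
    }
  }
  deg <- rowSums(w > 0)
  den <- sum(deg * (deg - 1))
  if (den == 0) 0 else num / den
}

# Newman weighted modularity of a membership vector, by the definition
modularity_oracle <- function(w, memb) {
  two_m <- sum(w)
  k <- rowSums(w)
  same <- outer(memb, memb, `==`)
  sum((w - outer(k, k) / two_m) * same) / two_m
}

# all set partitions of n items as a list of membership vectors
set_partitions <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- set_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    for (b in seq_len(max(p) + 1L)) {
      out[[length(out) + 1L]] <- c(p, b)
    }
  }
  out
}

exhaustive_modularity <- function(w) {
  best <- -Inf
  for (p in set_partitions(nrow(w))) {
    q <- modularity_oracle(w, p)
    if (q > best) best <- q
  }
  best
}

# exact two-sided rank-sum p by enumeration of all group-A rank placements
ranksum_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  na <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(length(pooled), na)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- na * (length(pooled) + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# two-sided Fisher p for a 2x2 table by point-probability hypergeometric sum
fisher_oracle_2x2 <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random symmetric weighted graph on n nodes, weights in (0, 1]
rand_wgraph <- function(n, p_edge = 0.6, wmin = 0.05, wmax = 1) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- ut[stats::runif(length(ut)) < p_edge]
  w[on] <- stats::runif(length(on), wmin, wmax)
  w + t(w)
}

# random graph with two planted communities (for modularity checks)
rand_community_graph <- function(n, p_in = 0.9, p_out = 0.2) {
  grp <- rep(1:2, length.out = n)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      p <- if (grp[i] == grp[j]) p_in else p_out
      if (stats::runif(1) < p) w[i, j] <- stats::runif(1, 0.2, 1)
    }
  }
  w + t(w)
}
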