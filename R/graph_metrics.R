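#' Whole-brain graph metrics on FA-weighted connectomes
#'
#' Four topological parameters are computed on the weighted, undirected
#' connectome: global efficiency (integration), weighted transitivity
#' (segregation), Louvain modularity (community structure) and
#' small-worldness (clustering relative to path length, against matched
#' random networks). Shortest paths use edge length `1/weight`: a higher
#' FA weight is a stronger connection and hence a shorter distance.
#'
#' @name graph_metrics
NULL

as_weighted_graph <- function(w) {
  ut <- which(upper.tri(w) & w > 0)
  g <- igraph::make_graph(rbind(row(w)[ut], col(w)[ut]), n = nrow(w),
                          directed = FALSE)
  igraph::E(g)$weight <- w[ut]
  g
}

#' Shortest-path distance matrix
#'
#' Dijkstra shortest paths from every node with edge length `1/weight`.
#' Unreachable pairs are `Inf`; the diagonal is 0.
#'
#' @param connectome A `connectome` or symmetric weight matrix.
#' @return An n x n distance matrix.
#' @export
shortest_path_matrix <- function(connectome) {
  w <- conn_weights(connectome)
  if (all(w == 0)) {
    d <- matrix(Inf, nrow(w), ncol(w), dimnames = dimnames(w))
    diag(d) <- 0
    return(d)
  }
  g <- as_weighted_graph(w)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  dimnames(d) <- dimnames(w)
  d
}

#' Global efficiency
#'
#' Mean over all unordered node pairs of the inverse shortest-path
#' distance, with unreachable pairs contributing zero (harmonic-mean
#' convention).
#'
#' @inheritParams shortest_path_matrix
#' @return A nonnegative scalar, bounded by the maximum edge weight.
#' @export
global_efficiency <- function(connectome) {
  d <- shortest_path_matrix(connectome)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0  # guards 1/Inf = 0 already; keeps NaN out
  mean(inv)
}

#' Characteristic path length
#'
#' Mean shortest-path distance over reachable (finite) node pairs,
#' excluding the diagonal. Errors when no pair is reachable.
#'
#' @inheritParams shortest_path_matrix
#' @return A positive scalar.
#' @export
characteristic_path_length <- function(connectome) {
  d <- shortest_path_matrix(connectome)
  v <- d[upper.tri(d)]
  v <- v[is.finite(v)]
  if (length(v) == 0) {
    stop("characteristic path length undefined: no finite paths", call. = FALSE)
  }
  mean(v)
}

#' Weighted transitivity
#'
#' Network-wide weighted clustering: weights are scaled by their maximum,
#' the triangle intensity at each node is the sum over its triangles of
#' the geometric mean (cube root of the product) of the three scaled
#' weights (each triangle counted in both orientations), and the ratio of
#' the summed intensities to `sum(k * (k - 1))` over nodes is returned,
#' where `k` is the binary degree. Zero when no node has degree >= 2.
#'
#' @inheritParams shortest_path_matrix
#' @return A scalar in \[0, 1\].
#' @export
transitivity_weighted <- function(connectome) {
  w <- conn_weights(connectome)
  mx <- max(w)
  if (mx == 0) return(0)
  ws <- (w / mx)^(1 / 3)
  cyc3 <- diag(ws %*% ws %*% ws)  # counts each triangle at a node twice
  k <- rowSums(w > 0)
  denom <- sum(k * (k - 1))
  if (denom == 0) return(0)
  sum(cyc3) / denom
}

#' Newman weighted modularity of a given partition
#'
#' @inheritParams shortest_path_matrix
#' @param membership Integer community labels, one per node.
#' @return Modularity Q in \[-0.5, 1\].
#' @export
modularity_q <- function(connectome, membership) {
  w <- conn_weights(connectome)
  g <- as_weighted_graph(w)
  igraph::modularity(g, membership, weights = igraph::E(g)$weight)
}

#' Louvain modularity
#'
#' Community structure by greedy Louvain optimization of Newman weighted
#' modularity, restarted `restarts` times from randomized orders; the
#' partition with maximal Q is kept (first encountered on ties, so the
#' result is deterministic given `seed`).
#'
#' @inheritParams shortest_path_matrix
#' @param resolution Resolution parameter (default 1, plain modularity).
#' @param restarts Number of randomized restarts (default 20).
#' @param seed Integer RNG seed (default 20110101).
#' @return A list with `Q` (best modularity) and `membership` (named
#'   integer vector of community labels).
#' @export
modularity_louvain <- function(connectome, resolution = 1, restarts = 20,
                               seed = 20110101) {
  w <- conn_weights(connectome)
  if (all(w == 0)) {
    stop("modularity undefined for an edgeless graph (total weight 0)", call. = FALSE)
  }
  n <- nrow(w)
  g <- as_weighted_graph(w)
  ew <- igraph::E(g)$weight
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      # Louvain's greedy passes depend on vertex order; each restart runs
      # on a randomly relabeled copy to explore different local optima,
      # followed by single-node refinement of the resulting partition
      perm <- sample.int(n)
      gp <- igraph::permute(g, perm)
      cl <- igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight,
                                    resolution = resolution)
      memb <- refine_partition(w, as.integer(igraph::membership(cl)[perm]),
                               resolution)
      # a refined random start escapes multi-node local optima Louvain's
      # agglomeration cannot leave (it can never split a community)
      rand0 <- sample.int(max(2L, as.integer(ceiling(sqrt(n)))), n,
                          replace = TRUE)
      memb2 <- refine_partition(w, rand0, resolution)
      for (mb in list(memb, memb2)) {
        q <- igraph::modularity(g, mb, weights = ew)
        if (is.null(best) || q > best$Q + 1e-12) {
          best <- list(Q = q, membership = mb)
        }
      }
    }
  })
  names(best$membership) <- rownames(w)
  best
}

# greedy single-node refinement of a partition (Kernighan-Lin style):
# repeatedly move the node whose relocation (to any community, or to a new
# singleton) most increases modularity, until no improving move exists.
# Aggregation-based Louvain cannot split communities, so this escapes the
# local optima it leaves behind on weakly structured graphs.
refine_partition <- function(w, memb, resolution = 1) {
  m2 <- sum(w)  # 2m: every edge weight counted in both directions
  if (m2 == 0) return(memb)
  k <- rowSums(w)
  for (sweep in 1:100) {
    improved <- FALSE
    for (i in sample.int(nrow(w))) {
      ki_all <- rowsum(w[i, ], memb)          # strength of i into each community
      sig_all <- rowsum(k, memb)
      lab <- as.integer(rownames(ki_all))
      ki_c <- ki_all[, 1]
      sig_c <- sig_all[, 1]
      a <- match(memb[i], lab)
      sig_ex <- sig_c
      sig_ex[a] <- sig_ex[a] - k[i]  # community strength totals excluding i
      # Q-contribution of i in community c (up to the constant 2/m2 factor):
      # k_{i,c} - gamma * k_i * Sigma_{c \ i} / m2
      contrib <- ki_c - resolution * k[i] * sig_ex / m2
      gain <- contrib - contrib[a]       # move to an existing community
      gain_new <- 0 - contrib[a]         # move to a new singleton community
      gain[a] <- 0
      t <- which.max(gain)
      if (gain_new > gain[t] + 1e-12 && gain_new > 1e-12) {
        memb[i] <- max(memb) + 1L
        improved <- TRUE
      } else if (gain[t] > 1e-12) {
        memb[i] <- lab[t]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  match(memb, unique(memb))  # relabel to consecutive integers
}

#' Small-worldness
#'
#' The ratio `sigma = (C / C_null) / (L / L_null)`, where `C` is weighted
#' transitivity and `L` is characteristic path length, and the null
#' statistics are means over `n_null` Erdos-Renyi G(n, m) random graphs
#' with the same node and edge count, carrying the observed nonzero
#' weights in randomly permuted order. Values above 1 indicate clustering
#' in excess of a comparably connected random network.
#'
#' @inheritParams shortest_path_matrix
#' @param n_null Number of null networks (default 100).
#' @param seed Integer RNG seed (default 20110101).
#' @param null_model `"gnm"` (default): Erdos-Renyi graphs with the same
#'   node and edge count; `"rewire"`: degree-preserving edge rewiring of
#'   the observed topology. Both carry the observed weight multiset in
#'   permuted order.
#' @return A positive scalar.
#' @export
small_worldness <- function(connectome, n_null = 100, seed = 20110101,
                            null_model = c("gnm", "rewire")) {
  null_model <- match.arg(null_model)
  w <- conn_weights(connectome)
  stopifnot(n_null >= 1)
  n <- nrow(w)
  wts <- w[upper.tri(w)]
  wts <- sort(wts[wts > 0])  # canonical order: result invariant to node relabeling
  m <- length(wts)
  if (m == 0) stop("small-worldness undefined for an edgeless graph", call. = FALSE)
  c_obs <- transitivity_weighted(w)
  l_obs <- characteristic_path_length(w)
  cs <- numeric(n_null)
  ls <- numeric(n_null)
  gobs <- if (null_model == "rewire") as_weighted_graph(w) else NULL
  withr::with_seed(seed, {
    for (b in seq_len(n_null)) {
      g0 <- if (null_model == "gnm") {
        igraph::sample_gnm(n, m)
      } else {
        igraph::rewire(gobs, igraph::keeping_degseq(niter = 10 * m))
      }
      wn <- matrix(0, n, n)
      el <- igraph::as_edgelist(g0, names = FALSE)
      perm <- sample(wts)
      wn[el] <- perm
      wn <- pmax(wn, t(wn))
      cs[b] <- transitivity_weighted(wn)
      ls[b] <- characteristic_path_length(wn)
    }
  })
  (c_obs / mean(cs)) / (l_obs / mean(ls))
}

#' Compute the full metric set for one connectome
#'
#' @inheritParams shortest_path_matrix
#' @param n_null Null networks for small-worldness.
#' @param restarts Louvain restarts.
#' @param seed Integer RNG seed for the stochastic metrics.
#' @return A list of class `graph_metric_set` with the four metrics, the
#'   settings used, and the Louvain partition.
#' @export
metric_set <- function(connectome, n_null = 100, restarts = 20, seed = 20110101) {
  lv <- modularity_louvain(connectome, restarts = restarts, seed = seed)
  structure(list(
    subject_id = if (inherits(connectome, "connectome")) connectome$subject_id else NA_character_,
    global_efficiency = global_efficiency(connectome),
    transitivity = transitivity_weighted(connectome),
    modularity = lv$Q,
    small_worldness = small_worldness(connectome, n_null = n_null, seed = seed),
    partition = lv$membership,
    null_model_runs = n_null,
    seed = seed
  ), class = "graph_metric_set")
}

#' Natural logs of a metric set
#'
#' Graph metrics are log-transformed before regression to improve
#' distributional normality; the log is defined only for positive values.
#'
#' @param metrics A `graph_metric_set`.
#' @return Named numeric vector `log_global_efficiency`, `log_transitivity`,
#'   `log_modularity`, `log_small_worldness`.
#' @export
log_metrics <- function(metrics) {
  v <- c(global_efficiency = metrics$global_efficiency,
         transitivity = metrics$transitivity,
         modularity = metrics$modularity,
         small_worldness = metrics$small_worldness)
  if (any(v <= 0)) {
    stop("log transform undefined: nonpositive metric(s): ",
         paste(names(v)[v <= 0], collapse = ", "), call. = FALSE)
  }
  stats::setNames(log(v), paste0("log_", names(v)))
}

#' Metric table for a set of connectomes
#'
#' @param connectomes A list of `connectome` objects.
#' @param n_null,restarts,seed Passed to [metric_set()].
#' @return A data frame with one row per subject: the four metrics, their
#'   natural logs, and the settings used.
#' @export
metric_table <- function(connectomes, n_null = 100, restarts = 20,
                         seed = 20110101) {
  rows <- lapply(connectomes, function(cn) {
    ms <- metric_set(cn, n_null = n_null, restarts = restarts, seed = seed)
    lg <- log_metrics(ms)
    data.frame(subject_id = ms$subject_id,
               global_efficiency = ms$global_efficiency,
               transitivity = ms$transitivity,
               modularity = ms$modularity,
               small_worldness = ms$small_worldness,
               log_global_efficiency = lg[["log_global_efficiency"]],
               log_transitivity = lg[["log_transitivity"]],
               log_modularity = lg[["log_modularity"]],
               log_small_worldness = lg[["log_small_worldness"]],
               n_null = n_null, seed = seed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
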