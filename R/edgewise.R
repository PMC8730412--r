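#' Edge-wise permutation comparison of connectomes
#'
#' Covariate-adjusted, permutation-based comparison of every included
#' connectome edge between two groups, with link-based false-discovery-rate
#' control (Benjamini-Hochberg across edges) and direction-split reporting
#' of hypoconnected edges. Covariates are adjusted by the Freedman-Lane
#' scheme: residuals of the reduced (covariate-only) model are permuted
#' while group labels stay fixed.
#'
#' @name edgewise
NULL

#' Edgewise analysis configuration
#'
#' @param alpha Significance (FDR) level, default 0.05.
#' @param n_perm Number of permutations, default 5000.
#' @param covariates Names of covariate columns, default `"ga_mri"`
#'   (corrected gestational age at MRI).
#' @param inclusion_threshold Minimum within-group fraction of subjects
#'   with a nonzero weight for an edge to enter the analysis, default 0.5.
#' @param seed Integer RNG seed.
#' @return A list of class `edgewise_config`.
#' @export
edgewise_config <- function(alpha = 0.05, n_perm = 5000,
                            covariates = "ga_mri",
                            inclusion_threshold = 0.5, seed = 20110101) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 1,
            inclusion_threshold >= 0, inclusion_threshold <= 1)
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 covariates = covariates,
                 inclusion_threshold = inclusion_threshold,
                 seed = as.integer(seed)),
            class = "edgewise_config")
}

#' Stack connectome upper triangles into a subject-by-edge matrix
#'
#' @param connectomes List of `connectome` objects (shared atlas order).
#' @return An n_subject x n_pair matrix; columns are named by the
#'   unordered edge key `"<region a> | <region b>"`, rows by subject id.
#' @export
connectome_edge_matrix <- function(connectomes) {
  w1 <- conn_weights(connectomes[[1]])
  n <- nrow(w1)
  ut <- which(upper.tri(w1))
  rowi <- row(w1)[ut]
  colj <- col(w1)[ut]
  keys <- edge_key(rowi, colj, rownames(w1))
  Y <- t(vapply(connectomes, function(cn) conn_weights(cn)[ut],
                numeric(length(ut))))
  dimnames(Y) <- list(vapply(connectomes, `[[`, character(1), "subject_id"), keys)
  Y
}

#' Edge inclusion mask
#'
#' An edge is analyzed only if its weight is nonzero in at least
#' `threshold` fraction of the subjects within *each* group.
#'
#' @param connectomes List of `connectome` objects.
#' @param groups Two-level factor, one entry per connectome.
#' @param threshold Within-group nonzero fraction (default 0.5).
#' @return Character vector of included edge keys.
#' @export
edge_inclusion_mask <- function(connectomes, groups, threshold = 0.5) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2 || any(table(groups) < 2)) {
    stop("need two groups with at least 2 subjects each", call. = FALSE)
  }
  Y <- connectome_edge_matrix(connectomes)
  keep <- rep(TRUE, ncol(Y))
  for (lev in levels(groups)) {
    frac <- colMeans(Y[groups == lev, , drop = FALSE] > 0)
    keep <- keep & frac >= threshold
  }
  colnames(Y)[keep]
}

# design matrix: intercept + group indicator (level 2 of `groups`) + covariates
edgewise_design <- function(groups, covariates, n) {
  X <- cbind(`(Intercept)` = rep(1, n), group = as.numeric(groups) - 1)
  if (!is.null(covariates) && length(covariates) > 0 && NCOL(covariates) > 0) {
    cv <- as.matrix(as.data.frame(covariates))
    if (anyNA(cv)) stop("covariates must be complete (no missing values)", call. = FALSE)
    X <- cbind(X, cv)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stop("design matrix rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  X
}

# vectorized OLS t statistic of the group coefficient for every column of Y.
# Sign convention: the group column codes level 2, and the returned t is
# negated so that positive t = first group (level A) stronger.
edge_tstats_matrix <- function(Y, X, gcol) {
  n <- nrow(X)
  p <- ncol(X)
  XtXinv <- solve(crossprod(X))
  beta <- XtXinv %*% crossprod(X, Y)
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / (n - p)
  # constant residuals (to numerical precision): 0/0 contract gives t = 0
  degenerate <- sigma2 < 1e-20
  se <- sqrt(sigma2 * XtXinv[gcol, gcol])
  b <- beta[gcol, ]
  t <- ifelse(!degenerate, b / se, ifelse(abs(b) < 1e-10, 0, sign(b) * Inf))
  -t
}

#' Per-edge group statistics
#'
#' Ordinary least-squares fit of each included edge weight on the group
#' indicator plus covariates; the statistic is the t value of the group
#' coefficient, with positive values meaning the first group (level A of
#' `groups`) is stronger. Constant residuals yield a statistic of 0.
#'
#' @inheritParams edge_inclusion_mask
#' @param covariates Data frame (or NULL) of numeric covariates, one row
#'   per connectome.
#' @param edges Edge keys to analyze; defaults to the inclusion mask at
#'   threshold 0.5.
#' @return Named numeric vector of t statistics.
#' @export
edge_statistics <- function(connectomes, groups, covariates = NULL,
                            edges = edge_inclusion_mask(connectomes, groups)) {
  groups <- droplevels(as.factor(groups))
  Y <- connectome_edge_matrix(connectomes)[, edges, drop = FALSE]
  X <- edgewise_design(groups, covariates, nrow(Y))
  t <- edge_tstats_matrix(Y, X, gcol = 2L)
  stats::setNames(t, edges)
}

#' Freedman-Lane permutation p-values
#'
#' Residuals of the reduced (covariate-only) model are permuted `n_perm`
#' times with group labels fixed, the group t statistic is recomputed each
#' time, and the two-sided p-value is
#' `(1 + #permutations with |t*| >= |t_obs|) / (1 + n_perm)` (the add-one
#' convention, so p is never zero). Deterministic given `config$seed`.
#'
#' @inheritParams edge_statistics
#' @param config An [edgewise_config()].
#' @return Named numeric vector of permutation p-values in (0, 1\].
#' @export
permutation_pvalues <- function(connectomes, groups, covariates = NULL,
                                config = edgewise_config(),
                                edges = edge_inclusion_mask(
                                  connectomes, groups,
                                  config$inclusion_threshold)) {
  groups <- droplevels(as.factor(groups))
  Y <- connectome_edge_matrix(connectomes)[, edges, drop = FALSE]
  res <- freedman_lane(Y, groups, covariates, config)
  res$p_perm
}

# shared permutation engine on a prebuilt edge matrix
freedman_lane <- function(Y, groups, covariates, config) {
  n <- nrow(Y)
  if (config$n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  X <- edgewise_design(groups, covariates, n)
  t_obs <- edge_tstats_matrix(Y, X, gcol = 2L)
  Z <- X[, -2L, drop = FALSE]  # reduced model: intercept + covariates
  ZtZinv <- solve(crossprod(Z))
  fitted <- Z %*% (ZtZinv %*% crossprod(Z, Y))
  R <- Y - fitted
  thr <- abs(t_obs) - 1e-8 * (1 + abs(t_obs))  # tolerate arithmetic ties
  count <- integer(ncol(Y))
  withr::with_seed(config$seed, {
    for (b in seq_len(config$n_perm)) {
      perm <- sample.int(n)
      t_star <- edge_tstats_matrix(fitted + R[perm, , drop = FALSE], X, gcol = 2L)
      count <- count + (abs(t_star) >= thr)
    }
  })
  list(statistic = t_obs,
       p_perm = stats::setNames((1 + count) / (1 + config$n_perm), colnames(Y)))
}

#' Benjamini-Hochberg selection split by direction
#'
#' Step-up FDR control at level `alpha` across all included edges; the
#' selected edges are partitioned by the sign of the observed statistic
#' into hypoconnected-in-A (statistic negative: A weaker) and
#' hypoconnected-in-B (statistic positive: A stronger).
#'
#' @param p_perm Named permutation p-values.
#' @param alpha FDR level.
#' @param statistic Named observed statistics (positive = group A stronger).
#' @return List with `significant_hypo_A` and `significant_hypo_B`
#'   (character vectors of edge keys).
#' @export
fdr_select <- function(p_perm, alpha = 0.05, statistic) {
  adj <- stats::p.adjust(p_perm, method = "BH")
  sel <- names(p_perm)[adj <= alpha]
  s <- statistic[sel]
  list(significant_hypo_A = sel[s < 0],
       significant_hypo_B = sel[s > 0])
}

#' Region involvement counts
#'
#' Counts, for each region, the number of significant edges incident to
#' it, sorted descending with ties broken by atlas order.
#'
#' @param edges Character vector of edge keys (`"a | b"`).
#' @param atlas The atlas (for tie-break ordering).
#' @return Data frame with columns `region`, `count`, `rank`.
#' @export
roi_involvement <- function(edges, atlas = load_atlas()) {
  if (length(edges) == 0) {
    return(data.frame(region = character(0), count = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  ends <- unlist(strsplit(edges, " | ", fixed = TRUE))
  tab <- table(factor(ends, levels = atlas$name))
  tab <- tab[tab > 0]
  ord <- order(-as.integer(tab), match(names(tab), atlas$name))
  data.frame(region = names(tab)[ord],
             count = as.integer(tab)[ord],
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

#' Full edge-wise group comparison
#'
#' Runs inclusion masking, observed statistics, Freedman-Lane permutation
#' p-values and BH selection in one pass. Subjects are internally sorted
#' by subject id so the result is invariant to input ordering.
#'
#' @inheritParams edge_statistics
#' @param covariates Data frame of covariates, one row per connectome (in
#'   the same order as `connectomes`), restricted to
#'   `config$covariates`; or NULL for an unadjusted comparison.
#' @param config An [edgewise_config()].
#' @param atlas The atlas the connectomes are indexed by.
#' @return An `edgewise_result`: `included_edges`, `statistic`, `p_perm`,
#'   `significant_hypo_A`, `significant_hypo_B`, `roi_involvement` (over
#'   all significant edges), `groups` (level labels), `n_nonzero_A/B`,
#'   and the `config` used.
#' @export
edgewise_compare <- function(connectomes, groups, covariates = NULL,
                             config = edgewise_config(),
                             atlas = load_atlas()) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2 || any(table(groups) < 2)) {
    stop("need two groups with at least 2 subjects each", call. = FALSE)
  }
  ids <- vapply(connectomes, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) stop("duplicate subject ids", call. = FALSE)
  ord <- order(ids)
  connectomes <- connectomes[ord]
  groups <- groups[ord]
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)[ord, config$covariates, drop = FALSE]
  }
  Yall <- connectome_edge_matrix(connectomes)
  keep <- rep(TRUE, ncol(Yall))
  for (lev in levels(groups)) {
    frac <- colMeans(Yall[groups == lev, , drop = FALSE] > 0)
    keep <- keep & frac >= config$inclusion_threshold
  }
  edges <- colnames(Yall)[keep]
  Y <- Yall[, keep, drop = FALSE]
  fl <- freedman_lane(Y, groups, covariates, config)
  sel <- fdr_select(fl$p_perm, config$alpha, fl$statistic)
  sig <- c(sel$significant_hypo_A, sel$significant_hypo_B)
  structure(list(
    included_edges = edges,
    statistic = fl$statistic,
    p_perm = fl$p_perm,
    significant_hypo_A = sel$significant_hypo_A,
    significant_hypo_B = sel$significant_hypo_B,
    roi_involvement = roi_involvement(sig, atlas = atlas),
    n_nonzero_A = colSums(Y[groups == levels(groups)[1], , drop = FALSE] > 0),
    n_nonzero_B = colSums(Y[groups == levels(groups)[2], , drop = FALSE] > 0),
    groups = levels(groups),
    config = config
  ), class = "edgewise_result")
}

#' @export
print.edgewise_result <- function(x, ...) {
  cat("<edgewise_result>", length(x$included_edges), "edges included;",
      length(x$significant_hypo_A), "hypoconnected in", x$groups[1], ";",
      length(x$significant_hypo_B), "hypoconnected in", x$groups[2], "\n")
  invisible(x)
}

#' Edge result table
#'
#' @param x An `edgewise_result`.
#' @param ... Unused.
#' @return Data frame with columns `roi_i`, `roi_j`, `n_A_nonzero`,
#'   `n_B_nonzero`, `t`, `p_perm`, `selected`, `direction`.
#' @export
as.data.frame.edgewise_result <- function(x, ...) {
  ends <- do.call(rbind, strsplit(x$included_edges, " | ", fixed = TRUE))
  direction <- rep("", length(x$included_edges))
  direction[x$included_edges %in% x$significant_hypo_A] <- paste0("hypo_", x$groups[1])
  direction[x$included_edges %in% x$significant_hypo_B] <- paste0("hypo_", x$groups[2])
  data.frame(roi_i = ends[, 1], roi_j = ends[, 2],
             n_A_nonzero = as.integer(x$n_nonzero_A),
             n_B_nonzero = as.integer(x$n_nonzero_B),
             t = as.numeric(x$statistic),
             p_perm = as.numeric(x$p_perm),
             selected = direction != "",
             direction = direction,
             stringsAsFactors = FALSE)
}
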