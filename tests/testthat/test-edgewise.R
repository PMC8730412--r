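test_that("edge inclusion requires the threshold fraction in each group", {
  atlas <- test_atlas()
  nms <- atlas$name
  e1 <- nms[c(1, 2)]   # present in everyone
  e2 <- nms[c(3, 4)]   # present in 60% of A, 40% of B
  mk <- function(id, with_e2) {
    pairs <- rbind(e1, if (with_e2) e2)
    make_connectome(pairs, rep(0.5, nrow(pairs)), subject_id = id,
                    atlas = atlas)
  }
  conns <- c(lapply(1:5, function(i) mk(paste0("a", i), i <= 3)),
             lapply(1:5, function(i) mk(paste0("b", i), i <= 2)))
  groups <- rep(c("A", "B"), each = 5)
  inc <- edge_inclusion_mask(conns, groups, threshold = 0.5)
  k1 <- edge_key(1, 2, nms)
  k2 <- edge_key(3, 4, nms)
  expect_true(k1 %in% inc)    # present in all subjects
  expect_false(k2 %in% inc)   # 0.6 vs 0.4: fails in group B
  expect_length(inc, 1)       # everything else absent everywhere
  expect_error(edge_inclusion_mask(conns, rep("A", 10)), "two groups")
})

test_that("edge statistics equal a per-edge lm oracle and honour the sign convention", {
  atlas <- test_atlas()
  set.seed(31)
  gg <- make_group_connectomes(8, 8, density = 0.1, deficit = 0.1,
                               deficit_edges = planted_edge_set()[1:3, ],
                               atlas = atlas)
  cov <- data.frame(ga_mri = rnorm(16, 40, 1))
  tt <- edge_statistics(gg$connectomes, gg$groups, covariates = cov)
  Y <- connectome_edge_matrix(gg$connectomes)[, names(tt), drop = FALSE]
  g <- as.numeric(gg$groups) - 1
  for (k in sample(length(tt), 12)) {
    fit <- summary(lm(Y[, k] ~ g + cov$ga_mri))
    expect_equal(unname(tt[k]), -unname(fit$coefficients["g", "t value"]),
                 tolerance = 1e-10)
  }
  # planted deficit in B => B weaker => positive statistic (A stronger)
  planted_keys <- edge_key(atlas_lookup(atlas, planted_edge_set()[1:3, 1]),
                           atlas_lookup(atlas, planted_edge_set()[1:3, 2]),
                           atlas$name)
  expect_true(all(tt[planted_keys] > 0))
})

test_that("constant residuals give a zero statistic", {
  atlas <- test_atlas()
  nms <- atlas$name
  conns <- lapply(1:6, function(i) {
    make_connectome(rbind(nms[c(1, 2)]), 0.4, subject_id = paste0("s", i),
                    atlas = atlas)
  })
  tt <- edge_statistics(conns, rep(c("A", "B"), each = 3))
  expect_equal(unname(tt), 0)
})

test_that("a covariate fully explaining the group difference absorbs the statistic", {
  atlas <- test_atlas()
  set.seed(32)
  nms <- atlas$name
  n <- 40
  confound <- c(rnorm(n / 2, 38, 0.3), rnorm(n / 2, 42, 0.3))  # separates groups
  conns <- lapply(seq_len(n), function(i) {
    make_connectome(rbind(nms[c(1, 2)]),
                    0.2 + 0.01 * (confound[i] - 40) + rnorm(1, 0, 0.002),
                    subject_id = sprintf("s%02d", i), atlas = atlas)
  })
  groups <- rep(c("A", "B"), each = n / 2)
  t_raw <- edge_statistics(conns, groups, covariates = NULL)
  t_adj <- edge_statistics(conns, groups,
                           covariates = data.frame(ga_mri = confound))
  expect_gt(abs(t_raw), 5)
  expect_lt(abs(t_adj), 2.5)
  # perfectly collinear design errors with the column named
  expect_error(edge_statistics(conns, groups,
                               covariates = data.frame(g2 = as.numeric(groups == "B"))),
               "collinear")
})

test_that("permutation p-values hit the add-one floor for overwhelming effects and are deterministic", {
  atlas <- test_atlas()
  set.seed(33)
  gg <- make_group_connectomes(10, 10, density = 0.05, deficit = 0.25,
                               deficit_edges = planted_edge_set()[1:2, ],
                               atlas = atlas)
  cfg <- edgewise_config(n_perm = 99, seed = 11)
  p1 <- permutation_pvalues(gg$connectomes, gg$groups, config = cfg)
  planted_keys <- edge_key(atlas_lookup(atlas, planted_edge_set()[1:2, 1]),
                           atlas_lookup(atlas, planted_edge_set()[1:2, 2]),
                           atlas$name)
  expect_equal(unname(p1[planted_keys]), rep(1 / 100, 2))
  expect_true(all(p1 >= 1 / 100))
  p2 <- permutation_pvalues(gg$connectomes, gg$groups, config = cfg)
  expect_identical(p1, p2)
  expect_error(edgewise_config(n_perm = 0), "n_perm")
})

test_that("the full comparison is invariant to subject ordering", {
  atlas <- test_atlas()
  set.seed(34)
  gg <- make_group_connectomes(7, 7, density = 0.08, atlas = atlas)
  cov <- data.frame(ga_mri = rnorm(14, 40, 1))
  cfg <- edgewise_config(n_perm = 50, seed = 5)
  r1 <- edgewise_compare(gg$connectomes, gg$groups, cov, cfg, atlas = atlas)
  perm <- sample(14)
  r2 <- edgewise_compare(gg$connectomes[perm], gg$groups[perm],
                         cov[perm, , drop = FALSE], cfg, atlas = atlas)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_identical(r1$statistic, r2$statistic)
})

test_that("BH selection splits by direction per the step-up rule", {
  p <- c(e1 = 0.001, e2 = 0.002, e3 = 0.9, e4 = 0.9, e5 = 0.9)
  stat <- c(e1 = 3, e2 = -3, e3 = 1, e4 = -1, e5 = 0.5)
  sel <- fdr_select(p, 0.05, stat)
  expect_equal(sel$significant_hypo_B, "e1")  # positive: A stronger, B weak
  expect_equal(sel$significant_hypo_A, "e2")
  expect_equal(fdr_select(c(a = 1, b = 1), 0.05, c(a = 1, b = -1)),
               list(significant_hypo_A = character(0),
                    significant_hypo_B = character(0)))
  one <- fdr_select(c(z = 0.04), 0.05, c(z = 2))
  expect_equal(one$significant_hypo_B, "z")
})

test_that("region involvement counts incident significant edges with atlas tie-break", {
  atlas <- test_atlas()
  nms <- atlas$name
  edges <- c(edge_key(1, 2, nms), edge_key(1, 3, nms))
  inv <- roi_involvement(edges, atlas)
  expect_equal(inv$region[1], nms[1])
  expect_equal(inv$count, c(2, 1, 1))
  expect_equal(inv$region[2:3], nms[2:3])   # tie broken by atlas order
  expect_equal(sum(inv$count), 2 * length(edges))
  expect_equal(nrow(roi_involvement(character(0), atlas)), 0)
  star <- edge_key(rep(10, 5), 11:15, nms)
  inv2 <- roi_involvement(star, atlas)
  expect_equal(inv2$count[1], 5)
  expect_equal(inv2$region[1], nms[10])
})

test_that("edge result table carries counts, statistics and directions", {
  atlas <- test_atlas()
  set.seed(35)
  gg <- make_group_connectomes(6, 6, density = 0.05, atlas = atlas)
  r <- edgewise_compare(gg$connectomes, gg$groups,
                        config = edgewise_config(n_perm = 20, seed = 2),
                        atlas = atlas)
  df <- as.data.frame(r)
  expect_equal(nrow(df), length(r$included_edges))
  expect_true(all(df$n_A_nonzero >= 3))
  expect_true(all(df$p_perm >= 1 / 21))
  sig <- c(r$significant_hypo_A, r$significant_hypo_B)
  expect_true(all(sig %in% r$included_edges))
  expect_equal(length(intersect(r$significant_hypo_A, r$significant_hypo_B)), 0)
})
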