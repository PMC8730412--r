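# Shared fixtures built in code at test time.

test_atlas <- function() load_atlas()

# connectome with specified edge weights on named region pairs
make_connectome <- function(pairs, weights, subject_id = "T01",
                            atlas = test_atlas()) {
  n <- nrow(atlas)
  w <- matrix(0, n, n, dimnames = list(atlas$name, atlas$name))
  i <- atlas_lookup(atlas, pairs[, 1])
  j <- atlas_lookup(atlas, pairs[, 2])
  w[cbind(i, j)] <- weights
  w[cbind(j, i)] <- weights
  new_connectome(subject_id, w, atlas = atlas)
}

# random full-size connectome with given density
random_connectome <- function(subject_id = "R01", density = 0.3,
                              fa_mean = 0.3, fa_sd = 0.05,
                              atlas = test_atlas()) {
  n <- nrow(atlas)
  w <- matrix(0, n, n, dimnames = list(atlas$name, atlas$name))
  ut <- which(upper.tri(w))
  on <- sample(ut, round(density * length(ut)))
  w[on] <- pmin(pmax(stats::rnorm(length(on), fa_mean, fa_sd), 0.01), 1)
  w <- w + t(w)
  new_connectome(subject_id, w, atlas = atlas)
}

# small two-group cohort of connectomes sharing a template, with an
# optional deficit on chosen template edges in group B
make_group_connectomes <- function(n_a, n_b, density = 0.3, fa_mean = 0.3,
                                   fa_sd = 0.03, deficit_edges = NULL,
                                   deficit = 0, atlas = test_atlas()) {
  n <- nrow(atlas)
  ut <- which(upper.tri(matrix(0, n, n)))
  template <- sort(sample(ut, round(density * length(ut))))
  if (!is.null(deficit_edges)) {
    i <- atlas_lookup(atlas, deficit_edges[, 1])
    j <- atlas_lookup(atlas, deficit_edges[, 2])
    lin <- (pmax(i, j) - 1L) * n + pmin(i, j)
    template <- sort(union(template, lin))
    hit <- template %in% lin
  } else {
    hit <- rep(FALSE, length(template))
  }
  groups <- factor(rep(c("A", "B"), c(n_a, n_b)), levels = c("A", "B"))
  conns <- lapply(seq_len(n_a + n_b), function(s) {
    vals <- stats::rnorm(length(template), fa_mean, fa_sd)
    if (groups[s] == "B") vals[hit] <- vals[hit] - deficit
    w <- matrix(0, n, n, dimnames = list(atlas$name, atlas$name))
    w[template] <- pmin(pmax(vals, 0.001), 1)
    w <- w + t(w)
    new_connectome(sprintf("G%03d", s), w, atlas = atlas)
  })
  list(connectomes = conns, groups = groups,
       template_keys = colnames(connectome_edge_matrix(conns))[
         which(upper.tri(matrix(0, n, n))) %in% template])
}
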