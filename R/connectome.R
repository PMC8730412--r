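#' Construct a connectome object
#'
#' A connectome is a symmetric, zero-diagonal 90x90 matrix of mean
#' fractional anisotropy (FA) weights in \[0, 1\], with an optional parallel
#' matrix of streamline counts. Zero weight means "no connection observed"
#' (an FA of exactly zero is not produced by real tracts).
#'
#' @param subject_id Subject identifier.
#' @param weights 90x90 numeric matrix; row/column names must be the atlas
#'   region names in atlas order (set from `atlas` if missing).
#' @param counts Optional 90x90 nonnegative integer matrix of streamline
#'   counts; must be positive exactly where `weights` is positive.
#' @param atlas An `atlas_definition` used to label and validate dimensions.
#' @return An object of class `connectome`: a list with elements
#'   `subject_id`, `weights` and (optionally) `counts`.
#' @export
new_connectome <- function(subject_id, weights, counts = NULL,
                           atlas = load_atlas()) {
  n <- nrow(atlas)
  if (!is.matrix(weights) || !identical(dim(weights), c(n, n))) {
    stop("weights must be a ", n, "x", n, " matrix, got ",
         paste(dim(weights), collapse = "x"), call. = FALSE)
  }
  dimnames(weights) <- list(atlas$name, atlas$name)
  if (any(weights < 0) || any(weights > 1)) {
    stop("connectome weights must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(weights - t(weights))) > 1e-9) {
    stop("connectome weights must be symmetric", call. = FALSE)
  }
  if (any(diag(weights) != 0)) {
    stop("connectome diagonal must be zero", call. = FALSE)
  }
  out <- list(subject_id = as.character(subject_id), weights = weights)
  if (!is.null(counts)) {
    if (!identical(dim(counts), dim(weights))) {
      stop("counts must match weight dimensions", call. = FALSE)
    }
    if (any(counts < 0) || any(counts != round(counts))) {
      stop("counts must be nonnegative integers", call. = FALSE)
    }
    if (max(abs(counts - t(counts))) != 0) {
      stop("counts must be symmetric", call. = FALSE)
    }
    if (!all((weights > 0) == (counts > 0))) {
      stop("weight > 0 must coincide with count > 0", call. = FALSE)
    }
    dimnames(counts) <- dimnames(weights)
    out$counts <- counts
  }
  structure(out, class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  v <- validate_connectome(x)
  cat("<connectome> subject", x$subject_id,
      sprintf("| density %.3f | %d isolated regions\n", v$density, v$n_isolated))
  invisible(x)
}

# accept a connectome or a bare symmetric matrix
conn_weights <- function(x) {
  if (inherits(x, "connectome")) x$weights else as.matrix(x)
}

#' Build a connectome from a streamline summary table
#'
#' Each record is one streamline with its mean FA between two regions. The
#' edge weight is the unweighted arithmetic mean of the FA values of all
#' streamlines connecting the pair (in either orientation); the count
#' matrix records how many streamlines contributed. Pairs with no
#' streamlines get weight zero.
#'
#' @param streams Data frame with columns `roi_i`, `roi_j` (region names)
#'   and `fa` (in \[0, 1\]).
#' @param atlas An `atlas_definition`.
#' @param subject_id Subject identifier.
#' @return A `connectome` with a `counts` matrix.
#' @export
build_connectome <- function(streams, atlas, subject_id) {
  stopifnot(is.data.frame(streams),
            all(c("roi_i", "roi_j", "fa") %in% names(streams)))
  n <- nrow(atlas)
  wsum <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  if (nrow(streams) == 0L) {
    warning("empty streamline set: returning an all-zero connectome", call. = FALSE)
  } else {
    i <- atlas_lookup(atlas, streams$roi_i)
    j <- atlas_lookup(atlas, streams$roi_j)
    if (any(i == j)) {
      stop("streamline records must connect two distinct regions", call. = FALSE)
    }
    if (any(streams$fa < 0 | streams$fa > 1)) {
      stop("streamline fa values must lie in [0, 1]", call. = FALSE)
    }
    a <- pmin(i, j)
    b <- pmax(i, j)
    key <- (a - 1L) * n + b  # linear index of the upper-triangle cell
    sums <- rowsum(streams$fa, key)
    kidx <- as.integer(rownames(sums))
    wsum[cbind((kidx - 1L) %/% n + 1L, (kidx - 1L) %% n + 1L)] <- sums[, 1]
    counts <- rowsum(rep(1L, length(key)), key)
    cnt[cbind((kidx - 1L) %/% n + 1L, (kidx - 1L) %% n + 1L)] <- counts[, 1]
  }
  w <- ifelse(cnt > 0, wsum / pmax(cnt, 1), 0)
  w <- w + t(w)
  cnt <- cnt + t(cnt)
  new_connectome(subject_id, w, counts = cnt, atlas = atlas)
}

#' Read / write a connectome as a dense labelled CSV
#'
#' The on-disk format is a dense 90x90 matrix with a header row and a
#' first column both carrying the atlas region names in atlas order.
#' Weights are written with 17 significant digits so the round trip is
#' bit-exact. The reader symmetrizes by averaging when the asymmetry is
#' within `tol`, and rejects larger asymmetries.
#'
#' @param path File path.
#' @param atlas An `atlas_definition`.
#' @param subject_id Subject identifier; defaults to the file stem.
#' @param tol Maximum tolerated absolute asymmetry (default 1e-9).
#' @return `read_connectome_csv` returns a `connectome`;
#'   `write_connectome_csv` returns `path` invisibly.
#' @export
read_connectome_csv <- function(path, atlas,
                                subject_id = tools::file_path_sans_ext(basename(path)),
                                tol = 1e-9) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- raw[[1]]
  m <- as.matrix(raw[, -1, drop = FALSE])
  n <- nrow(atlas)
  if (!identical(dim(m), c(n, n))) {
    stop("connectome CSV must be ", n, "x", n, ", got ",
         paste(dim(m), collapse = "x"), call. = FALSE)
  }
  if (!identical(rn, atlas$name) || !identical(colnames(m), atlas$name)) {
    stop("connectome CSV row/column names must be the atlas region names in atlas order",
         call. = FALSE)
  }
  if (!is.numeric(m) || anyNA(m)) {
    stop("connectome CSV contains non-numeric or missing entries", call. = FALSE)
  }
  bad <- which(m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("weight out of [0, 1] at row '%s', column '%s' (value %g)",
                 rn[bad[1, 1]], colnames(m)[bad[1, 2]], m[bad[1, , drop = FALSE]]),
         call. = FALSE)
  }
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    stop(sprintf("connectome CSV asymmetry %.3g exceeds tolerance %g", asym, tol),
         call. = FALSE)
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  new_connectome(subject_id, m, atlas = atlas)
}

#' @rdname read_connectome_csv
#' @param connectome A `connectome` to write.
#' @export
write_connectome_csv <- function(connectome, path) {
  w <- connectome$weights
  # region names contain commas: quote every label field
  header <- paste(c("region", sprintf("\"%s\"", colnames(w))), collapse = ",")
  body <- vapply(seq_len(nrow(w)), function(i) {
    paste(c(sprintf("\"%s\"", rownames(w)[i]), sprintf("%.17g", w[i, ])),
          collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Validate a connectome and summarize its structure
#'
#' Reports violated invariants (symmetry, zero diagonal, weight range),
#' the edge density (fraction of nonzero upper-triangle entries) and the
#' number of isolated regions. This is a reporting operation: it never
#' errors.
#'
#' @param connectome A `connectome` or bare weight matrix.
#' @return A list with `violations` (character vector, empty when valid),
#'   `density` and `n_isolated`.
#' @export
validate_connectome <- function(connectome) {
  w <- conn_weights(connectome)
  violations <- character(0)
  if (max(abs(w - t(w))) > 1e-9) violations <- c(violations, "asymmetric weights")
  if (any(diag(w) != 0)) violations <- c(violations, "nonzero diagonal")
  if (any(w < 0) || any(w > 1)) violations <- c(violations, "weights outside [0, 1]")
  ut <- w[upper.tri(w)]
  list(
    violations = violations,
    density = mean(ut != 0),
    n_isolated = sum(rowSums(w != 0) == 0)
  )
}
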