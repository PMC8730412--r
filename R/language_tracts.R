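#' Built-in left-hemisphere language tract definitions
#'
#' Five hypothesis-based white-matter pathways implicated in language,
#' encoded as sets of unordered left-hemisphere region-name pairs on the
#' 90-region parcellation: the three branches of the superior longitudinal
#' fasciculus (SLF 1: superior parietal to dorsal/medial superior frontal
#' and supplementary motor cortex; SLF 2: inferior parietal lobule to
#' middle and dorsal superior frontal cortex; SLF 3: supramarginal gyrus
#' to seven frontal targets), the inferior longitudinal fasciculus
#' (occipital/lingual/cuneal to anterior temporal regions, 12 pairs) and
#' the arcuate fasciculus (superior and middle temporal gyri to opercular,
#' triangular and orbital inferior frontal cortex, 6 pairs).
#'
#' @param path JSON file of tract definitions; defaults to the packaged
#'   set. User-supplied files use the same schema: a list of objects with
#'   `name`, `aggregation` (`"mean"` or `"sum"`) and `pairs` (list of
#'   2-element region-name arrays).
#' @param atlas Atlas used to validate region names.
#' @return A named list of `tract_definition` objects (fields `name`,
#'   `aggregation`, `pairs`: a 2-column character matrix).
#' @export
builtin_tracts <- function(path = system.file("extdata", "language_tracts.json",
                                              package = "neonconn"),
                           atlas = load_atlas()) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tracts <- lapply(raw, function(t) {
    pairs <- do.call(rbind, lapply(t$pairs, function(p) c(p[[1]], p[[2]])))
    new_tract_definition(t$name, pairs, t$aggregation, atlas = atlas)
  })
  stats::setNames(tracts, vapply(tracts, `[[`, character(1), "name"))
}

#' Construct and validate a tract definition
#'
#' @param name Tract name.
#' @param pairs 2-column character matrix of region-name pairs.
#' @param aggregation `"mean"` (default) or `"sum"`.
#' @param atlas Atlas used to validate region names.
#' @return A `tract_definition`.
#' @export
new_tract_definition <- function(name, pairs, aggregation = "mean",
                                 atlas = load_atlas()) {
  stopifnot(is.matrix(pairs), ncol(pairs) == 2, nrow(pairs) >= 1)
  aggregation <- match.arg(aggregation, c("mean", "sum"))
  i <- atlas_lookup(atlas, pairs[, 1])
  j <- atlas_lookup(atlas, pairs[, 2])
  if (any(i == j)) stop("tract pairs must connect distinct regions", call. = FALSE)
  keys <- edge_key(i, j, atlas$name)
  if (anyDuplicated(keys)) {
    stop("duplicate region pairs in tract '", name, "'", call. = FALSE)
  }
  structure(list(name = name, aggregation = aggregation, pairs = pairs),
            class = "tract_definition")
}

#' Tract connectivity score for one subject
#'
#' Aggregates the connectome's FA weights over a tract's region pairs.
#' Absent edges contribute zero rather than being dropped: a missing
#' connection is informative hypoconnectivity, and dropping it would
#' inflate the mean.
#'
#' @param connectome A `connectome`.
#' @param tract A `tract_definition`.
#' @param atlas The atlas the connectome is indexed by.
#' @param aggregation Override the tract's aggregation mode.
#' @return The aggregated score, with attribute `n_zero` (number of
#'   zero-weight pairs). Warns when every listed pair is absent.
#' @export
tract_connectivity <- function(connectome, tract, atlas = load_atlas(),
                               aggregation = tract$aggregation) {
  aggregation <- match.arg(aggregation, c("mean", "sum"))
  w <- conn_weights(connectome)
  i <- atlas_lookup(atlas, tract$pairs[, 1])
  j <- atlas_lookup(atlas, tract$pairs[, 2])
  vals <- w[cbind(i, j)]
  if (all(vals == 0)) {
    warning("all ", nrow(tract$pairs), " pairs of tract '", tract$name,
            "' are absent in this connectome", call. = FALSE)
  }
  out <- if (aggregation == "mean") mean(vals) else sum(vals)
  attr(out, "n_zero") <- sum(vals == 0)
  out
}

#' Per-subject tract score table
#'
#' @param connectomes List of `connectome` objects.
#' @param tracts List of `tract_definition`s (default: the built-in five).
#' @param atlas The atlas the connectomes are indexed by.
#' @return Data frame: `subject_id` plus one column per tract.
#' @export
tract_score_table <- function(connectomes, tracts = builtin_tracts(atlas = atlas),
                              atlas = load_atlas()) {
  rows <- lapply(connectomes, function(cn) {
    scores <- vapply(tracts, function(t) {
      as.numeric(tract_connectivity(cn, t, atlas = atlas))
    }, numeric(1))
    cbind(data.frame(subject_id = cn$subject_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(scores)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
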