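#' Load the 90-region infant parcellation
#'
#' Reads the packaged atlas table: 90 cerebral regions of interest on a
#' neonatal parcellation following the AAL-90 naming scheme, 45 per
#' hemisphere, with descriptive names of the form
#' `"fusiform gyrus, left"`. All connectome matrices in this package are
#' indexed in atlas row order, and all edge identifiers are unordered
#' region-name pairs.
#'
#' @param path Path to an atlas CSV with columns `index` (0-89), `name`
#'   (unique descriptive name) and `hemisphere` (`"left"`/`"right"`).
#'   Defaults to the packaged table.
#' @return A data frame of class `atlas_definition` with columns `index`,
#'   `name`, `hemisphere`, in matrix row order.
#' @export
load_atlas <- function(path = system.file("extdata", "aal90_infant_atlas.csv",
                                          package = "neonconn")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("atlas resource not found: packaged file is missing or corrupt", call. = FALSE)
  }
  atlas <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("index", "name", "hemisphere")
  if (!all(required %in% names(atlas))) {
    stop("atlas file must have columns index, name, hemisphere", call. = FALSE)
  }
  atlas <- atlas[required]
  if (nrow(atlas) != 90L) {
    stop("atlas must define exactly 90 regions, got ", nrow(atlas), call. = FALSE)
  }
  if (anyDuplicated(atlas$name)) {
    stop("atlas region names must be unique", call. = FALSE)
  }
  if (!identical(sort(atlas$index), 0:89)) {
    stop("atlas indices must be 0..89", call. = FALSE)
  }
  if (!all(atlas$hemisphere %in% c("left", "right")) ||
      sum(atlas$hemisphere == "left") != 45L) {
    stop("atlas must have 45 left and 45 right regions", call. = FALSE)
  }
  atlas <- atlas[order(atlas$index), , drop = FALSE]
  rownames(atlas) <- NULL
  class(atlas) <- c("atlas_definition", "data.frame")
  atlas
}

#' Resolve region names to matrix positions
#'
#' @param atlas An `atlas_definition`.
#' @param names Character vector of region names.
#' @return Integer vector of 1-based matrix row positions.
#' @export
atlas_lookup <- function(atlas, names) {
  pos <- match(names, atlas$name)
  if (anyNA(pos)) {
    bad <- unique(names[is.na(pos)])
    stop("unresolvable region name(s): ", paste(bad, collapse = "; "), call. = FALSE)
  }
  pos
}

#' Region names in matrix order
#' @param atlas An `atlas_definition`.
#' @return Character vector of length 90.
#' @export
region_names <- function(atlas) atlas$name

#' Canonical unordered edge label
#'
#' Edges are identified throughout the package by the label
#' `"<region a> | <region b>"` with the two endpoints in atlas order, so
#' that (i, j) and (j, i) map to the same key.
#'
#' @param i,j Integer matrix positions of the two endpoints.
#' @param nms Region names in matrix order.
#' @return Character vector of edge keys.
#' @export
edge_key <- function(i, j, nms) {
  a <- pmin(i, j)
  b <- pmax(i, j)
  paste(nms[a], nms[b], sep = " | ")
}
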