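#' Dynamic time warping distance
#'
#' Classic dynamic-programming DTW between two vector time series: local
#' cost is the Euclidean distance between aligned vectors, admissible steps
#' are `(1,0)`, `(0,1)` and `(1,1)`, with no band constraint. Symmetric,
#' nonnegative, and zero for identical series. The dynamic program runs in
#' C++.
#'
#' @param a,b Numeric matrices with one time point per row (a plain vector
#'   is treated as a scalar series), equal column counts.
#' @return Nonnegative alignment cost.
#' @export
dtw_distance <- function(a, b) {
  a <- series_matrix(a)
  b <- series_matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("series must be nonempty")
  if (ncol(a) != ncol(b))
    stop("series dimensions differ: ", ncol(a), " vs ", ncol(b))
  dtw_dp(a, b)
}

series_matrix <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 1) else as.matrix(x)
}

#' DTW 1-nearest-neighbour classification
#'
#' Assigns the label of the [dtw_distance()]-nearest template; distance
#' ties go to the class earliest in `classes`.
#'
#' @param query A series (matrix or vector).
#' @param templates List of template series.
#' @param labels Template labels (same length as `templates`).
#' @param classes Class order used for tie-breaking; defaults to the
#'   taxonomy order for known labels.
#' @return The predicted label.
#' @export
dtw_classify <- function(query, templates, labels, classes = NULL) {
  if (!length(templates)) stop("empty template set")
  stopifnot(length(templates) == length(labels))
  if (is.null(classes)) classes <- canonical_classes(labels)
  d <- vapply(templates, function(s) dtw_distance(query, s), numeric(1))
  nearest <- which(d == min(d))
  if (length(nearest) > 1) {
    ord <- match(labels[nearest], classes)
    nearest <- nearest[which.min(ord)]
  }
  labels[nearest[1]]
}

canonical_classes <- function(labels) {
  known <- names(activity_classes())
  u <- unique(as.character(labels))
  if (all(u %in% known)) known[known %in% u] else sort(u)
}

#' Per-frame descriptor series of a record
#'
#' The motion stream representation used by the DTW baseline: the
#' spine-centred per-frame region descriptors ([region_descriptors()])
#' flattened to one 42-dimensional vector per frame (6 regions x centre,
#' direction, distance).
#'
#' @param seq A [skeleton_sequence()].
#' @return Numeric matrix, frames x 42.
#' @export
record_series <- function(seq) {
  desc <- region_descriptors(normalize_skeleton(seq))
  matrix(desc, nrow = dim(desc)[1])
}
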