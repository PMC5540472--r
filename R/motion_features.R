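#' Spine-centre a skeleton sequence
#'
#' Re-expresses every frame with the spine joint as the origin: each joint's
#' coordinates minus the frame's spine coordinates. This removes the
#' patient's absolute position in the sensor frame; inter-joint geometry is
#' untouched. Idempotent.
#'
#' @param seq A [skeleton_sequence()].
#' @return A spine-centred `skeleton_sequence`.
#' @export
normalize_skeleton <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  if (!"spine" %in% dimnames(seq$xyz)[[2]]) stop("missing spine joint")
  spine <- seq$xyz[, "spine", , drop = FALSE]   # nf x 1 x 3
  xyz <- sweep(seq$xyz, c(1, 3), spine[, 1, ], `-`)
  skeleton_sequence(seq$t, xyz)
}

#' Per-frame body-region descriptors
#'
#' For each frame and each of the six body regions ([body_regions()]),
#' computes the region centre (mean of the member joints, spine-relative),
#' its direction (centre normalised to unit length; the zero vector when the
#' centre sits at the origin) and its distance (Euclidean norm of the
#' centre).
#'
#' @param seq A spine-centred [skeleton_sequence()] (see
#'   [normalize_skeleton()]).
#' @return Numeric array `[frame, region, component]` with components
#'   `cx,cy,cz,dx,dy,dz,dist` (centre, direction, distance).
#' @export
region_descriptors <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  regions <- body_regions()
  nf <- n_frames(seq)
  out <- array(0, c(nf, length(regions), 7),
               dimnames = list(NULL, names(regions),
                               c("cx", "cy", "cz", "dx", "dy", "dz", "dist")))
  for (r in seq_along(regions)) {
    members <- regions[[r]]
    ctr <- apply(seq$xyz[, members, , drop = FALSE], c(1, 3), mean)
    if (nf == 1) ctr <- matrix(ctr, 1, 3)
    dist <- sqrt(rowSums(ctr^2))
    dir <- ctr / ifelse(dist > 0, dist, 1)    # zero-norm centre -> zero dir
    dir[dist == 0, ] <- 0
    out[, r, 1:3] <- ctr
    out[, r, 4:6] <- dir
    out[, r, 7] <- dist
  }
  out
}

# Sizes of k contiguous segments of n items: as equal as possible, earlier
# segments take the remainder.
segment_sizes <- function(n, k) {
  stopifnot(n >= k, k >= 1)
  base <- n %/% k
  base + as.integer(seq_len(k) <= n %% k)
}

#' Split items into k contiguous, order-preserving segments
#'
#' @param n Number of items (frames or samples), at least `k`.
#' @param k Number of segments (default 3, the record-division scheme used by
#'   both feature extractors).
#' @return List of `k` integer index vectors partitioning `1:n` in order;
#'   segment sizes differ by at most one, with earlier segments taking the
#'   remainder.
#' @export
segment_record <- function(n, k = 3) {
  if (inherits(n, "skeleton_sequence")) n <- n_frames(n)
  n <- as.integer(n)
  if (n < k) stop("cannot split ", n, " items into ", k, " segments")
  sizes <- segment_sizes(n, k)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  mapply(function(a, b) seq.int(a, b), starts, ends, SIMPLIFY = FALSE)
}

#' Extract the 200-dimensional motion feature vector
#'
#' The layout, built only from region centres, directions, distances and
#' their temporal change over a three-way record division:
#' \itemize{
#'   \item per segment (3) and region (6): mean centre `x,y,z`, mean
#'     direction `x,y,z`, mean distance — 126 values;
#'   \item inter-segment region-centre displacements (segment-mean centres,
#'     segment 2 minus 1 and 3 minus 2): 6 regions x 3 coords x 2 — 36;
#'   \item per segment and region: mean frame-to-frame centre speed (m/s) —
#'     18;
#'   \item per joint (20): whole-record displacement norm, last minus first
#'     frame — 20.
#' }
#' The sequence is spine-centred first, so the vector is invariant to any
#' constant translation of the skeleton. Values are raw (metres, m/s);
#' dataset-level min-max scaling to \[0,1\] is applied separately with
#' [fit_feature_scaler()].
#'
#' @param seq A [skeleton_sequence()] with at least 3 frames.
#' @param scaler Optional scaler from [fit_feature_scaler()]; if supplied the
#'   vector is min-max scaled and clipped to \[0,1\].
#' @return Numeric vector of length 200.
#' @export
extract_motion_features <- function(seq, scaler = NULL) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  if (n_frames(seq) < 3) stop("need at least 3 frames for motion features")
  seq <- normalize_skeleton(seq)
  desc <- region_descriptors(seq)
  idx <- segment_record(n_frames(seq), 3)

  seg_summary <- lapply(idx, function(ii) {
    apply(desc[ii, , , drop = FALSE], c(2, 3), mean)    # 6 x 7
  })
  part1 <- unlist(lapply(seg_summary, function(m) as.vector(t(m))))  # 126

  centers <- lapply(seg_summary, function(m) m[, 1:3, drop = FALSE]) # 6 x 3
  part2 <- c(as.vector(t(centers[[2]] - centers[[1]])),
             as.vector(t(centers[[3]] - centers[[2]])))              # 36

  part3 <- unlist(lapply(idx, function(ii) {                         # 18
    if (length(ii) < 2) return(numeric(6))
    ctr <- desc[ii, , 1:3, drop = FALSE]
    dt <- diff(seq$t[ii])
    step <- sqrt(apply((ctr[-1, , , drop = FALSE] -
                        ctr[-length(ii), , , drop = FALSE])^2, c(1, 2), sum))
    if (length(ii) == 2) step <- matrix(step, 1)
    colMeans(step / dt)
  }))

  nf <- n_frames(seq)
  part4 <- sqrt(rowSums((seq$xyz[nf, , ] - seq$xyz[1, , ])^2))       # 20

  v <- c(part1, part2, part3, unname(part4))
  stopifnot(length(v) == 200, all(is.finite(v)))
  if (!is.null(scaler)) v <- as.vector(apply_feature_scaler(rbind(v), scaler))
  v
}

#' Motion feature matrix for a dataset
#'
#' @param dataset A `caresig_dataset`.
#' @return Numeric matrix, one 200-dimensional raw (unscaled) row per record.
#' @export
motion_feature_matrix <- function(dataset) {
  t(vapply(dataset, function(r) extract_motion_features(r$skeleton),
           numeric(200)))
}

#' Min-max feature scaler
#'
#' Fits per-dimension minima and maxima on a training feature matrix;
#' applying the scaler maps training values into \[0,1\] and clips unseen
#' values into the same range (the autoencoders reconstruct through a
#' sigmoid, so inputs must live in the unit interval). Constant dimensions
#' map to 0.
#'
#' @param X Numeric training matrix (records x features).
#' @return An object of class `feature_scaler`.
#' @export
fit_feature_scaler <- function(X) {
  X <- as.matrix(X)
  structure(list(min = apply(X, 2, min), max = apply(X, 2, max)),
            class = "feature_scaler")
}

#' @rdname fit_feature_scaler
#' @param scaler A fitted `feature_scaler`.
#' @export
apply_feature_scaler <- function(X, scaler) {
  X <- as.matrix(X)
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1
  out <- sweep(sweep(X, 2, scaler$min, `-`), 2, rng, `/`)
  pmin(pmax(out, 0), 1)
}
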