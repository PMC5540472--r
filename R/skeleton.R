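#' The 20-joint skeleton registry
#'
#' Names of the 20 joints tracked by a first-generation depth camera skeleton
#' (head, shoulder centre, spine, hip centre, and left/right shoulder, elbow,
#' wrist, hand, hip, knee, ankle, foot). All skeleton containers in the
#' package index joints by these names, in this order.
#'
#' @return Character vector of length 20.
#' @export
kinect_joints <- function() {
  c("head", "shoulder_center", "spine", "hip_center",
    "left_shoulder", "left_elbow", "left_wrist", "left_hand",
    "right_shoulder", "right_elbow", "right_wrist", "right_hand",
    "left_hip", "left_knee", "left_ankle", "left_foot",
    "right_hip", "right_knee", "right_ankle", "right_foot")
}

#' Resting (seated) reference posture
#'
#' A fixed seated skeleton used as the base posture for every activity class:
#' the patients the system targets are bed- or chair-bound, so all motion
#' motifs are deviations from a seated rest. Coordinates are metres in a
#' right-handed sensor-facing frame: x lateral, y up, z distance from the
#' sensor (torso at about 2 m).
#'
#' @return A 20 x 3 numeric matrix, rows named by [kinect_joints()],
#'   columns `x`, `y`, `z`.
#' @export
resting_posture <- function() {
  m <- rbind(
    head            = c( 0.00,  0.70, 2.00),
    shoulder_center = c( 0.00,  0.50, 2.00),
    spine           = c( 0.00,  0.25, 2.00),
    hip_center      = c( 0.00,  0.00, 2.00),
    left_shoulder   = c( 0.18,  0.45, 2.00),
    left_elbow      = c( 0.25,  0.20, 2.00),
    left_wrist      = c( 0.20,  0.00, 1.85),
    left_hand       = c( 0.18,  0.00, 1.80),
    right_shoulder  = c(-0.18,  0.45, 2.00),
    right_elbow     = c(-0.25,  0.20, 2.00),
    right_wrist     = c(-0.20,  0.00, 1.85),
    right_hand      = c(-0.18,  0.00, 1.80),
    left_hip        = c( 0.12, -0.02, 2.00),
    left_knee       = c( 0.14,  0.00, 1.65),
    left_ankle      = c( 0.14, -0.40, 1.65),
    left_foot       = c( 0.14, -0.45, 1.58),
    right_hip       = c(-0.12, -0.02, 2.00),
    right_knee      = c(-0.14,  0.00, 1.65),
    right_ankle     = c(-0.14, -0.40, 1.65),
    right_foot      = c(-0.14, -0.45, 1.58)
  )
  colnames(m) <- c("x", "y", "z")
  m[kinect_joints(), , drop = FALSE]
}

#' Body-region definitions for motion features
#'
#' The six body regions the motion features summarise, with their member
#' joints. Region centres are the mean of the member joints; regions were
#' chosen to cover the body parts whose position carries the help-requirement
#' signal (hands, head/neck, pelvis, knees).
#'
#' @return Named list of character vectors (member joint names), in the fixed
#'   region order `cervical`, `left_wrist`, `right_wrist`, `crotch`,
#'   `left_knee`, `right_knee`.
#' @export
body_regions <- function() {
  list(
    cervical    = c("head", "shoulder_center"),
    left_wrist  = c("left_wrist", "left_hand"),
    right_wrist = c("right_wrist", "right_hand"),
    crotch      = c("hip_center", "left_hip", "right_hip"),
    left_knee   = c("left_knee", "left_ankle"),
    right_knee  = c("right_knee", "right_ankle")
  )
}

#' Construct a skeleton sequence
#'
#' @param t Numeric vector of frame timestamps in seconds, strictly
#'   increasing.
#' @param xyz Numeric array `[frame, joint, coordinate]` with 20 named joints
#'   and coordinates `x`,`y`,`z`, in metres.
#' @return An object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(t, xyz) {
  stopifnot(is.numeric(t), length(dim(xyz)) == 3)
  if (dim(xyz)[1] != length(t))
    stop("frame count of `xyz` does not match length of `t`")
  if (dim(xyz)[2] != 20L)
    stop("a skeleton sequence needs all 20 joints")
  if (is.null(dimnames(xyz)[[2]]) || !setequal(dimnames(xyz)[[2]], kinect_joints()))
    stop("joint dimension of `xyz` must be named with the 20 standard joints")
  if (length(t) > 1 && any(diff(t) <= 0))
    stop("timestamps must be strictly increasing")
  xyz <- xyz[, kinect_joints(), , drop = FALSE]
  structure(list(t = as.numeric(t), xyz = xyz), class = "skeleton_sequence")
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf("<skeleton_sequence: %d frames, %.2f s, 20 joints>\n",
              length(x$t), if (length(x$t)) diff(range(x$t)) else 0))
  invisible(x)
}

n_frames <- function(seq) length(seq$t)

#' Construct an EEG record
#'
#' @param t Numeric vector of sample timestamps in seconds.
#' @param signals Numeric matrix `samples x 8`, columns named with the
#'   electrode sites `F3,F4,C3,C4,T5,T6,O1,O2`, in microvolts.
#' @param rate Sampling rate in samples per second.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(t, signals, rate) {
  signals <- as.matrix(signals)
  if (ncol(signals) != 8L || is.null(colnames(signals)) ||
      !setequal(colnames(signals), eeg_channels()))
    stop("EEG signals must have the 8 named channels ",
         paste(eeg_channels(), collapse = ","))
  if (nrow(signals) != length(t))
    stop("sample count does not match timestamps")
  signals <- signals[, eeg_channels(), drop = FALSE]
  structure(list(t = as.numeric(t), signals = signals, rate = rate),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record: %d samples x 8 channels @ %g Hz>\n",
              nrow(x$signals), x$rate))
  invisible(x)
}

#' EEG electrode montage
#'
#' The eight 10-20 electrode sites used by the system.
#' @return Character vector of channel names.
#' @export
eeg_channels <- function() c("F3", "F4", "C3", "C4", "T5", "T6", "O1", "O2")
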