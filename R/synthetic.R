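#' Activity-class registry for the synthetic generator
#'
#' One specification per help-requirement class in the nine-class taxonomy
#' (sleeping, standing, walking, drinking, eating, defecation, urination,
#' calling the doctor, nothing). Each spec carries a motion motif — a set of
#' parameterised joint movements away from the resting posture (target joint,
#' target point, oscillation amplitude in metres, oscillation frequency in
#' Hz, plus follower joints that move a fraction of the primary displacement)
#' — and an EEG profile of relative band-power weights (delta, theta, alpha,
#' beta) per channel.
#'
#' Class information is deliberately split across modalities, mirroring the
#' structure of the real taxonomy: drinking/eating share one motion motif
#' ("hand near the mouth") and are separated only by their EEG profiles
#' (thirsty: alpha-dominant vs hungry: theta-dominant), as do
#' defecation/urination ("head movement" with different urgency profiles);
#' conversely standing/walking share one EEG profile (vibrant/intent:
#' beta-dominant) and are separated only by motion (open arms vs knee up).
#'
#' @return Named list of 9 `activity_class_spec` objects, in taxonomy order.
#' @export
activity_classes <- function() {
  mov <- function(joint, target, amplitude, freq, followers = NULL) {
    list(joint = joint, target = target, amplitude = amplitude,
         freq = freq, followers = followers)
  }
  # band weights in order delta, theta, alpha, beta
  spec <- function(label, motif, bands, duration_range = c(2, 3)) {
    stopifnot(all(bands >= 0), duration_range[1] >= 2)
    structure(list(label = label, motion_motif = motif,
                   eeg_profile = expand_eeg_profile(bands),
                   duration_range = duration_range),
              class = "activity_class_spec")
  }
  hand_to_mouth <- list(
    mov("right_hand", c(0.00, 0.60, 1.90), 0.02, 0.5,
        c(right_wrist = 0.85, right_elbow = 0.45))
  )
  head_move <- list(
    mov("head", c(0.08, 0.68, 2.00), 0.05, 0.8, c(shoulder_center = 0.3))
  )
  list(
    sleeping = spec("sleeping",
      list(mov("right_hand", c(0.07, 0.64, 1.94), 0.01, 0.2,
               c(right_wrist = 0.85, right_elbow = 0.45))),
      bands = c(1.6, 0.8, 0.3, 0.2)),
    standing = spec("standing",
      list(mov("left_hand", c(0.50, 0.45, 2.00), 0.03, 0.5,
               c(left_wrist = 0.9, left_elbow = 0.5)),
           mov("right_hand", c(-0.50, 0.45, 2.00), 0.03, 0.5,
               c(right_wrist = 0.9, right_elbow = 0.5))),
      bands = c(0.3, 0.4, 0.6, 1.4)),
    walking = spec("walking",
      list(mov("left_knee", c(0.14, 0.25, 1.70), 0.05, 1.0,
               c(left_ankle = 0.8, left_foot = 0.8))),
      bands = c(0.3, 0.4, 0.6, 1.4)),        # same profile as standing
    drinking = spec("drinking", hand_to_mouth, bands = c(0.3, 0.5, 1.5, 0.5)),
    eating   = spec("eating",   hand_to_mouth, bands = c(0.4, 1.5, 0.4, 0.6)),
    defecation = spec("defecation", head_move, bands = c(1.2, 0.4, 0.4, 1.2)),
    urination  = spec("urination",  head_move, bands = c(0.3, 1.2, 1.0, 1.2)),
    calling = spec("calling",
      list(mov("right_hand", c(-0.35, 0.45, 1.95), 0.12, 1.5,
               c(right_wrist = 0.9, right_elbow = 0.5))),
      bands = c(0.2, 0.3, 0.8, 1.6)),
    nothing = spec("nothing", list(), bands = c(0.5, 0.5, 0.5, 0.5))
  )
}

# Expand a 4-vector of band weights to the 8 x 4 per-channel profile using a
# fixed topographic gain pattern (alpha stronger occipitally, beta frontally,
# theta temporally).
expand_eeg_profile <- function(bands) {
  stopifnot(length(bands) == 4)
  gain <- matrix(1, 8, 4, dimnames = list(eeg_channels(),
                                          c("delta", "theta", "alpha", "beta")))
  gain[c("O1", "O2"), "alpha"] <- 1.3
  gain[c("F3", "F4"), "beta"]  <- 1.2
  gain[c("T5", "T6"), "theta"] <- 1.1
  sweep(gain, 2, bands, `*`)
}

#' Frequency band edges
#'
#' The four conventional EEG bands used throughout the package, in Hz:
#' delta 0.1-3, theta 4-7, alpha 8-12, beta 12-30.
#' @return Named list of `c(low, high)` pairs.
#' @export
eeg_bands <- function() {
  list(delta = c(0.1, 3), theta = c(4, 7), alpha = c(8, 12), beta = c(12, 30))
}

#' Default per-class record counts
#'
#' The dataset composition the generator reproduces: 1800 records over the
#' nine classes.
#' @return Named integer vector summing to 1800.
#' @export
default_class_counts <- function() {
  c(sleeping = 192L, standing = 198L, walking = 202L, drinking = 208L,
    eating = 193L, defecation = 207L, urination = 215L, calling = 185L,
    nothing = 200L)
}

#' Generator configuration
#'
#' @param class_counts Named integer vector, records per class. Defaults to
#'   the study composition ([default_class_counts()], 1800 records).
#' @param skeleton_rate Skeleton frame rate, frames/s.
#' @param eeg_rate EEG sampling rate, samples/s (must be at least 64 to
#'   resolve the beta band).
#' @param noise_sd Noise scale. Interpreted as the per-coordinate Gaussian
#'   noise s.d. in metres on the skeleton stream and, scaled by 250, as the
#'   white-noise s.d. in microvolts on the EEG stream. The preset names
#'   `"none"`, `"moderate"`, `"high"` map to 0, 0.02 and 0.05.
#' @param seed Integer seed making the generated dataset reproducible.
#' @return A `generator_config` object.
#' @export
generator_config <- function(class_counts = default_class_counts(),
                             skeleton_rate = 30, eeg_rate = 250,
                             noise_sd = "moderate", seed = 1L) {
  if (is.character(noise_sd)) {
    noise_sd <- switch(match.arg(noise_sd, c("none", "moderate", "high")),
                       none = 0, moderate = 0.02, high = 0.05)
  }
  stopifnot(skeleton_rate > 0, eeg_rate > 0, noise_sd >= 0,
            all(class_counts >= 0), !is.null(names(class_counts)))
  unknown <- setdiff(names(class_counts), names(activity_classes()))
  if (length(unknown))
    stop("unknown class label(s) in class_counts: ",
         paste(unknown, collapse = ", "))
  structure(list(class_counts = class_counts, skeleton_rate = skeleton_rate,
                 eeg_rate = eeg_rate, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Reduced-scale generator configuration
#'
#' The default composition divided by `factor` (rounded), keeping the class
#' proportions; used for desk-scale evaluation sweeps.
#' @param factor Scale divisor (default 10, giving 181 records).
#' @param ... Passed to [generator_config()].
#' @export
scaled_config <- function(factor = 10, ...) {
  counts <- pmax(1L, as.integer(round(default_class_counts() / factor)))
  names(counts) <- names(default_class_counts())
  generator_config(class_counts = counts, ...)
}

#' Generate one skeleton stream for an activity class
#'
#' Emits `floor(duration * rate)` frames. Every class starts from the fixed
#' seated resting posture; each movement in the class's motion motif
#' displaces its target joint toward the movement's target point (linear
#' reach over the first 0.5 s, then hold) with a sinusoidal oscillation of
#' the motif's amplitude and frequency along the displacement direction;
#' follower joints move a fixed fraction of the same displacement.
#' Independent Gaussian noise of s.d. `noise_sd` metres is added to every
#' coordinate.
#'
#' @param spec An `activity_class_spec`.
#' @param duration Seconds, > 0.
#' @param rate Frames per second, > 0.
#' @param noise_sd Coordinate noise s.d. in metres.
#' @param seed Optional integer seed.
#' @return A [skeleton_sequence()].
#' @export
generate_skeleton_stream <- function(spec, duration, rate, noise_sd = 0,
                                     seed = NULL) {
  stopifnot(duration > 0, rate > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  rest <- resting_posture()
  for (m in spec$motion_motif) {
    bad <- setdiff(c(m$joint, names(m$followers)), rownames(rest))
    if (length(bad))
      stop("unknown joint name in motif: ", paste(bad, collapse = ", "))
  }
  nf <- floor(duration * rate)
  t <- (seq_len(nf) - 1) / rate
  xyz <- array(rep(rest, each = nf), dim = c(nf, 20, 3),
               dimnames = list(NULL, rownames(rest), colnames(rest)))
  reach <- pmin(1, t / 0.5)               # linear reach, hold at target
  for (m in spec$motion_motif) {
    d <- m$target - rest[m$joint, ]
    nd <- sqrt(sum(d^2))
    u <- if (nd > 0) d / nd else c(0, 0, 0)
    osc <- m$amplitude * sin(2 * pi * m$freq * t)
    frac <- c(stats::setNames(1, m$joint), m$followers)
    for (j in names(frac)) {
      disp <- outer(reach, d * frac[[j]]) + outer(osc * frac[[j]], u)
      xyz[, j, ] <- xyz[, j, ] + disp
    }
  }
  if (noise_sd > 0)
    xyz <- xyz + array(stats::rnorm(length(xyz), sd = noise_sd), dim = dim(xyz))
  skeleton_sequence(t, xyz)
}

#' Generate one EEG stream for an activity class
#'
#' Each of the 8 channels is a sum over the four bands of three random
#' in-band sinusoids (uniform frequencies inside the band, uniform phases),
#' with per-sinusoid amplitude `10 * w / sqrt(3)` microvolts for profile
#' weight `w`, so a weight of 1 gives the band the RMS power of a single
#' 10-microvolt sinusoid. White Gaussian noise of s.d. `250 * noise_sd`
#' microvolts is added.
#'
#' @inheritParams generate_skeleton_stream
#' @param rate Samples per second; at least 64 so the beta band (up to
#'   30 Hz) is resolvable.
#' @return An [eeg_record()].
#' @export
generate_eeg_stream <- function(spec, duration, rate, noise_sd = 0,
                                seed = NULL) {
  stopifnot(duration > 0)
  if (rate < 64) stop("eeg_rate must be at least 64 samples/s")
  if (!is.null(seed)) set.seed(seed)
  ns <- floor(duration * rate)
  t <- (seq_len(ns) - 1) / rate
  bands <- eeg_bands()
  prof <- spec$eeg_profile
  sig <- matrix(0, ns, 8, dimnames = list(NULL, eeg_channels()))
  for (ch in seq_len(8)) {
    for (b in seq_along(bands)) {
      w <- prof[ch, b]
      if (w <= 0) next
      # floor at 0.5 Hz so every sinusoid completes a cycle within the
      # 2-3 s records and band power is estimable
      f <- stats::runif(3, max(bands[[b]][1], 0.5), bands[[b]][2])
      ph <- stats::runif(3, 0, 2 * pi)
      amp <- 10 * w / sqrt(3)
      sig[, ch] <- sig[, ch] +
        amp * rowSums(sin(outer(t, 2 * pi * f) + rep(ph, each = ns)))
    }
  }
  if (noise_sd > 0)
    sig <- sig + matrix(stats::rnorm(length(sig), sd = 250 * noise_sd),
                        nrow = ns)
  eeg_record(t, sig, rate)
}

#' Generate a labelled shuffled dataset
#'
#' Generates exactly `config$class_counts[l]` synchronised skeleton+EEG
#' records for every class `l`, each with a duration drawn uniformly from the
#' class's duration range, then shuffles the record order. Deterministic for
#' a fixed `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A list of class `caresig_dataset`: each element has components
#'   `skeleton` ([skeleton_sequence()]), `eeg` ([eeg_record()]) and `label`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  classes <- activity_classes()
  labels <- rep(names(config$class_counts), times = config$class_counts)
  labels <- sample(labels)
  records <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    sp <- classes[[labels[i]]]
    dur <- stats::runif(1, sp$duration_range[1], sp$duration_range[2])
    records[[i]] <- list(
      skeleton = generate_skeleton_stream(sp, dur, config$skeleton_rate,
                                          config$noise_sd),
      eeg = generate_eeg_stream(sp, dur, config$eeg_rate, config$noise_sd),
      label = labels[i]
    )
  }
  structure(records, class = "caresig_dataset")
}

#' @export
print.caresig_dataset <- function(x, ...) {
  cat(sprintf("<caresig_dataset: %d records>\n", length(x)))
  print(table(dataset_labels(x)))
  invisible(x)
}

#' Labels of a dataset
#' @param dataset A `caresig_dataset`.
#' @return Character vector of record labels.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset, `[[`, character(1), "label")
}

#' Generate a continuous session recording
#'
#' Concatenates the activities of [generate_dataset()] in random order,
#' separated by "nothing" gaps, into one continuous pair of streams with
#' global timestamps. Gap records are explicit "nothing" records, so the
#' session's records tile the whole timeline; per-timepoint ground truth is
#' recoverable from the record intervals.
#'
#' @param config A [generator_config()]. Classes other than "nothing" give
#'   the activities; "nothing" counts are ignored (gaps supply the idle
#'   class).
#' @param gap Seconds of "nothing" between consecutive activities (also used
#'   as a leading gap).
#' @return A `session_recording`: list with `records` (each with `skeleton`,
#'   `eeg`, `label`, `start`, `end` in global seconds), `duration`, and
#'   `sync_marker` (a stored alignment offset, not applied as a correction).
#' @export
generate_continuous_session <- function(config, gap = 1) {
  stopifnot(inherits(config, "generator_config"), gap >= 0)
  set.seed(config$seed)
  classes <- activity_classes()
  counts <- config$class_counts[setdiff(names(config$class_counts), "nothing")]
  labels <- rep(names(counts), times = counts)
  if (length(labels)) labels <- sample(labels)
  nothing <- classes$nothing
  records <- list()
  t0 <- 0
  add <- function(records, sp, dur, t0) {
    rec <- list(
      skeleton = generate_skeleton_stream(sp, dur, config$skeleton_rate,
                                          config$noise_sd),
      eeg = generate_eeg_stream(sp, dur, config$eeg_rate, config$noise_sd),
      label = sp$label, start = t0, end = t0 + dur)
    rec$skeleton$t <- rec$skeleton$t + t0
    rec$eeg$t <- rec$eeg$t + t0
    c(records, list(rec))
  }
  if (gap > 0) {
    records <- add(records, nothing, gap, t0)
    t0 <- t0 + gap
  }
  for (i in seq_along(labels)) {
    sp <- classes[[labels[i]]]
    dur <- stats::runif(1, sp$duration_range[1], sp$duration_range[2])
    records <- add(records, sp, dur, t0)
    t0 <- t0 + dur
    if (gap > 0 && i < length(labels)) {
      records <- add(records, nothing, gap, t0)
      t0 <- t0 + gap
    }
  }
  if (!length(records)) records <- add(records, nothing, max(gap, 2), 0)
  structure(list(records = records,
                 duration = records[[length(records)]]$end,
                 sync_marker = 0),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  acts <- sum(vapply(x$records, function(r) r$label != "nothing", logical(1)))
  cat(sprintf("<session_recording: %.1f s, %d activities (+gaps)>\n",
              x$duration, acts))
  invisible(x)
}

#' Ground-truth label at a time point
#'
#' @param session A `session_recording`.
#' @param time Seconds (vectorised).
#' @return Character vector: the label of the record whose `[start, end)`
#'   interval covers each time ("nothing" outside all records).
#' @export
session_label_at <- function(session, time) {
  vapply(time, function(tt) {
    for (r in session$records)
      if (tt >= r$start && tt < r$end) return(r$label)
    "nothing"
  }, character(1))
}
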