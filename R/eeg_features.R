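#' Band-pass decomposition of an EEG record
#'
#' Splits every channel into the four conventional bands ([eeg_bands()]):
#' delta 0.1-3 Hz, theta 4-7 Hz, alpha 8-12 Hz, beta 12-30 Hz. Filtering is
#' zero-phase (forward-backward) with 4-pole Butterworth band-passes; the
#' delta band is realised as a 0.1 Hz high-pass followed by a 3 Hz low-pass
#' because a band-pass with a 0.1 Hz edge is numerically fragile at these
#' sampling rates. Band edges are taken verbatim, so alpha and beta share
#' the 12 Hz edge and the 3-4 Hz gap below theta is left uncovered.
#'
#' @param rec An [eeg_record()] with rate at least 64 samples/s and at least
#'   1 s of signal.
#' @return Numeric array `[sample, channel, band]` (8 channels x 4 bands),
#'   class `band_decomposition`.
#' @export
bandpass_decompose <- function(rec) {
  stopifnot(inherits(rec, "eeg_record"))
  if (rec$rate < 64) stop("sampling rate must be at least 64 samples/s")
  ns <- nrow(rec$signals)
  if (ns < rec$rate) stop("need at least 1 s of signal")
  nyq <- rec$rate / 2
  bands <- eeg_bands()
  out <- array(0, c(ns, 8, length(bands)),
               dimnames = list(NULL, eeg_channels(), names(bands)))
  lp3 <- signal::butter(4, 3 / nyq, type = "low")
  hp01 <- signal::butter(2, 0.1 / nyq, type = "high")
  filts <- lapply(bands[-1], function(b)
    signal::butter(2, b / nyq, type = "pass"))
  for (ch in seq_len(8)) {
    x <- rec$signals[, ch]
    out[, ch, 1] <- signal::filtfilt(lp3, signal::filtfilt(hp01, x))
    for (b in 2:4)
      out[, ch, b] <- signal::filtfilt(filts[[b - 1]], x)
  }
  class(out) <- c("band_decomposition", class(out))
  out
}

# 80-d mental feature layout from a band decomposition plus the raw signals.
# Instantaneous power = squared band signal. Channel-major ordering:
#   [1:32]  mean power per (channel, band) over the whole record
#   [33:64] variance of power per (channel, band) over the whole record
#   [65:80] per channel: broadband mean power and power variance over the
#           middle of the three record divisions
mental_features_from_bands <- function(bandarr, raw) {
  ns <- dim(bandarr)[1]
  p <- bandarr^2
  means <- apply(p, c(2, 3), mean)                      # 8 x 4
  vars <- apply(p, c(2, 3), stats::var)
  mid <- segment_record(ns, 3)[[2]]
  braw <- raw[mid, , drop = FALSE]^2
  v <- c(as.vector(t(means)), as.vector(t(vars)),
         as.vector(rbind(colMeans(braw), apply(braw, 2, stats::var))))
  stopifnot(length(v) == 80, all(is.finite(v)))
  v
}

#' Extract the 80-dimensional mental feature vector
#'
#' Band-power statistics of an EEG record: for every channel and band, the
#' mean and variance of instantaneous power (the squared band-limited
#' signal) over the whole record (64 values), plus each channel's broadband
#' mean power and power variance over the middle of a three-way record
#' division (16 values) — the same division rule as the motion features
#' ([segment_record()]). Values are raw (microvolts squared); dataset-level
#' min-max scaling is applied separately.
#'
#' @param rec An [eeg_record()] with at least 3 samples per channel and at
#'   least 1 s of signal.
#' @param scaler Optional [fit_feature_scaler()] result; if supplied the
#'   vector is scaled and clipped to \[0,1\].
#' @return Numeric vector of length 80.
#' @export
extract_mental_features <- function(rec, scaler = NULL) {
  stopifnot(inherits(rec, "eeg_record"))
  if (nrow(rec$signals) < 3) stop("need at least 3 samples")
  v <- mental_features_from_bands(bandpass_decompose(rec), rec$signals)
  if (!is.null(scaler)) v <- as.vector(apply_feature_scaler(rbind(v), scaler))
  v
}

#' Mental feature matrix for a dataset
#'
#' @param dataset A `caresig_dataset`.
#' @return Numeric matrix, one 80-dimensional raw row per record.
#' @export
mental_feature_matrix <- function(dataset) {
  t(vapply(dataset, function(r) extract_mental_features(r$eeg), numeric(80)))
}
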