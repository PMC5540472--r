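#' Slice a continuous session into labelled frames
#'
#' Sliding windows of `frame_length` seconds hopping by
#' `frame_length * shift_fraction`, starting at 0 and kept fully inside the
#' session. Each frame is labelled by the activity covering the majority
#' (more than half) of its span; if no activity does, the frame is
#' "nothing"; an exact 50/50 tie between two activities goes to the earlier
#' one.
#'
#' @param session A `session_recording`.
#' @param frame_length Window length in seconds (default 3).
#' @param shift_fraction Hop as a fraction of the window (default 0.5).
#' @return A `caresig_dataset` of framed records (skeleton + EEG + label),
#'   with the window start times in attribute `starts`.
#' @export
frame_session <- function(session, frame_length = 3, shift_fraction = 0.5) {
  stopifnot(inherits(session, "session_recording"),
            frame_length > 0, shift_fraction > 0, shift_fraction <= 1)
  if (session$duration < frame_length)
    stop("session shorter than one frame")
  step <- frame_length * shift_fraction
  n_win <- floor((session$duration - frame_length) / step + 1e-9) + 1
  starts <- (seq_len(n_win) - 1) * step
  activities <- Filter(function(r) r$label != "nothing", session$records)
  records <- lapply(starts, function(s) {
    e <- s + frame_length
    lab <- frame_label(activities, s, e, frame_length)
    sk_t <- numeric(0)
    sk_rows <- list()
    ee_t <- numeric(0)
    ee_rows <- list()
    for (r in session$records) {
      ki <- which(r$skeleton$t >= s - 1e-9 & r$skeleton$t < e - 1e-9)
      if (length(ki)) {
        sk_t <- c(sk_t, r$skeleton$t[ki])
        sk_rows <- c(sk_rows, list(r$skeleton$xyz[ki, , , drop = FALSE]))
      }
      ei <- which(r$eeg$t >= s - 1e-9 & r$eeg$t < e - 1e-9)
      if (length(ei)) {
        ee_t <- c(ee_t, r$eeg$t[ei])
        ee_rows <- c(ee_rows, list(r$eeg$signals[ei, , drop = FALSE]))
      }
    }
    xyz <- do.call(abind_frames, sk_rows)
    rate <- session$records[[1]]$eeg$rate
    list(skeleton = skeleton_sequence(sk_t - s, xyz),
         eeg = eeg_record(ee_t - s, do.call(rbind, ee_rows), rate),
         label = lab)
  })
  structure(records, class = "caresig_dataset", starts = starts)
}

abind_frames <- function(...) {
  parts <- list(...)
  nf <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(NA_real_, c(nf, dim(parts[[1]])[2], 3),
               dimnames = dimnames(parts[[1]]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

frame_label <- function(activities, s, e, len, tol = 1e-9) {
  if (!length(activities)) return("nothing")
  ov <- vapply(activities, function(r)
    max(0, min(r$end, e) - max(r$start, s)), numeric(1))
  m <- max(ov)
  if (m > len / 2 + tol) {
    return(activities[[which(ov >= m - tol)[1]]]$label)   # earliest on tie
  }
  if (abs(m - len / 2) <= tol && sum(ov >= m - tol) >= 2) {
    return(activities[[which(ov >= m - tol)[1]]]$label)   # exact 50/50 tie
  }
  "nothing"
}

#' Confusion matrix and P / R / F1 report
#'
#' Builds the k x k confusion matrix (rows: truth, columns: prediction) and
#' derives: `A_g`, the correctly distinguished count (trace); `A_n`, the
#' misrecognition count (off-diagonal sum); `N_g`, the count of "nothing"
#' records recognised as an activity (tallied for reporting, used in no
#' formula); accuracy `P = 100 * A_g / (A_g + A_n)`; recall `R`, the
#' macro-average of per-class recalls x100 (classes absent from the truth
#' are skipped); and `F1 = 2PR / (P + R)`.
#'
#' @param predictions,truth Label vectors of equal length.
#' @param classes Optional class order; defaults to taxonomy order.
#' @param nothing_label Label of the idle class (for `N_g`).
#' @return An `eval_report` with fields `confusion`, `A_g`, `A_n`, `N_g`,
#'   `P`, `R`, `F1`.
#' @export
compute_metrics <- function(predictions, truth, classes = NULL,
                            nothing_label = "nothing") {
  if (length(predictions) != length(truth) || !length(truth))
    stop("predictions and truth must be nonempty and of equal length")
  if (is.null(classes)) classes <- canonical_classes(c(truth, predictions))
  confusion <- table(factor(truth, classes), factor(predictions, classes),
                     dnn = c("truth", "predicted"))
  A_g <- sum(diag(confusion))
  A_n <- sum(confusion) - A_g
  P <- 100 * A_g / (A_g + A_n)
  per_class <- diag(confusion) / rowSums(confusion)
  R <- 100 * mean(per_class[rowSums(confusion) > 0])
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  N_g <- sum(truth == nothing_label & predictions != nothing_label)
  structure(list(confusion = confusion, A_g = A_g, A_n = A_n, N_g = N_g,
                 P = P, R = R, F1 = F1),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Accuracy P = %.1f%%  macro recall R = %.1f%%  F1 = %.1f\n",
              x$P, x$R, x$F1))
  cat(sprintf("A_g = %d  A_n = %d  N_g = %d\n", x$A_g, x$A_n, x$N_g))
  print(x$confusion)
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Splits records into `k_folds` stratified folds (per-class fold counts
#' within one of each other), trains with `builder` on each training split
#' and evaluates on the held-out split. `builder` receives the training
#' record indices and must return a prediction function mapping test record
#' indices to predicted labels; all fitting — scalers, pretraining,
#' fine-tuning — must happen inside `builder`, so no information leaks from
#' held-out folds.
#'
#' @param labels Record labels (defines stratification and truth).
#' @param builder `function(train_idx) -> function(test_idx) -> labels`.
#' @param k_folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param classes Optional class order for the reports.
#' @return List with `folds` (per-fold `eval_report`s), `pooled` (report
#'   over all held-out predictions), `assignments` (fold id per record) and
#'   `predictions`.
#' @export
cross_validate <- function(labels, builder, k_folds = 10, seed = 1L,
                           classes = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  tab <- table(labels)
  if (any(tab < k_folds))
    stop("every class needs at least k_folds records; short: ",
         paste(names(tab)[tab < k_folds], collapse = ", "))
  if (is.null(classes)) classes <- canonical_classes(labels)
  set.seed(seed)
  fold <- integer(n)
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k_folds), length(idx))
  }
  predictions <- character(n)
  folds <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    train <- which(fold != f)
    test <- which(fold == f)
    predict_fun <- builder(train)
    predictions[test] <- predict_fun(test)
    folds[[f]] <- compute_metrics(predictions[test], labels[test], classes)
  }
  list(folds = folds,
       pooled = compute_metrics(predictions, labels, classes),
       assignments = fold, predictions = predictions)
}

#' Cross-validation builder for the SAE classifier
#'
#' Captures raw (unscaled) feature matrices and labels; each training call
#' fits scalers and the full two-stage model on the training rows only.
#'
#' @param motion,mental Raw feature matrices for all records.
#' @param labels All record labels.
#' @param architecture,sparsity,control Passed to [caresig()].
#' @return A builder suitable for [cross_validate()].
#' @export
caresig_builder <- function(motion, mental, labels,
                            architecture = "late_fusion",
                            sparsity = sparsity_config(),
                            control = train_control()) {
  force(motion); force(mental); force(labels)
  function(train_idx) {
    fit <- caresig(motion[train_idx, , drop = FALSE],
                   mental[train_idx, , drop = FALSE],
                   labels[train_idx], architecture = architecture,
                   sparsity = sparsity, control = control)
    function(test_idx)
      predict(fit, motion[test_idx, , drop = FALSE],
              mental[test_idx, , drop = FALSE])
  }
}

#' Cross-validation builder for the DTW baseline
#'
#' 1-nearest-neighbour over [dtw_distance()] with every training record as a
#' template, on the per-frame motion descriptor series
#' ([record_series()]).
#'
#' @param series List of per-record series (matrices).
#' @param labels All record labels.
#' @param classes Optional tie-break class order.
#' @return A builder suitable for [cross_validate()].
#' @export
dtw_builder <- function(series, labels, classes = NULL) {
  force(series); force(labels)
  if (is.null(classes)) classes <- canonical_classes(labels)
  function(train_idx) {
    templates <- series[train_idx]
    tlabels <- labels[train_idx]
    function(test_idx)
      vapply(series[test_idx], dtw_classify, character(1),
             templates = templates, labels = tlabels, classes = classes)
  }
}

#' Evaluate a fitted model on a continuous session
#'
#' Frames the session ([frame_session()]), extracts features per frame,
#' predicts with the model and scores against the frame labels.
#'
#' @param model A fitted `caresig` model.
#' @param session A `session_recording`.
#' @param frame_length,shift_fraction Framing parameters.
#' @return An `eval_report`.
#' @export
evaluate_session <- function(model, session, frame_length = 3,
                             shift_fraction = 0.5) {
  frames <- frame_session(session, frame_length, shift_fraction)
  motion <- motion_feature_matrix(frames)
  mental <- mental_feature_matrix(frames)
  compute_metrics(predict(model, motion, mental), dataset_labels(frames),
                  classes = model$classes)
}
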