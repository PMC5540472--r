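#' Write a dataset to a two-file-per-record CSV layout
#'
#' Each record `i` becomes `<id>_skel.csv` (columns `t` then
#' `<joint>_x,<joint>_y,<joint>_z` for the 20 joints) and `<id>_eeg.csv`
#' (columns `t`, `F3`..`O2`); a `manifest.csv` lists `id,label,start,end`.
#'
#' @param dataset A `caresig_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("rec%04d", seq_along(dataset))
  for (i in seq_along(dataset)) {
    rec <- dataset[[i]]
    utils::write.csv(skeleton_to_frame(rec$skeleton),
                     file.path(dir, paste0(ids[i], "_skel.csv")),
                     row.names = FALSE)
    utils::write.csv(eeg_to_frame(rec$eeg),
                     file.path(dir, paste0(ids[i], "_eeg.csv")),
                     row.names = FALSE)
  }
  manifest <- data.frame(
    id = ids,
    label = dataset_labels(dataset),
    start = vapply(dataset, function(r) r$skeleton$t[1], numeric(1)),
    end = vapply(dataset, function(r) {
      n <- length(r$skeleton$t)
      r$skeleton$t[n] + (r$skeleton$t[n] - r$skeleton$t[1]) / max(1, n - 1)
    }, numeric(1)))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.csv` and the per-record CSVs.
#' @param eeg_rate Sampling rate to stamp on the EEG records; if `NULL` it is
#'   inferred from the median timestamp step.
#' @return A `caresig_dataset`.
#' @export
read_dataset <- function(dir, eeg_rate = NULL) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$id[i]
    sk <- utils::read.csv(file.path(dir, paste0(id, "_skel.csv")))
    ee <- utils::read.csv(file.path(dir, paste0(id, "_eeg.csv")))
    rate <- eeg_rate
    if (is.null(rate)) rate <- 1 / stats::median(diff(ee$t))
    list(skeleton = frame_to_skeleton(sk),
         eeg = eeg_record(ee$t, as.matrix(ee[, eeg_channels()]), rate),
         label = manifest$label[i])
  })
  structure(records, class = "caresig_dataset")
}

#' Write a continuous session to CSV
#'
#' Concatenates all records (activities and gaps) into `session_skel.csv` and
#' `session_eeg.csv` with global timestamps, plus an `intervals.csv` of
#' `label,start,end` ground-truth intervals and the stored sync offset in
#' `sync.csv`.
#'
#' @param session A `session_recording`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sk <- do.call(rbind, lapply(session$records,
                              function(r) skeleton_to_frame(r$skeleton)))
  ee <- do.call(rbind, lapply(session$records,
                              function(r) eeg_to_frame(r$eeg)))
  utils::write.csv(sk, file.path(dir, "session_skel.csv"), row.names = FALSE)
  utils::write.csv(ee, file.path(dir, "session_eeg.csv"), row.names = FALSE)
  iv <- data.frame(label = vapply(session$records, `[[`, character(1), "label"),
                   start = vapply(session$records, `[[`, numeric(1), "start"),
                   end = vapply(session$records, `[[`, numeric(1), "end"))
  utils::write.csv(iv, file.path(dir, "intervals.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sync_marker = session$sync_marker),
                   file.path(dir, "sync.csv"), row.names = FALSE)
  invisible(dir)
}

skeleton_to_frame <- function(seq) {
  joints <- kinect_joints()
  out <- data.frame(t = seq$t)
  for (j in joints)
    for (k in 1:3)
      out[[paste0(j, "_", c("x", "y", "z")[k])]] <- seq$xyz[, j, k]
  out
}

frame_to_skeleton <- function(df) {
  joints <- kinect_joints()
  nf <- nrow(df)
  xyz <- array(NA_real_, c(nf, 20, 3),
               dimnames = list(NULL, joints, c("x", "y", "z")))
  for (j in joints)
    for (k in 1:3)
      xyz[, j, k] <- df[[paste0(j, "_", c("x", "y", "z")[k])]]
  skeleton_sequence(df$t, xyz)
}

eeg_to_frame <- function(rec) {
  cbind(data.frame(t = rec$t), as.data.frame(rec$signals))
}
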