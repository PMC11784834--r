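#' Canonical 62-channel extended 10-20 montage labels
#'
#' The electrode order used by 62-channel emotion-EEG recordings
#' (FP1 ... CB2, frontal to occipital, left to right within a row).
#'
#' @return Character vector of 62 electrode labels.
#' @export
#' @examples
#' head(eeg_channels_62())
eeg_channels_62 <- function() {
  c("FP1", "FPZ", "FP2",
    "AF3", "AF4",
    "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
    "CB1", "O1", "OZ", "O2", "CB2")
}

#' Construct a raw EEG recording
#'
#' Bundles a channels-by-time sample matrix (microvolts) with its channel
#' labels, sampling rate and emotion label. This is the entry point of the
#' featurization pipeline.
#'
#' @param samples Numeric matrix, channels x time points, in microvolts.
#' @param channel_labels Character vector naming the rows of `samples`;
#'   defaults to the 62-channel extended 10-20 montage.
#' @param fs Sampling rate in Hz (positive).
#' @param label Integer emotion class index (0-based), or `NA`.
#' @param subject,session Identifiers carried through featurization.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, channel_labels = NULL, fs = 200,
                          label = NA_integer_, subject = 1L, session = 1L) {
  samples <- as.matrix(samples)
  if (is.null(channel_labels)) {
    channel_labels <- if (nrow(samples) == 62L) eeg_channels_62() else
      paste0("CH", seq_len(nrow(samples)))
  }
  if (nrow(samples) != length(channel_labels))
    stop("raw_recording: row count of samples (", nrow(samples),
         ") must equal the number of channel labels (", length(channel_labels), ")")
  if (anyDuplicated(channel_labels))
    stop("raw_recording: channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("raw_recording: sampling rate must be a positive scalar")
  if (!all(is.finite(samples)))
    stop("raw_recording: non-finite sample values (data-integrity error)")
  structure(list(samples = samples,
                 channel_labels = as.character(channel_labels),
                 fs = fs, label = label,
                 subject = subject, session = session),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.2f s), label=%s, subject=%s\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, format(x$label), format(x$subject)))
  invisible(x)
}

#' Segment a recording into fixed-length non-overlapping windows
#'
#' Splits a recording into contiguous `window_s`-second windows (4 s by
#' default). Each segment inherits the recording's label, subject and
#' session; a trailing partial window is discarded.
#'
#' @param rec A [raw_recording()].
#' @param window_s Window length in seconds (> 0).
#' @return A list of `raw_recording` segments; empty if the recording is
#'   shorter than one window.
#' @export
#' @examples
#' rec <- raw_recording(matrix(rnorm(62 * 1600), 62), fs = 200, label = 0L)
#' length(segment_recording(rec))  # floor(8 s / 4 s) = 2
segment_recording <- function(rec, window_s = 4) {
  stopifnot(inherits(rec, "raw_recording"), window_s > 0)
  if (ncol(rec$samples) == 0L) stop("segment_recording: empty recording")
  if (!all(is.finite(rec$samples)))
    stop("segment_recording: non-finite sample values (data-integrity error)")
  n_win <- ncol(rec$samples) %/% round(window_s * rec$fs)
  len <- round(window_s * rec$fs)
  if (n_win < 1L) return(list())
  lapply(seq_len(n_win), function(i) {
    seg <- rec
    seg$samples <- rec$samples[, ((i - 1L) * len + 1L):(i * len), drop = FALSE]
    seg
  })
}

#' Read a plain-text array-archive of EEG trials
#'
#' Reads a directory in which each trial is stored as `<name>.tsv` (a
#' channels x time matrix, tab-separated, no header) alongside a
#' `<name>.json` sidecar holding at least `fs` and `label`, and optionally
#' `subject`, `session` and `channel_labels`.
#'
#' @param dir Directory containing `.tsv`/`.json` trial pairs.
#' @return List of [raw_recording()] objects, sorted by file name.
#' @export
read_array_archive <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  lapply(files, function(f) {
    meta_file <- sub("\\.tsv$", ".json", f)
    if (!file.exists(meta_file))
      stop("read_array_archive: missing sidecar ", basename(meta_file))
    meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
    x <- as.matrix(utils::read.table(f, sep = "\t", header = FALSE))
    dimnames(x) <- NULL
    raw_recording(x,
                  channel_labels = meta$channel_labels,
                  fs = meta$fs,
                  label = as.integer(meta$label),
                  subject = if (!is.null(meta$subject)) meta$subject else 1L,
                  session = if (!is.null(meta$session)) meta$session else 1L)
  })
}

#' Write recordings as a plain-text array-archive
#'
#' Inverse of [read_array_archive()]; used by the command-line `simulate`
#' step to hand synthetic data to `featurize`.
#'
#' @param recs List of [raw_recording()] objects.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_array_archive <- function(recs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    stem <- file.path(dir, sprintf("trial%05d", i))
    utils::write.table(rec$samples, paste0(stem, ".tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(list(fs = rec$fs, label = rec$label,
                              subject = rec$subject, session = rec$session,
                              channel_labels = rec$channel_labels),
                         paste0(stem, ".json"), auto_unbox = TRUE)
  }
  invisible(dir)
}
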