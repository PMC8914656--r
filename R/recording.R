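#' Multichannel EEG recording
#'
#' A timestamped sample matrix in microvolts with channel labels and a
#' sampling rate.  The headband montage has six channels (Fp1, Fp2, C3, C4,
#' O1, O2, common reference on the mastoids), but any label set is accepted.
#'
#' @param data Numeric matrix, samples in rows, channels in columns (a bare
#'   vector is treated as one channel).  Values are microvolts.
#' @param fs Sampling rate in Sa/s.
#' @param channels Character vector of unique channel labels, one per
#'   column.
#' @param provenance Character vector logging the processing steps applied.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs,
                          channels = colnames(data),
                          provenance = character()) {
  data <- as.matrix(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(data)))
  channels <- as.character(channels)
  if (length(channels) != ncol(data))
    stop("eeg_recording: one channel label per column required")
  if (anyDuplicated(channels))
    stop("eeg_recording: channel labels must be unique")
  if (any(!is.finite(data)))
    stop("eeg_recording: data must be finite (no NaN/NA)")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("eeg_recording: fs must be a single positive number")
  colnames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels,
                 provenance = as.character(provenance)),
            class = "eeg_recording")
}

#' Montage labels of the headband
#' @return The six channel labels in board order.
#' @export
headband_channels <- function() c("Fp1", "Fp2", "C3", "C4", "O1", "O2")

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples x %d channels, %g Sa/s (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  if (length(x$provenance))
    cat("  steps   :", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An [eeg_recording()].
#' @export
recording_duration <- function(rec) nrow(rec$data) / rec$fs

# internal: append a provenance entry
log_step <- function(rec, step) {
  rec$provenance <- c(rec$provenance, step)
  rec
}
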