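# The six-channel sEMG recording container.

#' Create a six-channel sEMG recording
#'
#' @param samples Numeric matrix, 6 rows (channels, canonical order
#'   [MN_CHANNELS]) by N columns (samples), or N x 6 (transposed on input).
#' @param fs Sampling rate in Hz (default 2000).
#' @param channel_labels Channel labels; must equal [MN_CHANNELS].
#' @param subject_id,sentence_id,group_label,stage_label Optional metadata.
#' @return An object of class `semg_recording`.
#' @export
semg_recording <- function(samples, fs = 2000,
                           channel_labels = MN_CHANNELS,
                           subject_id = NA_character_,
                           sentence_id = NA_integer_,
                           group_label = NA_character_,
                           stage_label = NA_character_) {
  samples <- as.matrix(samples)
  if (nrow(samples) != 6L && ncol(samples) == 6L) samples <- t(samples)
  if (nrow(samples) != 6L) {
    abort(sprintf("expected 6 channels, got %d.", min(dim(samples))))
  }
  if (!identical(as.character(channel_labels), MN_CHANNELS)) {
    abort(paste0("channel labels must be, in order: ",
                 paste(MN_CHANNELS, collapse = ", ")))
  }
  if (!is.numeric(fs) || fs <= 0) abort("`fs` must be a positive sampling rate in Hz.")
  if (!all(is.finite(samples))) abort("recording contains non-finite values.")
  if (ncol(samples) < fs) {
    abort(sprintf("recording must span at least 1 s (%d samples at %g Hz).", as.integer(fs), fs))
  }
  rownames(samples) <- MN_CHANNELS
  structure(
    list(samples = samples, fs = fs, channel_labels = MN_CHANNELS,
         subject_id = subject_id, sentence_id = sentence_id,
         group_label = group_label, stage_label = stage_label),
    class = "semg_recording"
  )
}

as_semg_recording <- function(x) {
  if (inherits(x, "semg_recording")) return(x)
  semg_recording(x)
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf(
    "<semg_recording> 6 x %d samples @ %g Hz (%.2f s)\n  subject: %s  sentence: %s  group: %s\n",
    ncol(x$samples), x$fs, ncol(x$samples) / x$fs,
    x$subject_id, x$sentence_id, x$group_label
  ))
  invisible(x)
}

#' Convert a recording to a long tibble
#'
#' @param x A `semg_recording`.
#' @param ... Unused.
#' @return Tibble with columns `time`, `channel`, `value`.
#' @export
as_tibble.semg_recording <- function(x, ...) {
  n <- ncol(x$samples)
  tibble::tibble(
    time = rep(seq_len(n) / x$fs, each = 6L),
    channel = factor(rep(MN_CHANNELS, n), levels = MN_CHANNELS),
    value = as.vector(x$samples)
  )
}
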