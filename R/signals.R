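# Containers for raw input signals and encoded feature matrices.

#' Construct an EEG epoch
#'
#' @param samples numeric vector, microvolts.
#' @param fs sampling rate, Hz.
#' @param stage_label optional sleep stage, one of "wake", "light", "deep".
#' @return an object of class `fibrc_eeg_epoch`.
#' @export
eeg_epoch <- function(samples, fs, stage_label = NULL) {
  if (!is.numeric(samples) || any(!is.finite(samples))) stop_input("EEG samples must be finite numeric")
  if (!is.null(stage_label) && !stage_label %in% c("wake", "light", "deep"))
    stop_input("stage_label must be one of wake/light/deep")
  structure(list(samples = as.numeric(samples), fs = fs, stage_label = stage_label),
            class = "fibrc_eeg_epoch")
}

#' Construct an audio clip
#'
#' @param samples numeric vector in [-1, 1].
#' @param fs sampling rate, Hz (>= 8000).
#' @param snore_label optional logical snore annotation.
#' @return an object of class `fibrc_audio_clip`.
#' @export
audio_clip <- function(samples, fs, snore_label = NULL) {
  if (!is.numeric(samples) || any(!is.finite(samples))) stop_input("audio samples must be finite numeric")
  if (fs < 8000) stop_input("audio sampling rate must be >= 8000 Hz")
  if (length(samples) && max(abs(samples)) > 1 + 1e-9) stop_input("audio samples must lie in [-1, 1]")
  structure(list(samples = as.numeric(samples), fs = fs, snore_label = snore_label),
            class = "fibrc_audio_clip")
}

#' Construct a feature matrix
#'
#' @param values numeric matrix.
#' @param kind one of "MTF", "MFCC", "IMAGE".
#' @param meta optional list of source metadata (stage, snore flag, window).
#' @return an object of class `fibrc_feature_matrix`.
#' @export
feature_matrix <- function(values, kind = c("MTF", "MFCC", "IMAGE"), meta = list()) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || any(!is.finite(values))) stop_input("feature values must be a finite matrix")
  if (kind == "MTF" && (min(values) < -1e-12 || max(values) > 1 + 1e-12))
    stop_input("MTF entries must lie in [0, 1]")
  structure(list(values = values, kind = kind, meta = meta), class = "fibrc_feature_matrix")
}

#' @export
print.fibrc_feature_matrix <- function(x, ...) {
  cat(sprintf("<%s feature matrix: %d x %d>\n", x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
print.fibrc_eeg_epoch <- function(x, ...) {
  cat(sprintf("<EEG epoch: %d samples @ %g Hz (%.1f s)%s>\n", length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (is.null(x$stage_label)) "" else paste0(", stage=", x$stage_label)))
  invisible(x)
}

#' @export
print.fibrc_audio_clip <- function(x, ...) {
  cat(sprintf("<audio clip: %d samples @ %g Hz (%.1f s)%s>\n", length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (is.null(x$snore_label)) "" else paste0(", snore=", x$snore_label)))
  invisible(x)
}
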