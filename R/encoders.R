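# Feature encoders: Markov transition fields for EEG, MFCCs for audio,
# threshold pulse maps for images, and the feature-matrix -> pulse-train
# mapping that feeds the reservoir.

#' Markov transition field of an EEG epoch
#'
#' Quantile-bins the series into `n_bins` states, estimates the first-order
#' Markov transition matrix W by transition counting with row normalisation,
#' expands it to the full MTF `M[i, j] = W[q(x_i), q(x_j)]`, and block-averages
#' M down to `out_size` x `out_size`. Rows of W for bins the series never
#' leaves from are set uniform (1/n_bins). A constant series (a single
#' occupied bin) degenerates to the uniform matrix, with a warning.
#'
#' Because binning is by quantiles, the MTF is invariant under strictly
#' monotone transformations of the series.
#'
#' @param epoch a `fibrc_eeg_epoch` or numeric vector.
#' @param n_bins number of quantile bins (>= 2; default 8).
#' @param out_size output side length (default 64).
#' @return a `fibrc_feature_matrix` of kind "MTF" with entries in [0, 1].
#' @export
mtf_transform <- function(epoch, n_bins = 8, out_size = 64) {
  x <- if (inherits(epoch, "fibrc_eeg_epoch")) epoch$samples else as.numeric(epoch)
  if (n_bins < 2) stop_config("n_bins must be >= 2")
  n <- length(x)
  if (n < n_bins) stop_input("epoch shorter than n_bins")
  q <- .quantile_bins(x, n_bins)
  W <- matrix(0, n_bins, n_bins)
  if (length(unique(q)) == 1L) {
    warning("constant series: returning the uniform MTF")
    W[] <- 1 / n_bins
  } else {
    tab <- table(factor(q[-n], levels = 1:n_bins), factor(q[-1], levels = 1:n_bins))
    W <- matrix(as.numeric(tab), n_bins, n_bins)
    rs <- rowSums(W)
    W[rs == 0, ] <- 1 / n_bins
    W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  M <- W[q, q, drop = FALSE]   # full n x n MTF
  M <- block_average(M, out_size, out_size)
  meta <- if (inherits(epoch, "fibrc_eeg_epoch")) list(stage = epoch$stage_label, fs = epoch$fs) else list()
  meta$transitions <- W        # the estimated n_bins x n_bins Markov matrix
  meta$bins <- q
  feature_matrix(M, "MTF", meta)
}

# quantile bin assignment: breaks at the 1/n..(n-1)/n quantiles; ties on a
# break go to the lower bin
.quantile_bins <- function(x, n_bins) {
  br <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1), names = FALSE)
  br <- br[-c(1, n_bins + 1)]
  1L + findInterval(x, unique(br), left.open = TRUE)  # collapsed breaks merge bins
}

#' Mel-frequency cepstral coefficients of an audio clip
#'
#' Per-frame pipeline: pre-emphasis, Hann window, magnitude spectrum, HTK
#' mel triangular filterbank, log with a fixed floor, orthonormal DCT-II;
#' the first `n_mfcc` coefficients of each frame form one column.
#'
#' @param clip a `fibrc_audio_clip` or numeric vector (then `fs` required).
#' @param n_mfcc number of cepstral coefficients kept (default 13).
#' @param frame_len frame length, seconds (default 0.025).
#' @param hop hop between frames, seconds (default 0.010).
#' @param n_mels number of mel filters (default 26).
#' @param fs sampling rate when `clip` is a bare vector.
#' @param preemph pre-emphasis coefficient (default 0.97).
#' @param log_floor floor applied before the log (default 1e-10).
#' @param fmax upper filterbank edge, Hz (default fs/2).
#' @return a `fibrc_feature_matrix` of kind "MFCC", `n_mfcc` x `n_frames`.
#' @export
mfcc_transform <- function(clip, n_mfcc = 13, frame_len = 0.025, hop = 0.010,
                           n_mels = 26, fs = NULL, preemph = 0.97,
                           log_floor = 1e-10, fmax = NULL) {
  if (inherits(clip, "fibrc_audio_clip")) { x <- clip$samples; fs <- clip$fs }
  else { x <- as.numeric(clip); if (is.null(fs)) stop_config("fs required for a bare vector") }
  fmax <- fmax %||% (fs / 2)
  if (fmax > fs / 2) stop_config("filterbank upper edge exceeds Nyquist for this sampling rate")
  flen <- round(frame_len * fs); fhop <- round(hop * fs)
  if (length(x) < flen) stop_input("clip too short for one frame")
  n_frames <- floor((length(x) - flen) / fhop) + 1L
  xe <- c(x[1], x[-1] - preemph * x[-length(x)])
  starts <- (seq_len(n_frames) - 1L) * fhop
  frames <- vapply(starts, function(s) xe[(s + 1):(s + flen)], numeric(flen))
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(flen) - 1) / (flen - 1))  # Hann
  frames <- frames * win
  nfft <- 2^ceiling(log2(flen))
  padded <- rbind(frames, matrix(0, nfft - flen, n_frames))
  spec <- abs(stats::mvfft(padded))[1:(nfft / 2 + 1), , drop = FALSE]
  fb <- mel_filterbank(n_mels, nfft, fs, fmax = fmax)
  melspec <- fb %*% spec
  logmel <- log(pmax(melspec, log_floor))
  D <- .dct2_matrix(n_mels)[1:n_mfcc, , drop = FALSE]
  cc <- D %*% logmel
  meta <- if (inherits(clip, "fibrc_audio_clip")) list(snore = clip$snore_label, fs = fs) else list(fs = fs)
  feature_matrix(unname(cc), "MFCC", meta)
}

#' HTK-style mel triangular filterbank
#'
#' @param n_mels number of filters.
#' @param nfft FFT length; the filterbank has `nfft/2 + 1` columns.
#' @param fs sampling rate, Hz.
#' @param fmin,fmax filterbank edges, Hz.
#' @return `n_mels` x `(nfft/2 + 1)` matrix of triangular weights.
#' @export
mel_filterbank <- function(n_mels, nfft, fs, fmin = 0, fmax = fs / 2) {
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  mels <- seq(hz2mel(fmin), hz2mel(fmax), length.out = n_mels + 2)
  edges <- mel2hz(mels)
  freqs <- (0:(nfft / 2)) * fs / nfft
  fb <- matrix(0, n_mels, length(freqs))
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (freqs - lo) / (ce - lo)
    dn <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

#' Centre frequencies of the mel filterbank, Hz
#' @inheritParams mel_filterbank
#' @export
mel_centers <- function(n_mels, fs, fmin = 0, fmax = fs / 2) {
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  mel2hz(seq(hz2mel(fmin), hz2mel(fmax), length.out = n_mels + 2))[2:(n_mels + 1)]
}

# orthonormal DCT-II matrix (n x n)
.dct2_matrix <- function(n) {
  k <- 0:(n - 1)
  D <- sqrt(2 / n) * cos(pi / n * outer(k, k + 0.5))
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

#' Encode an image as a binary pulse map
#'
#' Every pixel above `threshold` becomes a fixed-voltage write pulse
#' (1.5 V, 200 ms by default); pixels at or below threshold are unstimulated
#' slots of equal width. Each image row becomes one pulse train, row-major
#' pixel order preserved.
#'
#' @param image numeric matrix of pixel intensities.
#' @param threshold intensity threshold (default 0.5 for binary images).
#' @param v_write pulse amplitude, volts (default 1.5).
#' @param slot_duration,slot_gap slot width and gap, seconds.
#' @return list with `mask` (binary matrix) and `rows` (list of
#'   `fibrc_pulse_train`, one per image row).
#' @export
image_to_pulsemap <- function(image, threshold = 0.5, v_write = 1.5,
                              slot_duration = 0.2, slot_gap = 0.05) {
  if (!is.matrix(image) || length(image) == 0) stop_input("image must be a non-empty matrix")
  if (any(!is.finite(image))) stop_input("image intensities must be finite")
  mask <- (image > threshold) * 1L
  rows <- lapply(seq_len(nrow(mask)), function(i)
    pulse_train(mask[i, ] * v_write, slot_duration, slot_gap))
  list(mask = mask, rows = rows)
}

#' Map a feature matrix to per-row pulse trains
#'
#' Each matrix row becomes an independent pulse train, segmented into frames
#' of `frame_k` slots (zero-padded on the right when `frame_k` does not
#' divide the column count). In `"binary"` mode, entries above the row median
#' become write pulses at `v_write`; in `"amplitude"` mode each row is
#' min-max rescaled into [0, v_write] and used directly as pulse amplitudes
#' (an all-equal row maps to all-zero amplitudes).
#'
#' @param fm a `fibrc_feature_matrix` or numeric matrix.
#' @param mode "binary" or "amplitude".
#' @param frame_k slots per reservoir frame (default 4).
#' @param v_write write amplitude, volts.
#' @param slot_duration,slot_gap slot width and gap, seconds.
#' @return list of `fibrc_pulse_train`, one per row; each has
#'   `ceiling(n_cols / frame_k) * frame_k` slots.
#' @export
matrix_to_pulserows <- function(fm, mode = c("amplitude", "binary"), frame_k = 4,
                                v_write = 1.5, slot_duration = 0.2, slot_gap = 0.05) {
  mode <- match.arg(mode)
  m <- if (inherits(fm, "fibrc_feature_matrix")) fm$values else fm
  if (!is.matrix(m)) stop_input("fm must be a matrix or feature_matrix")
  n_cols <- ncol(m)
  pad <- (frame_k - n_cols %% frame_k) %% frame_k
  lapply(seq_len(nrow(m)), function(i) {
    row <- m[i, ]
    amps <- if (mode == "binary") {
      (row > stats::median(row)) * v_write
    } else {
      rng <- range(row)
      if (diff(rng) == 0) rep(0, n_cols)
      else (row - rng[1]) / diff(rng) * v_write
    }
    pulse_train(c(amps, rep(0, pad)), slot_duration, slot_gap)
  })
}
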