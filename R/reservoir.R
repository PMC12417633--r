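# The virtual reservoir: banks of devices driven frame-wise by encoded pulse
# rows. Every frame of frame_k slots programs a fresh device from the common
# baseline (the physical bank of 16 discrete conductance states); the current
# read after the frame's last slot is one component of the state vector.

#' Reservoir configuration
#'
#' @param frame_k pulses per device frame (default 4, i.e. 16 levels).
#' @param device_params a `fibrc_device_params`; slot timing is taken from it.
#' @param mode pulse mapping mode used by encoders, "binary" or "amplitude".
#' @return an object of class `fibrc_reservoir_config`.
#' @export
reservoir_config <- function(frame_k = 4, device_params = fibrc::device_params(),
                             mode = c("amplitude", "binary")) {
  mode <- match.arg(mode)
  if (frame_k < 1) stop_config("frame_k must be >= 1")
  structure(list(frame_k = as.integer(frame_k), device_params = device_params, mode = mode),
            class = "fibrc_reservoir_config")
}

#' @export
print.fibrc_reservoir_config <- function(x, ...) {
  cat(sprintf("<reservoir config: frame_k=%d, mode=%s, slot %g s + %g s gap>\n",
              x$frame_k, x$mode, x$device_params$slot_duration, x$device_params$slot_gap))
  invisible(x)
}

#' Drive the reservoir with per-row pulse trains
#'
#' Each row train is cut into frames of `frame_k` slots; each frame drives a
#' device freshly initialised at baseline, and the current read after the
#' frame's last slot (after its trailing gap) becomes one state component.
#' Components are ordered row-major by (row, frame). The hot path is a
#' vectorised slot recurrence over all frames at once; it is exactly
#' equivalent to composing `apply_pulse` per device.
#'
#' @param rows list of `fibrc_pulse_train` (empty rows are skipped with a
#'   warning) or a numeric amplitude matrix (one row per train).
#' @param cfg a `fibrc_reservoir_config`.
#' @param modality character tag stored on the result ("eeg", "audio", ...).
#' @return an object of class `fibrc_state_vector`: numeric `currents` with
#'   attributes `layout = c(n_rows, n_frames)` and `modality`.
#' @export
run_reservoir <- function(rows, cfg = reservoir_config(), modality = "generic") {
  if (is.matrix(rows)) rows <- lapply(seq_len(nrow(rows)), function(i)
    pulse_train(rows[i, ], cfg$device_params$slot_duration, cfg$device_params$slot_gap))
  if (length(rows) == 0) stop_input("rows must be non-empty")
  keep <- vapply(rows, function(r) length(r) > 0, logical(1))
  if (!all(keep)) {
    warning(sum(!keep), " empty row(s) skipped")
    rows <- rows[keep]
    if (length(rows) == 0) stop_input("all rows empty")
  }
  k <- cfg$frame_k
  params <- cfg$device_params
  n_slots <- vapply(rows, length, integer(1))
  if (length(unique(n_slots)) != 1L)
    stop_input("all rows must have the same slot count (pad with matrix_to_pulserows)")
  durs <- unique(unlist(lapply(rows, `[[`, "duration")))
  gaps <- unique(unlist(lapply(rows, `[[`, "gap_after")))
  if (length(durs) != 1L || length(gaps) != 1L)
    stop_input("the vectorised reservoir requires uniform slot timing across all pulses")
  slot_duration <- durs; slot_gap <- gaps
  decay <- exp(-slot_gap / params$tau_decay)
  n_cols <- n_slots[1]
  pad <- (k - n_cols %% k) %% k
  amp <- do.call(rbind, lapply(rows, function(r) c(r$amplitude, rep(0, pad))))
  n_frames <- ncol(amp) / k
  n_rows <- nrow(amp)
  # frames as rows of a (n_rows*n_frames) x k matrix, row-major by (row, frame)
  fr <- matrix(NA_real_, n_rows * n_frames, k)
  for (j in seq_len(k))
    fr[, j] <- as.vector(t(amp[, seq(j, ncol(amp), by = k), drop = FALSE]))
  w <- rep(params$w_min, nrow(fr))
  energy <- numeric(nrow(fr))
  noise <- NULL
  if (params$sigma_c2c > 0) {
    noise <- with_seed(params$seed,
      matrix(exp(stats::rnorm(length(fr), 0, params$sigma_c2c)), nrow(fr), k))
  }
  for (j in seq_len(k)) {
    a <- fr[, j]
    set_mask <- a >= params$v_set
    reset_mask <- a <= params$v_reset
    if (any(set_mask)) {
      dw <- params$a_write * (params$w_max - w[set_mask])
      if (!is.null(noise)) dw <- dw * noise[set_mask, j]
      w[set_mask] <- pmin(w[set_mask] + dw, params$w_max)
    }
    if (any(reset_mask)) w[reset_mask] <- params$w_min
    energy <- energy + abs(a) * .current_of_w(w, params) * slot_duration
    w <- params$w_min + (w - params$w_min) * decay
  }
  currents <- .current_of_w(w, params)
  out <- state_vector(currents, layout = c(n_rows, n_frames), modality = modality)
  attr(out, "frame_energy") <- energy
  attr(out, "frame_duration") <- k * (slot_duration + slot_gap)
  out
}

#' Construct a reservoir state vector
#'
#' @param currents numeric vector of read currents, amperes.
#' @param layout integer pair (n_rows, n_frames); the row-major grid shape.
#' @param modality character tag ("eeg", "audio", ...).
#' @export
state_vector <- function(currents, layout = c(length(currents), 1L), modality = "generic") {
  if (prod(layout) != length(currents)) stop_input("layout does not match current count")
  structure(as.numeric(currents), layout = as.integer(layout), modality = modality,
            class = "fibrc_state_vector")
}

#' @export
print.fibrc_state_vector <- function(x, ...) {
  ly <- attr(x, "layout")
  cat(sprintf("<reservoir state vector [%s]: %d x %d grid, currents %.3g..%.3g A>\n",
              attr(x, "modality"), ly[1], ly[2],
              if (length(x)) min(x) else NA, if (length(x)) max(x) else NA))
  invisible(x)
}

#' Reshape a state vector to its (n_rows, n_frames) grid
#' @param s a `fibrc_state_vector`.
#' @export
state_grid <- function(s) {
  ly <- attr(s, "layout")
  matrix(unclass(s), nrow = ly[1], ncol = ly[2], byrow = TRUE)
}

#' Fuse two modality state vectors into one feature vector
#'
#' Each modality is z-normalised (its own mean and s.d.) before
#' concatenation, EEG first, so that neither modality's current scale
#' dominates the readout. The raw sub-vectors are retained so the fusion is
#' losslessly invertible with [unfuse_modalities()].
#'
#' @param s_eeg,s_audio `fibrc_state_vector`s from the same time window.
#'   If one is empty (length 0) the other is returned unchanged.
#' @param check_window if TRUE, error when both carry a `window` attribute
#'   and the windows differ.
#' @return a fused `fibrc_state_vector` of length `|s_eeg| + |s_audio|`.
#' @export
fuse_modalities <- function(s_eeg, s_audio, check_window = TRUE) {
  if (length(s_audio) == 0) return(s_eeg)
  if (length(s_eeg) == 0) return(s_audio)
  w1 <- attr(s_eeg, "window"); w2 <- attr(s_audio, "window")
  if (check_window && !is.null(w1) && !is.null(w2) && !identical(w1, w2))
    stop_input("cannot fuse state vectors from different time windows")
  z <- function(v) {
    if (length(v) < 2) return(v * 0)
    s <- stats::sd(v)
    if (s == 0) v * 0 else (v - mean(v)) / s
  }
  fused <- c(z(unclass(s_eeg)), z(unclass(s_audio)))
  out <- structure(fused,
            layout = c(1L, length(fused)), modality = "fused",
            raw_eeg = unclass(s_eeg), raw_audio = unclass(s_audio),
            layout_eeg = attr(s_eeg, "layout"), layout_audio = attr(s_audio, "layout"),
            class = "fibrc_state_vector")
  e1 <- attr(s_eeg, "frame_energy"); e2 <- attr(s_audio, "frame_energy")
  if (!is.null(e1) && !is.null(e2)) {
    attr(out, "frame_energy") <- c(e1, e2)
    d1 <- attr(s_eeg, "frame_duration"); d2 <- attr(s_audio, "frame_duration")
    attr(out, "frame_duration") <-
      (d1 * length(s_eeg) + d2 * length(s_audio)) / (length(s_eeg) + length(s_audio))
  }
  out
}

#' Recover the raw per-modality vectors from a fused vector
#' @param fused a vector produced by [fuse_modalities()].
#' @return list with `eeg` and `audio` state vectors (pre-normalisation).
#' @export
unfuse_modalities <- function(fused) {
  if (is.null(attr(fused, "raw_eeg"))) stop_input("not a fused state vector")
  list(eeg = state_vector(attr(fused, "raw_eeg"), attr(fused, "layout_eeg"), "eeg"),
       audio = state_vector(attr(fused, "raw_audio"), attr(fused, "layout_audio"), "audio"))
}

#' Compress an image through the reservoir and reconstruct it
#'
#' The thresholded image is encoded row-wise into binary pulse trains; each
#' frame of `frame_k` pixels programs one device, so the compressed
#' representation is the `n_rows x n_frames` grid of read currents
#' (compression ratio `frame_k : 1` along columns). Reconstruction decodes
#' each current to the nearest programmed level of the noiseless 16-level
#' bank (ties broken toward the lower level) and expands the level's bit
#' pattern back into `frame_k` pixels; with `sigma_c2c = 0` and an injective
#' level map the round trip is exact.
#'
#' @param image numeric or binary matrix.
#' @param cfg a `fibrc_reservoir_config`.
#' @param threshold binarisation threshold (default 0.5).
#' @return list with `compressed` (current grid), `reconstruction` (binary
#'   matrix of the image's size) and `levels` (the frame -> current table).
#' @export
compress_image <- function(image, cfg = reservoir_config(mode = "binary"), threshold = 0.5) {
  pm <- image_to_pulsemap(image, threshold, v_write = cfg$device_params$v_write,
                          slot_duration = cfg$device_params$slot_duration,
                          slot_gap = cfg$device_params$slot_gap)
  s <- run_reservoir(pm$rows, cfg, modality = "image")
  grid <- state_grid(s)
  # noiseless decode table for this frame length
  noiseless <- cfg$device_params; noiseless$sigma_c2c <- 0
  lev <- enumerate_levels(cfg$frame_k, noiseless)
  lev_cur <- lev$table$current
  lev_bits <- do.call(rbind, lapply(lev$table$frame, function(f) as.integer(strsplit(f, "")[[1]])))
  ord <- order(lev_cur)   # decode in ascending current order; ties -> lower level
  lev_cur_s <- lev_cur[ord]; lev_bits_s <- lev_bits[ord, , drop = FALSE]
  decode1 <- function(cur) {
    d <- abs(lev_cur_s - cur)
    lev_bits_s[which.min(d), ]   # which.min takes the first (lower) on ties
  }
  rec <- matrix(0L, nrow(grid), nrow(lev_bits_s) * 0 + ncol(grid) * cfg$frame_k)
  for (i in seq_len(nrow(grid)))
    rec[i, ] <- as.integer(unlist(lapply(grid[i, ], decode1)))
  rec <- rec[, seq_len(ncol(pm$mask)), drop = FALSE]  # drop padding columns
  list(compressed = grid, reconstruction = rec, levels = lev$table)
}
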