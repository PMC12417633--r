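# Plain-format I/O: CSV EEG traces, 16-bit PCM mono WAV, PGM images,
# feature/state CSVs. The WAV and PGM codecs are written out here because
# no reader for these formats ships with the installed stack; both cover
# only the minimal profile the package emits (PCM 16-bit mono; P2/P5 PGM).

#' Read an EEG trace from CSV (`time_s,uv`)
#'
#' @param path CSV file with columns `time_s` and `uv`.
#' @param stage_label optional stage annotation.
#' @return a `fibrc_eeg_epoch`; the sampling rate is inferred from the
#'   median time step.
#' @export
read_eeg_csv <- function(path, stage_label = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "uv") %in% names(d))) stop_input("expected columns time_s, uv")
  fs <- 1 / stats::median(diff(d$time_s))
  eeg_epoch(d$uv, round(fs), stage_label)
}

#' Write an EEG epoch to CSV (`time_s,uv`)
#' @param epoch a `fibrc_eeg_epoch`.
#' @param path output path.
#' @export
write_eeg_csv <- function(epoch, path) {
  n <- length(epoch$samples)
  utils::write.csv(data.frame(time_s = (seq_len(n) - 1) / epoch$fs, uv = epoch$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#' @param path WAV path.
#' @return a `fibrc_audio_clip` with samples scaled to [-1, 1].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4))
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- rawToChar(readBin(con, "raw", 4))
  if (riff != "RIFF" || wave != "WAVE") stop_input("not a RIFF/WAVE file")
  fs <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readBin(con, "raw", 4)
    if (length(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    tag <- rawToChar(id)
    if (tag == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      channels <- fmt[2]
      fs <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "raw", 6))
      bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (tag == "data") {
      samples <- readBin(con, "integer", sz / 2, 2, endian = "little", signed = TRUE)
      break
    } else invisible(readBin(con, "raw", sz))
  }
  if (is.null(samples)) stop_input("no data chunk found")
  if (bits != 16 || channels != 1) stop_input("only 16-bit PCM mono WAV is supported")
  audio_clip(samples / 32768, fs)
}

#' Write an audio clip as 16-bit PCM mono WAV
#' @param clip a `fibrc_audio_clip`.
#' @param path output path.
#' @export
write_wav <- function(clip, path) {
  x <- as.integer(round(pmax(-1, pmin(1, clip$samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_sz <- 2L * length(x)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_sz, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")            # PCM, mono
  writeBin(as.integer(clip$fs), con, size = 4, endian = "little")
  writeBin(as.integer(clip$fs) * 2L, con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")           # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_sz, con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a PGM image (P2 ASCII or P5 binary)
#' @param path PGM path.
#' @return numeric matrix of intensities in [0, 1].
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- rawToChar(readBin(con, "raw", 1))
      if (ch == "#") { repeat { c2 <- rawToChar(readBin(con, "raw", 1)); if (c2 == "\n") break } ; next }
      if (grepl("[[:space:]]", ch)) { if (nzchar(tok)) return(tok) } else tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop_input("not a P2/P5 PGM file")
  w <- as.integer(read_token()); h <- as.integer(read_token()); mx <- as.integer(read_token())
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", w * h))
  } else {
    out <- integer(w * h)
    for (i in seq_len(w * h)) out[i] <- as.integer(read_token())
    out
  }
  matrix(vals / mx, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a matrix as an ASCII PGM (P2) image
#' @param m numeric matrix in [0, 1].
#' @param path output path.
#' @param maxval grey levels (default 255).
#' @export
write_pgm <- function(m, path, maxval = 255) {
  v <- round(pmin(pmax(m, 0), 1) * maxval)
  lines <- c("P2", paste(ncol(m), nrow(m)), as.character(maxval),
             apply(v, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Write a feature matrix to CSV with a metadata header line
#' @param fm a `fibrc_feature_matrix`.
#' @param path output path.
#' @export
write_feature_csv <- function(fm, path) {
  hdr <- sprintf("# kind=%s nrow=%d ncol=%d", fm$kind, nrow(fm$values), ncol(fm$values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(fm$values, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_csv()]
#' @param path CSV path.
#' @export
read_feature_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  kind <- sub(".*kind=([A-Z]+).*", "\\1", hdr)
  m <- as.matrix(utils::read.csv(path, skip = 1, header = FALSE))
  dimnames(m) <- NULL
  feature_matrix(m, kind)
}

#' Write reservoir state vectors to CSV (one row per window)
#'
#' Metadata columns (window index, modality, label) precede the currents; a
#' sidecar JSON records the grid layout.
#'
#' @param states list of `fibrc_state_vector`s.
#' @param path output CSV path; the sidecar is `<path>.layout.json`.
#' @param labels optional per-state labels.
#' @export
write_states_csv <- function(states, path, labels = NULL) {
  X <- do.call(rbind, lapply(states, as.numeric))
  meta <- data.frame(window = seq_along(states),
                     modality = vapply(states, function(s) attr(s, "modality") %||% "generic", character(1)))
  if (!is.null(labels)) meta$label <- labels
  utils::write.csv(cbind(meta, as.data.frame(X)), path, row.names = FALSE)
  ly <- attr(states[[1]], "layout")
  jsonlite::write_json(list(n_rows = ly[1], n_frames = ly[2]),
                       paste0(path, ".layout.json"), auto_unbox = TRUE)
  invisible(path)
}
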