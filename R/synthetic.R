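# Synthetic data generators: stage-dependent EEG, snore audio with ambient
# noise, whole-night streams, and binary glyph images. All generators are
# pure functions of (parameters, seed). The spectral structure is a
# synthetic design choice, not a fit to any recording: deep sleep is
# delta-dominated, light sleep carries spindle bursts, wake is
# alpha/beta-dominated -- the qualitative ordering clinical EEG shows.

#' Stage-dependent EEG band-power specification
#'
#' Relative amplitude weights for the rhythmic components the generator
#' emulates: slow-wave delta, theta, alpha, beta, and bursty sleep spindles,
#' plus a broadband white-noise floor. Each component is a narrowband
#' Gaussian process centred in its clinical band (`band_edges`); the narrow
#' bandwidth gives each rhythm a coherence time of several seconds, which is
#' what makes the stage signature visible to transition-field imaging.
#' Defaults are synthetic design constants: wake is low-amplitude and
#' alpha/beta dominated, light sleep is spindle-burst dominated, deep sleep
#' is dominated by the ~1 Hz slow oscillation; delta weight is ordered
#' deep > light > wake.
#'
#' @param wake,light,deep named numeric vectors of band weights
#'   (delta, theta, alpha, beta, spindle).
#' @param noise_floor white-noise amplitude weight.
#' @param amp_uv overall scale: target epoch standard deviation, microvolts.
#' @param band_edges named list of (low, high) Hz edges for each component.
#' @param spindle_rate mean spindle-burst rate, bursts per second.
#' @param spindle_burst_s spindle burst duration, seconds.
#' @return an object of class `fibrc_stage_spec`.
#' @export
stage_spec <- function(
    wake  = c(delta = 0.1, theta = 0.2, alpha = 1.5, beta = 0.8, spindle = 0.0),
    light = c(delta = 0.7, theta = 1.2, alpha = 0.2, beta = 0.1, spindle = 1.6),
    deep  = c(delta = 5.0, theta = 0.2, alpha = 0.05, beta = 0.02, spindle = 0.02),
    noise_floor = 0.15, amp_uv = 15,
    band_edges = list(delta = c(0.85, 1.1), theta = c(5, 6), alpha = c(9.5, 10.5),
                      beta = c(19, 21), spindle = c(13, 14)),
    spindle_rate = 0.3, spindle_burst_s = 1.5) {
  bands <- c("delta", "theta", "alpha", "beta", "spindle")
  for (w in list(wake, light, deep))
    if (!all(bands %in% names(w)) || any(w < 0)) stop_config("stage weights must be non-negative and named delta/theta/alpha/beta/spindle")
  if (!(deep["delta"] > light["delta"] && light["delta"] > wake["delta"]))
    stop_config("delta weights must be ordered deep > light > wake")
  structure(list(wake = wake, light = light, deep = deep,
                 noise_floor = noise_floor, amp_uv = amp_uv,
                 band_edges = band_edges, spindle_rate = spindle_rate,
                 spindle_burst_s = spindle_burst_s),
            class = "fibrc_stage_spec")
}

# unit-variance band-limited Gaussian noise via FFT masking
.band_noise <- function(n, fs, lo, hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) * fs / n
  keep <- abs(f) >= lo & abs(f) <= hi
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) y else y / s
}

#' Generate one synthetic EEG epoch
#'
#' Sum of band-limited Gaussian processes with stage-specific amplitude
#' weights plus a white-noise floor; spindle-band activity is gated by a
#' burst envelope (~1 s raised-cosine bursts) rather than continuous. The
#' epoch is scaled to the stage specification's target standard deviation (default 15 uV,
#' i.e. excursions of roughly +/-50 uV).
#'
#' @param stage "wake", "light" or "deep".
#' @param fs sampling rate, Hz (>= 64).
#' @param epoch_s epoch length, seconds (default 30, clinical convention).
#' @param spec a `fibrc_stage_spec`.
#' @param seed integer seed; the generator is deterministic per seed.
#' @return a `fibrc_eeg_epoch` with `stage_label = stage`.
#' @export
gen_eeg_epoch <- function(stage, fs = 128, epoch_s = 30, spec = stage_spec(), seed = 1L) {
  if (fs < 64) stop_config("fs must be >= 64 Hz")
  stage <- match.arg(stage, c("wake", "light", "deep"))
  w <- spec[[stage]]
  n <- round(fs * epoch_s)
  x <- with_seed(seed, {
    acc <- spec$noise_floor * stats::rnorm(n)
    for (b in names(spec$band_edges)) {
      if (w[[b]] == 0) next
      e <- spec$band_edges[[b]]
      comp <- .band_noise(n, fs, e[1], e[2])
      if (b == "spindle") comp <- comp * .burst_envelope(n, fs, rate_hz = spec$spindle_rate %||% 0.3,
                                                         burst_s = spec$spindle_burst_s %||% 1.0)
      acc <- acc + w[[b]] * comp
    }
    acc
  })
  denom <- sqrt(sum(w^2) + spec$noise_floor^2)
  eeg_epoch(x / denom * spec$amp_uv, fs, stage_label = stage)
}

# 0/1-ish envelope of raised-cosine bursts recurring quasi-periodically at
# 1/rate_hz intervals with +/-15% onset jitter (sleep spindles recur every
# few seconds rather than as a Poisson process); uses the current RNG
.burst_envelope <- function(n, fs, rate_hz, burst_s) {
  env <- numeric(n)
  dur <- n / fs
  period <- 1 / rate_hz
  start <- stats::runif(1, 0, period)
  if (start > dur - burst_s) return(env)
  base <- seq(start, dur - burst_s, by = period)
  onsets <- pmax(0, base + stats::runif(length(base), -0.15, 0.15) * period)
  bl <- round(burst_s * fs)
  shape <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = bl))
  for (o in onsets) {
    i0 <- round(o * fs) + 1L
    idx <- i0:min(i0 + bl - 1L, n)
    env[idx] <- pmax(env[idx], shape[seq_along(idx)])
  }
  env
}

#' Generate a synthetic snore / breathing audio clip
#'
#' With `snore = TRUE`: a train of inspiratory snore bursts at breathing rate
#' ~0.25 Hz; each burst is a 90-180 Hz fundamental with 4 harmonics under a
#' jittered amplitude-modulation envelope, over low-level breathing noise.
#' With `snore = FALSE`: broadband low-level breathing noise only (its
#' spectral centroid sits far above the snore fundamental band). The clip is
#' peak-normalised to 0.9.
#'
#' @param duration_s clip length, seconds.
#' @param fs sampling rate, Hz (>= 8000; default 16000).
#' @param snore logical: include snore bursts?
#' @param seed integer seed.
#' @param breath_rate_hz breathing rate (default 0.25 Hz).
#' @return a `fibrc_audio_clip` with `snore_label = snore`.
#' @export
gen_snore_clip <- function(duration_s, fs = 16000, snore = TRUE, seed = 1L,
                           breath_rate_hz = 0.25) {
  if (fs < 8000) stop_config("fs must be >= 8000 Hz")
  n <- round(duration_s * fs)
  x <- with_seed(seed, {
    base <- 0.02 * stats::rnorm(n)          # breathing noise floor
    if (snore) {
      t <- seq_len(n) / fs
      period <- 1 / breath_rate_hz
      first <- 0.35 * period
      onsets <- if (duration_s - 1.3 > first) seq(first, duration_s - 1.3, by = period) else numeric(0)
      onsets <- onsets + stats::runif(length(onsets), -0.15, 0.15)
      for (o in onsets) {
        f0 <- stats::runif(1, 90, 180)
        dur <- stats::runif(1, 0.8, 1.2)
        idx <- which(t >= o & t < o + dur)
        tt <- t[idx] - o
        env <- sin(pi * tt / dur)^2 * (1 + 0.3 * sin(2 * pi * stats::runif(1, 8, 14) * tt))
        burst <- 0
        for (h in 1:5)  # fundamental + 4 harmonics
          burst <- burst + (0.6^(h - 1)) * sin(2 * pi * h * f0 * tt + stats::runif(1, 0, 2 * pi))
        base[idx] <- base[idx] + env * burst
      }
    }
    base
  })
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak * 0.9
  audio_clip(x, fs, snore_label = snore)
}

#' Mix ambient background noise into an audio clip at a target SNR
#'
#' `"rain"` is pink-ish broadband noise (1/sqrt(f) spectral shaping);
#' `"traffic"` is a low-frequency rumble (< 120 Hz) with sparse slow swells
#' emulating vehicle passes; `"none"` returns the clip unchanged. The noise
#' is scaled so the full-clip signal-to-noise power ratio equals `snr_db`,
#' then the mix is peak-renormalised if it exceeds 1 (scaling signal and
#' noise together, preserving the SNR).
#'
#' @param clip a `fibrc_audio_clip`.
#' @param kind "rain", "traffic" or "none".
#' @param snr_db target signal-to-noise ratio, dB.
#' @param seed integer seed.
#' @return a `fibrc_audio_clip`.
#' @export
add_ambient <- function(clip, kind = c("rain", "traffic", "none"), snr_db = 10, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "none" || !is.finite(snr_db)) return(clip)
  n <- length(clip$samples)
  fs <- clip$fs
  noise <- with_seed(seed, {
    if (kind == "rain") {
      X <- stats::fft(stats::rnorm(n))
      f <- pmax(1, abs(c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1))) * fs / n)
      Re(stats::fft(X / sqrt(f), inverse = TRUE)) / n
    } else {
      rumble <- .band_noise(n, fs, 20, 120)
      swell <- .burst_envelope(n, fs, rate_hz = 0.1, burst_s = 3.0)
      rumble * (0.4 + swell)
    }
  })
  noise <- noise / stats::sd(noise)
  p_sig <- mean(clip$samples^2)
  noise <- noise * sqrt(p_sig / 10^(snr_db / 10))
  y <- clip$samples + noise
  peak <- max(abs(y))
  if (peak > 1) y <- y / peak
  audio_clip(y, fs, snore_label = clip$snore_label)
}

#' Night plan: stage Markov chain and snore schedule
#'
#' @param duration_s night length, seconds (default 600 s, the desk-scale
#'   default; full nights are just longer plans).
#' @param epoch_s epoch length, seconds (default 30).
#' @param transition row-stochastic 3x3 stage transition matrix
#'   (order wake, light, deep).
#' @param p_snore_light probability a light-sleep epoch contains snoring
#'   (snore events are concentrated in light sleep; never scheduled in wake).
#' @param p_snore_deep probability for deep-sleep epochs.
#' @param ambient "none", "rain" or "traffic".
#' @param snr_db ambient SNR, dB.
#' @param seed integer seed.
#' @return an object of class `fibrc_night_plan`.
#' @export
night_plan <- function(duration_s = 600, epoch_s = 30,
                       transition = matrix(c(0.80, 0.19, 0.01,
                                             0.10, 0.75, 0.15,
                                             0.02, 0.28, 0.70),
                                           3, 3, byrow = TRUE,
                                           dimnames = list(c("wake", "light", "deep"),
                                                           c("wake", "light", "deep"))),
                       p_snore_light = 0.4, p_snore_deep = 0.15,
                       ambient = "none", snr_db = 10, seed = 1L) {
  if (any(abs(rowSums(transition) - 1) > 1e-9) || any(transition < 0))
    stop_config("transition matrix rows must be non-negative and sum to 1")
  if (duration_s < epoch_s) stop_config("night shorter than one epoch")
  structure(list(duration_s = duration_s, epoch_s = epoch_s, transition = transition,
                 p_snore_light = p_snore_light, p_snore_deep = p_snore_deep,
                 ambient = ambient, snr_db = snr_db, seed = as.integer(seed)),
            class = "fibrc_night_plan")
}

#' Generate a labelled synthetic night
#'
#' Draws the stage sequence from the plan's Markov chain (started from
#' wake), schedules snore events in light/deep epochs only, and generates
#' epoch-aligned EEG and audio streams.
#'
#' @param plan a `fibrc_night_plan`.
#' @param fs_eeg,fs_audio sampling rates, Hz.
#' @param spec a `fibrc_stage_spec`.
#' @param signals if FALSE, only the label sequence is generated (fast; used
#'   for long-run statistics of the stage chain).
#' @return list with `labels` (data.frame: epoch, start_s, end_s, stage,
#'   snore), `eeg` (list of `fibrc_eeg_epoch`) and `audio` (list of
#'   `fibrc_audio_clip`), one element per epoch.
#' @export
gen_night <- function(plan, fs_eeg = 128, fs_audio = 16000, spec = stage_spec(),
                      signals = TRUE) {
  n_epochs <- floor(plan$duration_s / plan$epoch_s)
  stages <- character(n_epochs)
  snore <- logical(n_epochs)
  st_names <- rownames(plan$transition)
  with_seed(substream_seed(plan$seed, "night-labels"), {
    cur <- "wake"
    for (i in seq_len(n_epochs)) {
      stages[i] <- cur
      p <- if (cur == "light") plan$p_snore_light else if (cur == "deep") plan$p_snore_deep else 0
      snore[i] <- stats::runif(1) < p
      cur <- sample(st_names, 1, prob = plan$transition[cur, ])
    }
  })
  labels <- data.frame(epoch = seq_len(n_epochs),
                       start_s = (seq_len(n_epochs) - 1) * plan$epoch_s,
                       end_s = seq_len(n_epochs) * plan$epoch_s,
                       stage = stages, snore = snore)
  if (!signals) return(list(labels = labels, eeg = NULL, audio = NULL))
  eeg <- lapply(seq_len(n_epochs), function(i)
    gen_eeg_epoch(stages[i], fs_eeg, plan$epoch_s, spec,
                  seed = substream_seed(plan$seed, paste0("eeg-", i))))
  audio <- lapply(seq_len(n_epochs), function(i) {
    clip <- gen_snore_clip(plan$epoch_s, fs_audio, snore = snore[i],
                           seed = substream_seed(plan$seed, paste0("audio-", i)))
    if (plan$ambient != "none")
      clip <- add_ambient(clip, plan$ambient, plan$snr_db,
                          seed = substream_seed(plan$seed, paste0("ambient-", i)))
    clip
  })
  list(labels = labels, eeg = eeg, audio = audio)
}

# 8x8 stroke bitmaps for the default glyph set
.glyph_bitmaps <- list(
  W = matrix(as.integer(strsplit(paste0(
    "10000001","10000001","10000001","10011001",
    "10100101","11000011","11000011","10000001"), "")[[1]]), 8, 8, byrow = TRUE),
  G = matrix(as.integer(strsplit(paste0(
    "00111100","01000010","10000000","10000000",
    "10001110","10000010","01000010","00111100"), "")[[1]]), 8, 8, byrow = TRUE),
  `6` = matrix(as.integer(strsplit(paste0(
    "00011100","00100000","01000000","01111100",
    "01000010","01000010","01000010","00111100"), "")[[1]]), 8, 8, byrow = TRUE))

#' Generate binary glyph images
#'
#' Stroke-rendered binary glyphs for a configurable symbol set (defaults
#' "W", "G", "6"), optionally upscaled (nearest neighbour) and corrupted by
#' independent pixel-flip noise.
#'
#' @param symbols character vector of symbols; unknown symbols error.
#' @param size output side length (>= 8; default 8).
#' @param flip_p per-pixel flip probability (default 0).
#' @param seed integer seed (only used when `flip_p > 0`).
#' @return named list of binary `size` x `size` matrices.
#' @export
gen_glyphs <- function(symbols = c("W", "G", "6"), size = 8, flip_p = 0, seed = 1L) {
  if (size < 8) stop_config("size must be >= 8")
  unknown <- setdiff(symbols, names(.glyph_bitmaps))
  if (length(unknown)) stop_input("unknown glyph symbol(s): ", paste(unknown, collapse = ", "))
  out <- with_seed(seed, lapply(symbols, function(s) {
    g <- .glyph_bitmaps[[s]]
    if (size != 8) {
      idx <- ceiling(seq_len(size) * 8 / size)
      g <- g[idx, idx, drop = FALSE]
    }
    if (flip_p > 0) {
      flips <- matrix(stats::runif(size * size) < flip_p, size, size)
      g <- abs(g - flips * 1L)
    }
    g
  }))
  names(out) <- symbols
  out
}

#' Generate a random binary glyph (for round-trip testing)
#' @param size side length.
#' @param density probability a pixel is on.
#' @param seed integer seed.
#' @return binary `size` x `size` matrix.
#' @export
gen_random_glyph <- function(size = 8, density = 0.4, seed = 1L) {
  with_seed(seed, matrix((stats::runif(size * size) < density) * 1L, size, size))
}
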