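# Shared fixtures: tiny deterministic inputs built in code.

# two well-separated Gaussian clusters, linearly separable
toy_two_cluster <- function(n = 30, p = 5, gap = 4, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n * p), n, p), matrix(rnorm(n * p, gap), n, p))
    labeled_states(X, rep(c("a", "b"), each = n))
  })
}

# independent straight-line re-implementation of the device state recurrence
# (the oracle for apply_pulse compositions); returns final w
oracle_recurrence <- function(amplitudes, durations, gaps, params) {
  w <- params$w_min
  for (i in seq_along(amplitudes)) {
    if (amplitudes[i] >= params$v_set) {
      w <- w + params$a_write * (params$w_max - w)
      if (w > params$w_max) w <- params$w_max
    } else if (amplitudes[i] <= params$v_reset) {
      w <- params$w_min
    }
    w <- params$w_min + (w - params$w_min) * exp(-gaps[i] / params$tau_decay)
  }
  w
}

# band power of a series in [lo, hi] Hz via the periodogram
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  P <- Mod(fft(x - mean(x)))[1:(n %/% 2)]^2
  f <- (0:(n %/% 2 - 1)) * fs / n
  sum(P[f >= lo & f <= hi])
}

.fixture_cache <- new.env(parent = emptyenv())

# reservoir states for a small synthetic stage3 set (shared by readout tests;
# cached per (n, seed) since generation dominates test runtime)
small_stage3_states <- function(n_per_class = 12, seed = 7) {
  key <- paste0("s3-", n_per_class, "-", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  .fixture_cache[[key]] <- .small_stage3_states(n_per_class, seed)
  .fixture_cache[[key]]
}

.small_stage3_states <- function(n_per_class = 12, seed = 7) {
  rcfg <- reservoir_config()
  states <- list(); labs <- character(0)
  for (st in c("wake", "light", "deep")) for (i in seq_len(n_per_class)) {
    ep <- gen_eeg_epoch(st, seed = substream_seed(seed, paste0("fix-", st, "-", i)))
    states[[length(states) + 1L]] <- run_reservoir(
      matrix_to_pulserows(mtf_transform(ep)), rcfg, "eeg")
    labs <- c(labs, st)
  }
  labeled_states(states, labs, "stage3")
}
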