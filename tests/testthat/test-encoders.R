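# MTF, MFCC and pulse-map encoders.

test_that("MTF matches hand-counted transition frequencies on a small series", {
  x <- c(1, 3, 2, 5, 4, 6, 8, 7, 9, 10, 2, 1)   # 12-sample toy
  n_bins <- 2
  fm <- mtf_transform(x, n_bins, out_size = 12)
  # oracle: count transitions by hand between below/above-median halves
  med <- stats::median(x)
  q <- ifelse(x <= med, 1L, 2L)
  counts <- matrix(0, 2, 2)
  for (i in 1:11) counts[q[i], q[i + 1]] <- counts[q[i], q[i + 1]] + 1
  W <- counts / rowSums(counts)
  expect_equal(fm$meta$transitions, W, tolerance = 1e-12)
  # the full (non-averaged) MTF is W indexed by the bin sequence
  expect_equal(fm$values, W[q, q], tolerance = 1e-12)
})

test_that("a strictly increasing ramp only transitions within or to the next bin", {
  fm <- mtf_transform(seq_len(32), n_bins = 4, out_size = 32)
  W <- fm$meta$transitions
  for (i in 1:4) for (j in 1:4)
    if (j != i && j != i + 1) expect_identical(W[i, j], 0)
})

test_that("MTF transition rows sum to one and entries stay in [0,1] for random inputs", {
  withr::with_seed(3, {
    for (rep in 1:100) {
      x <- rnorm(60)
      fm <- mtf_transform(x, n_bins = 4, out_size = 16)
      expect_equal(rowSums(fm$meta$transitions), rep(1, 4), tolerance = 1e-9)
      expect_true(all(fm$values >= 0 & fm$values <= 1))
    }
  })
})

test_that("MTF is invariant under strictly monotone transformations", {
  withr::with_seed(4, x <- cumsum(rnorm(200)))
  x <- x / max(abs(x))            # keep exp() well-conditioned
  a <- mtf_transform(x, 8, 32)
  b <- mtf_transform(exp(x), 8, 32)
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("a constant series degenerates to the uniform MTF with a warning", {
  expect_warning(fm <- mtf_transform(rep(1, 50), 4, 16), "constant")
  expect_true(all(abs(fm$values - 0.25) < 1e-12))
})

test_that("MFCC of digital silence has identical frames and energy only in c0", {
  clip <- audio_clip(rep(0, 16000), 16000)
  fm <- mfcc_transform(clip)
  expect_true(all(apply(fm$values, 1, function(r) max(r) - min(r)) < 1e-9))
  expect_true(all(abs(fm$values[-1, ]) < 1e-6))
})

test_that("a pure tone at a mel filter centre maximises that filter's output", {
  fs <- 16000; n_mels <- 26
  centers <- mel_centers(n_mels, fs)
  for (m in c(5, 13, 20)) {
    tone <- sin(2 * pi * centers[m] * (0:3999) / fs)
    # oracle: evaluate the filterbank directly on the tone's spectrum
    nfft <- 512
    fb <- mel_filterbank(n_mels, nfft, fs)
    spec <- abs(fft(tone[1:nfft] * (0.5 - 0.5 * cos(2 * pi * (0:(nfft - 1)) / (nfft - 1)))))[1:(nfft / 2 + 1)]
    expect_identical(which.max(as.numeric(fb %*% spec)), as.integer(m))
  }
})

test_that("MFCC frame count follows the framing arithmetic", {
  fs <- 16000
  for (n in c(4000, 5000, 12345)) {
    clip <- audio_clip(sin(2 * pi * 300 * (1:n) / fs), fs)
    fm <- mfcc_transform(clip, frame_len = 0.025, hop = 0.010)
    expect_identical(ncol(fm$values),
                     as.integer(floor((n - 0.025 * fs) / (0.010 * fs)) + 1))
  }
})

test_that("MFCC gain invariance: doubling the amplitude only shifts c0", {
  withr::with_seed(9, x <- rnorm(8000) * 0.05)
  a <- mfcc_transform(audio_clip(x, 16000))
  b <- mfcc_transform(audio_clip(2 * x, 16000))
  expect_equal(a$values[-1, ], b$values[-1, ], tolerance = 1e-8)
  expect_gt(mean(b$values[1, ] - a$values[1, ]), 0)
})

test_that("filterbank edge above Nyquist is a configuration error", {
  clip <- audio_clip(rnorm(9000) / 10, 8000)
  expect_error(mfcc_transform(clip, fmax = 6000), class = "fibrc_config_error")
})

test_that("image pulse maps encode exactly the above-threshold pixels", {
  img <- matrix(0, 8, 8)
  expect_identical(sum(image_to_pulsemap(img)$mask), 0L)
  withr::with_seed(2, img <- matrix(runif(64), 8, 8))
  pm <- image_to_pulsemap(img, threshold = 0.5)
  expect_identical(sum(pm$mask), sum(img > 0.5))
  expect_identical(length(pm$rows), 8L)
  for (r in pm$rows) {
    expect_identical(length(r), 8L)
    expect_true(all(r$amplitude %in% c(0, 1.5)))
    expect_true(all(r$duration == 0.2))
  }
  n_pulses <- sum(vapply(pm$rows, function(r) sum(r$amplitude > 0), numeric(1)))
  expect_identical(as.integer(n_pulses), as.integer(sum(img > 0.5)))
  expect_error(image_to_pulsemap(matrix(numeric(0), 0, 0)), class = "fibrc_input_error")
})

test_that("matrix_to_pulserows thresholds, rescales and pads as specified", {
  m <- rbind(c(1, 1, 5, 5, 1, 5), c(0, 2, 4, 6, 8, 10))
  bin <- matrix_to_pulserows(m, "binary", frame_k = 4, v_write = 1.5)
  expect_equal(bin[[1]]$amplitude, c(0, 0, 1.5, 1.5, 0, 1.5, 0, 0))   # median split + padding
  amp <- matrix_to_pulserows(m, "amplitude", frame_k = 4, v_write = 1.5)
  expect_equal(max(amp[[2]]$amplitude), 1.5)                          # row max maps to v_write
  expect_equal(amp[[2]]$amplitude[1], 0)                              # row min maps to 0
  expect_identical(length(amp[[1]]), as.integer(ceiling(6 / 4) * 4))
  # an all-equal row in amplitude mode becomes all-zero amplitudes
  flat <- matrix_to_pulserows(matrix(3, 1, 4), "amplitude", 4)
  expect_true(all(flat[[1]]$amplitude == 0))
})

test_that("encoders are deterministic", {
  withr::with_seed(6, x <- rnorm(500))
  expect_identical(mtf_transform(x, 8, 16)$values, mtf_transform(x, 8, 16)$values)
  clip <- audio_clip(sin(2 * pi * 200 * (1:8000) / 16000), 16000)
  expect_identical(mfcc_transform(clip)$values, mfcc_transform(clip)$values)
})
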