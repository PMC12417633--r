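# Synthetic data generators: stage-dependent EEG, snore/ambient audio,
# night plans and glyphs. All are pure functions of (parameters, seed).

test_that("zero band weights leave pure white noise at the configured floor variance", {
  spec <- stage_spec()
  spec$wake[] <- 0
  vars <- vapply(1:50, function(s)
    stats::var(gen_eeg_epoch("wake", fs = 128, epoch_s = 10, spec = spec, seed = s)$samples),
    numeric(1))
  expect_equal(mean(vars), spec$amp_uv^2, tolerance = 0.1)
})

test_that("deep epochs carry more relative delta power than wake epochs", {
  spec <- stage_spec()
  rel_delta <- function(stage, s) {
    x <- gen_eeg_epoch(stage, fs = 128, epoch_s = 10, spec = spec, seed = s)$samples
    band_power(x, 128, 0.5, 4) / band_power(x, 128, 0.5, 64)
  }
  wins <- vapply(1:100, function(s) rel_delta("deep", s) > rel_delta("wake", s + 1000), logical(1))
  expect_gte(sum(wins), 95)
})

test_that("EEG generation is deterministic per seed", {
  a <- gen_eeg_epoch("light", seed = 42)
  b <- gen_eeg_epoch("light", seed = 42)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, gen_eeg_epoch("light", seed = 43)$samples))
})

test_that("snore clips have bounded amplitude and the expected burst count", {
  for (s in 1:10) {
    clip <- gen_snore_clip(12, snore = TRUE, seed = s)
    expect_lte(max(abs(clip$samples)), 1)
    # oracle: count bursts from a heavily smoothed envelope (0.25 s window
    # removes the intra-burst amplitude modulation)
    env <- stats::filter(abs(clip$samples), rep(1 / 4000, 4000), sides = 2)
    env[is.na(env)] <- 0
    above <- env > 0.4 * max(env)
    n_bursts <- sum(diff(c(0, above)) == 1)
    expect_lte(abs(n_bursts - 12 * 0.25), 1)
  }
})

test_that("non-snore clips have their spectral centroid above the snore fundamental band", {
  hits <- vapply(1:20, function(s) {
    clip <- gen_snore_clip(5, snore = FALSE, seed = s)
    x <- clip$samples
    P <- Mod(fft(x))[1:(length(x) %/% 2)]^2
    f <- (0:(length(x) %/% 2 - 1)) * clip$fs / length(x)
    sum(f * P) / sum(P) > 180
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("ambient mixing hits the requested SNR and respects amplitude bounds", {
  clip <- gen_snore_clip(6, snore = TRUE, seed = 3)
  for (kind in c("rain", "traffic")) {
    mixed <- add_ambient(clip, kind, snr_db = 10, seed = 4)
    expect_lte(max(abs(mixed$samples)), 1)
    # recompute the realised SNR: the noise is the difference (up to the
    # common peak renormalisation, which preserves the ratio)
    scl <- 1
    resid <- mixed$samples * scl - clip$samples
    # solve the common rescale factor by least squares against the clip
    scl <- sum(clip$samples^2) / sum(mixed$samples * clip$samples)
    resid <- mixed$samples * scl - clip$samples
    snr <- 10 * log10(mean(clip$samples^2) / mean(resid^2))
    expect_lt(abs(snr - 10), 0.5)
  }
  expect_identical(add_ambient(clip, "none"), clip)
})

test_that("night generation is epoch-aligned, labelled and schedule-consistent", {
  plan <- night_plan(duration_s = 600, epoch_s = 30, seed = 5)
  night <- gen_night(plan)
  expect_identical(nrow(night$labels), 20L)
  expect_identical(length(night$eeg), 20L)
  expect_identical(length(night$audio), 20L)
  expect_false(any(night$labels$snore & night$labels$stage == "wake"))
  expect_true(all(vapply(seq_len(20), function(i)
    night$eeg[[i]]$stage_label == night$labels$stage[i], logical(1))))
  # determinism
  night2 <- gen_night(plan)
  expect_identical(night$labels, night2$labels)
  expect_identical(night$eeg[[3]]$samples, night2$eeg[[3]]$samples)
})

test_that("long-run stage transition frequencies converge to the plan's Markov matrix", {
  plan <- night_plan(duration_s = 1e4 * 30, epoch_s = 30, seed = 9)
  labs <- gen_night(plan, signals = FALSE)$labels$stage
  emp <- prop.table(table(factor(labs[-length(labs)], rownames(plan$transition)),
                          factor(labs[-1], rownames(plan$transition))), 1)
  expect_equal(matrix(as.numeric(emp), 3), unname(plan$transition), tolerance = 0.05)
})

test_that("glyphs are deterministic, distinct, and flip noise follows the binomial law", {
  g1 <- gen_glyphs(seed = 1); g2 <- gen_glyphs(seed = 99)
  expect_identical(g1, g2)
  expect_gt(sum(g1$W != g1$G), 0)
  expect_gt(sum(g1$W != g1$`6`), 0)
  expect_gt(sum(g1$G != g1$`6`), 0)
  p <- 0.1; size <- 16
  base <- gen_glyphs("W", size = size)$W
  ham <- vapply(1:200, function(s) sum(gen_glyphs("W", size = size, flip_p = p, seed = s)$W != base),
                numeric(1))
  expected <- p * size^2
  sigma <- sqrt(size^2 * p * (1 - p))
  expect_lt(abs(mean(ham) - expected), 3 * sigma / sqrt(200))
  expect_error(gen_glyphs("Q"), class = "fibrc_input_error")
})
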