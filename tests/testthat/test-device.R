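# Phenomenological fiber-memristor model: baseline, pulse response, fading
# memory, switching, programming levels and energy accounting.

test_that("baseline state and current endpoints behave as defined", {
  p <- device_params()
  st <- reset_to_baseline(p)
  expect_identical(st$w, p$w_min)
  expect_identical(st$t, 0)
  expect_equal(read_current(st, p), p$i_off)
  st$w <- p$w_max
  expect_equal(read_current(st, p), p$i_on)
  # linear readout at midpoint
  pl <- device_params(p_nl = 1)
  st$w <- (pl$w_min + pl$w_max) / 2
  expect_equal(read_current(st, pl), (pl$i_off + pl$i_on) / 2)
})

test_that("invalid parameters are rejected as configuration errors", {
  expect_error(device_params(a_write = 1.2), class = "fibrc_config_error")
  expect_error(device_params(tau_decay = -1), class = "fibrc_config_error")
  expect_error(device_params(i_off = 1e-9, i_on = 1e-11), class = "fibrc_config_error")
  expect_error(device_params(v_set = -1, v_reset = 1), class = "fibrc_config_error")
})

test_that("apply_pulse implements threshold potentiation, hard reset and exponential decay", {
  p <- device_params()
  # pure decay: w = 0.8 relaxing over 3 time constants
  st <- reset_to_baseline(p); st$w <- 0.8
  st <- apply_pulse(st, pulse(0, 0.2, 3 * p$tau_decay), p)
  expect_equal(st$w, 0.8 * exp(-3), tolerance = 1e-12)
  # single write pulse from baseline, no gap: exactly a_write
  st <- apply_pulse(reset_to_baseline(p), pulse(p$v_write, 0.2, 0), p)
  expect_equal(st$w, p$a_write)
  # sub-threshold amplitude leaves the state untouched (zero gap)
  st2 <- apply_pulse(st, pulse(0.5, 0.2, 0), p)
  expect_equal(st2$w, st$w)
  # reset pulse ruptures to w_min
  st3 <- apply_pulse(st, pulse(p$v_reset, 0.2, 0), p)
  expect_equal(st3$w, p$w_min)
  # clock is non-decreasing and advances by duration + gap
  expect_equal(st3$t, st$t + 0.2)
})

test_that("pulse-train simulation matches the independent scalar recurrence", {
  p <- device_params()
  withr::with_seed(11, {
    for (rep in 1:100) {
      n <- sample(3:20, 1)
      amps <- sample(c(0, p$v_write, p$v_reset, 0.4), n, replace = TRUE)
      gaps <- runif(n, 0, 0.5)
      st <- reset_to_baseline(p)
      for (i in seq_len(n)) st <- apply_pulse(st, pulse(amps[i], 0.2, gaps[i]), p)
      w_oracle <- oracle_recurrence(amps, rep(0.2, n), gaps, p)
      expect_equal(st$w, w_oracle, tolerance = 1e-12)
    }
  })
})

test_that("read current is strictly increasing in the state variable", {
  p <- device_params()
  ws <- seq(p$w_min, p$w_max, length.out = 100)
  cur <- vapply(ws, function(w) { s <- reset_to_baseline(p); s$w <- w; read_current(s, p) },
                numeric(1))
  expect_true(all(diff(cur) > 0))
})

test_that("4-bit programming frames give 16 distinct levels with fading-memory ordering", {
  lev <- enumerate_levels(4)
  expect_identical(lev$n_levels, 16L)
  expect_gte(lev$min_margin, 0.01)
  expect_equal(program_states("0000"), device_params()$i_off)
  expect_gt(program_states("0001"), program_states("1000"))
  expect_error(program_states(c(0, 2, 1)), class = "fibrc_input_error")
})

test_that("moving a single write pulse later in the frame never decreases the current", {
  k <- 6
  cur <- vapply(seq_len(k), function(pos) {
    frame <- rep(0L, k); frame[pos] <- 1L
    program_states(frame)
  }, numeric(1))
  expect_true(all(diff(cur) > 0))
})

test_that("echo-state property: opposite initial states converge after an idle segment", {
  p <- device_params()
  withr::with_seed(5, {
    amps <- sample(c(0, p$v_write), 20, replace = TRUE)
    gaps <- rep(p$slot_gap, 20)
    gaps[12] <- 5 * p$tau_decay          # one long idle segment
    s1 <- reset_to_baseline(p)
    s2 <- reset_to_baseline(p); s2$w <- p$w_max
    for (i in 1:20) {
      s1 <- apply_pulse(s1, pulse(amps[i], 0.2, gaps[i]), p)
      s2 <- apply_pulse(s2, pulse(amps[i], 0.2, gaps[i]), p)
    }
    expect_lt(abs(s1$w - s2$w), 1e-3)
  })
})

test_that("cycle-to-cycle noise is reproducible for equal seeds and differs across seeds", {
  p1 <- device_params(sigma_c2c = 0.05, seed = 42)
  p2 <- device_params(sigma_c2c = 0.05, seed = 42)
  p3 <- device_params(sigma_c2c = 0.05, seed = 43)
  drive <- function(p) {
    st <- reset_to_baseline(p)
    for (i in 1:6) st <- apply_pulse(st, pulse(p$v_write, 0.2, 0.05), p)
    st$w
  }
  expect_identical(drive(p1), drive(p2))
  expect_false(identical(drive(p1), drive(p3)))
})

test_that("the I-V sweep shows a pinched, bipolar hysteresis loop", {
  p <- device_params()
  sw <- iv_sweep(p, v_max = 1.5, n_points = 400)
  expect_true(all(sw$current[sw$voltage == 0] == 0))
  # SET occurs at the first sample at or above +1 V
  first_set <- which(sw$w == p$w_max)[1]
  expect_gte(sw$voltage[first_set], p$v_set)
  expect_lt(sw$voltage[first_set - 1], p$v_set)
  # hysteresis: forward and return branches differ below v_set
  g_on <- p$i_on / p$v_read; g_off <- p$i_off / p$v_read
  v_probe <- 0.5
  fwd <- sw$current[which(abs(sw$voltage - v_probe) < 0.02 & sw$w == p$w_min)[1]]
  ret <- sw$current[which(abs(sw$voltage - v_probe) < 0.02 & sw$w == p$w_max)[1]]
  expect_equal(fwd / v_probe, g_off, tolerance = 0.05)
  expect_equal(ret / v_probe, g_on, tolerance = 0.05)
  expect_error(iv_sweep(p, v_max = 0.5), class = "fibrc_config_error")
})

test_that("energy accounting matches a dense-time integration oracle", {
  p <- device_params()
  tr <- pulse_train(c(p$v_write, 0, p$v_write, p$v_write, 0), 0.2, 0.05)
  res <- energy_of_train(tr, p)
  # oracle: integrate |V(t) I(t)| on a fine grid over the piecewise trajectory
  dt <- 1e-4
  w <- p$w_min; e <- 0
  for (i in seq_len(length(tr))) {
    a <- tr$amplitude[i]
    if (a >= p$v_set) w <- min(w + p$a_write * (p$w_max - w), p$w_max)
    else if (a <= p$v_reset) w <- p$w_min
    i_now <- p$i_off + (p$i_on - p$i_off) * ((w - p$w_min) / (p$w_max - p$w_min))^p$p_nl
    e <- e + sum(rep(abs(a) * i_now, tr$duration[i] / dt)) * dt
    w <- p$w_min + (w - p$w_min) * exp(-tr$gap_after[i] / p$tau_decay)
  }
  expect_equal(res$energy, e, tolerance = 0.01)
  # zero train carries no energy
  z <- energy_of_train(pulse_train(rep(0, 4), 0.2, 0.05), p)
  expect_identical(z$energy, 0)
  # a single 1 V read at sub-nanoampere currents stays under a nanowatt
  st <- reset_to_baseline(p); st$w <- p$w_max
  rd <- energy_of_train(pulse_train(0.999, 0.2, 0), p, st)   # sub-threshold probe
  expect_lt(rd$mean_power, 1e-9)
})
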