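# Phenomenological model of the Ag/MoS2-QD/Ag fiber memristor.
#
# The device carries one internal state variable w in [w_min, w_max]
# (normalised filament extent). A supra-threshold write pulse potentiates
# w by a fixed fraction of the remaining headroom (saturating update); a
# pulse at or below the negative threshold ruptures the filament (hard
# reset to w_min); between pulses w relaxes exponentially toward w_min
# with time constant tau_decay — the fading memory that makes the device a
# reservoir. Read current follows a power law between the off- and
# on-state currents.

#' Device model parameters
#'
#' Defaults realise a diffusive fiber memristor switching at +/-1 V with
#' sub-nanoampere currents and 16 separable conductance levels under 4-pulse
#' programming frames (200 ms pulses, 50 ms gaps).
#'
#' @param w_min,w_max internal state bounds (dimensionless).
#' @param a_write per-pulse potentiation fraction, in (0, 1).
#' @param tau_decay state relaxation time constant, seconds.
#' @param v_write write-pulse amplitude, volts.
#' @param v_read read voltage, volts.
#' @param v_set,v_reset switching thresholds, volts (defaults +1 / -1).
#' @param i_off,i_on read currents at w = w_min and w = w_max, amperes.
#' @param p_nl readout nonlinearity exponent (>= 1).
#' @param sigma_c2c cycle-to-cycle multiplicative noise s.d. on the
#'   potentiation increment (log-normal); 0 disables noise.
#' @param slot_duration,slot_gap default programming slot width and gap,
#'   seconds; `tau_decay` defaults to twice the slot period.
#' @param seed RNG seed used when `sigma_c2c > 0`.
#' @return an object of class `fibrc_device_params`.
#' @export
device_params <- function(w_min = 0, w_max = 1,
                          a_write = 0.3,
                          slot_duration = 0.2, slot_gap = 0.05,
                          tau_decay = 2 * (slot_duration + slot_gap),
                          v_write = 1.5, v_read = 1.0,
                          v_set = 1.0, v_reset = -1.0,
                          i_off = 10e-12, i_on = 0.5e-9,
                          p_nl = 2, sigma_c2c = 0, seed = 1L) {
  p <- list(w_min = w_min, w_max = w_max, a_write = a_write,
            tau_decay = tau_decay, v_write = v_write, v_read = v_read,
            v_set = v_set, v_reset = v_reset, i_off = i_off, i_on = i_on,
            p_nl = p_nl, sigma_c2c = sigma_c2c,
            slot_duration = slot_duration, slot_gap = slot_gap,
            seed = as.integer(seed))
  for (nm in setdiff(names(p), "seed")) assert_scalar_num(p[[nm]], nm)
  if (!(p$a_write > 0 && p$a_write < 1)) stop_config("a_write must lie in (0, 1)")
  if (p$tau_decay <= 0) stop_config("tau_decay must be > 0")
  if (!(p$i_on > p$i_off && p$i_off > 0)) stop_config("need i_on > i_off > 0")
  if (!(p$v_set > 0 && p$v_reset < 0)) stop_config("need v_set > 0 > v_reset")
  if (p$w_max <= p$w_min) stop_config("need w_max > w_min")
  if (p$p_nl < 1) stop_config("p_nl must be >= 1")
  if (p$sigma_c2c < 0) stop_config("sigma_c2c must be >= 0")
  structure(p, class = "fibrc_device_params")
}

#' @export
print.fibrc_device_params <- function(x, ...) {
  cat(sprintf(paste0("<fiber memristor params: a_write=%g, tau=%g s, p_nl=%g,\n",
                     "  i_off=%.3g A, i_on=%.3g A, v_set=%g V, v_reset=%g V, sigma_c2c=%g>\n"),
              x$a_write, x$tau_decay, x$p_nl, x$i_off, x$i_on, x$v_set, x$v_reset, x$sigma_c2c))
  invisible(x)
}

#' Initialise a device at its common baseline
#'
#' All devices in the reservoir start from the same baseline (fully relaxed)
#' state, with the device clock at zero.
#'
#' @param params a `fibrc_device_params` object.
#' @return a `fibrc_device_state` with `w = w_min`, `t = 0`. When
#'   `sigma_c2c > 0` the state carries a private RNG stream derived from
#'   `params$seed`, so equal seeds give identical trajectories.
#' @export
reset_to_baseline <- function(params) {
  if (!inherits(params, "fibrc_device_params")) stop_config("params must come from device_params()")
  st <- list(w = params$w_min, t = 0)
  if (params$sigma_c2c > 0) {
    st$rng <- with_seed(params$seed, {
      runif(1)  # advance once so the stream depends on the seed alone
      get(".Random.seed", envir = globalenv())
    })
  }
  structure(st, class = "fibrc_device_state")
}

#' @export
print.fibrc_device_state <- function(x, ...) {
  cat(sprintf("<device state: w=%.6g, t=%.3f s>\n", x$w, x$t))
  invisible(x)
}

# one noise draw from the state's private stream (log-normal multiplier)
.draw_noise <- function(state, sigma) {
  assign(".Random.seed", state$rng, envir = globalenv())
  z <- exp(stats::rnorm(1, 0, sigma))
  state$rng <- get(".Random.seed", envir = globalenv())
  list(mult = z, state = state)
}

#' Apply one voltage pulse to a device
#'
#' A pulse at or above `v_set` potentiates the state by `a_write` times the
#' remaining headroom (optionally perturbed by multiplicative log-normal
#' cycle-to-cycle noise); a pulse at or below `v_reset` hard-resets the
#' filament to `w_min`; any other amplitude leaves the state untouched by the
#' pulse itself. The state then relaxes exponentially toward `w_min` over the
#' idle gap, and the device clock advances by `duration + gap_after`.
#'
#' @param state a `fibrc_device_state`.
#' @param pulse a `fibrc_pulse` (or a list with amplitude/duration/gap_after).
#' @param params a `fibrc_device_params`.
#' @return the updated `fibrc_device_state`.
#' @export
apply_pulse <- function(state, pulse, params) {
  if (!inherits(state, "fibrc_device_state")) stop_input("state must come from reset_to_baseline()")
  w <- state$w
  if (pulse$amplitude >= params$v_set) {
    dw <- params$a_write * (params$w_max - w)
    if (params$sigma_c2c > 0) {
      nd <- .draw_noise(state, params$sigma_c2c)
      dw <- dw * nd$mult
      state <- nd$state
    }
    w <- min(w + dw, params$w_max)
  } else if (pulse$amplitude <= params$v_reset) {
    w <- params$w_min
  }
  w <- params$w_min + (w - params$w_min) * exp(-pulse$gap_after / params$tau_decay)
  state$w <- w
  state$t <- state$t + pulse$duration + pulse$gap_after
  state
}

#' Read the device current (non-destructive)
#'
#' Current under the read voltage follows a power law in the normalised
#' state: `I = i_off + (i_on - i_off) * ((w - w_min)/(w_max - w_min))^p_nl`.
#' Strictly increasing in `w`; the state is not modified.
#'
#' @param state a `fibrc_device_state`.
#' @param params a `fibrc_device_params`.
#' @return read current in amperes.
#' @export
read_current <- function(state, params) {
  wn <- (state$w - params$w_min) / (params$w_max - params$w_min)
  params$i_off + (params$i_on - params$i_off) * wn^params$p_nl
}

.current_of_w <- function(w, params) {
  wn <- (w - params$w_min) / (params$w_max - params$w_min)
  params$i_off + (params$i_on - params$i_off) * wn^params$p_nl
}

#' Program a device with a binary frame and read the resulting level
#'
#' From the common baseline, each bit of `frame` becomes one programming
#' slot: bit 1 is a write pulse at `v_write`, bit 0 an unstimulated slot of
#' the same width; every slot is followed by the same idle gap. The current
#' read after the final slot is the programmed conductance level. With
#' `sigma_c2c = 0` the map from the `2^k` frames to currents is injective
#' (16 separable levels at the default k = 4).
#'
#' @param frame binary vector (0/1), or a string such as `"1011"`.
#' @param params a `fibrc_device_params`.
#' @return final read current, amperes.
#' @export
program_states <- function(frame, params = device_params()) {
  if (is.character(frame)) frame <- as.integer(strsplit(frame, "")[[1]])
  if (length(frame) == 0 || !all(frame %in% c(0, 1))) stop_input("frame must be a non-empty 0/1 sequence")
  state <- reset_to_baseline(params)
  amps <- ifelse(frame == 1, params$v_write, 0)
  for (a in amps)
    state <- apply_pulse(state, pulse(a, params$slot_duration, params$slot_gap), params)
  read_current(state, params)
}

#' Enumerate the programmable conductance levels of a frame length
#'
#' Programs every binary frame of length `k` from baseline and returns the
#' read currents, the level table, and the count of mutually distinguishable
#' levels at a relative separation margin.
#'
#' @param k frame length in pulses (default 4, giving 16 levels).
#' @param params device parameters (noiseless by default).
#' @param margin_min minimum relative separation between adjacent sorted
#'   currents for two levels to count as distinct (default 1%).
#' @return a list with `table` (data.frame: frame, current), `n_levels`
#'   (count of distinguishable levels) and `min_margin`.
#' @export
enumerate_levels <- function(k = 4, params = device_params(), margin_min = 0.01) {
  frames <- expand.grid(rep(list(c(0L, 1L)), k))[, k:1, drop = FALSE]
  labels <- apply(frames, 1, paste0, collapse = "")
  currents <- vapply(seq_len(nrow(frames)), function(i)
    program_states(as.integer(frames[i, ]), params), numeric(1))
  ord <- order(currents)
  s <- currents[ord]
  margins <- diff(s) / s[-length(s)]
  n_levels <- 1L + sum(margins >= margin_min)
  list(table = data.frame(frame = labels, current = currents, stringsAsFactors = FALSE),
       n_levels = n_levels,
       min_margin = if (length(margins)) min(margins) else NA_real_)
}

#' Quasi-static I-V sweep with bipolar switching
#'
#' Triangular voltage sweep 0 -> +v_max -> 0 -> -v_max -> 0. The device SETs
#' to `w_max` once the voltage reaches `v_set` and RESETs to `w_min` once it
#' reaches `v_reset`; current is `G(w) * v` with the conductance interpolated
#' between `i_off/v_read` and `i_on/v_read`. The loop is pinched (I = 0 at
#' every zero crossing) and hysteretic.
#'
#' @param params device parameters.
#' @param v_max sweep amplitude, volts; must exceed `v_set`.
#' @param n_points number of samples along the full sweep.
#' @return data.frame with columns `voltage`, `current`, `w`.
#' @export
iv_sweep <- function(params = device_params(), v_max = 1.5, n_points = 400) {
  if (v_max <= params$v_set) stop_config("v_max must exceed v_set for switching to occur")
  q <- ceiling(n_points / 4)
  v <- c(seq(0, v_max, length.out = q + 1),
         seq(v_max, 0, length.out = q + 1)[-1],
         seq(0, -v_max, length.out = q + 1)[-1],
         seq(-v_max, 0, length.out = q + 1)[-1])
  w <- numeric(length(v))
  cur_w <- params$w_min
  for (i in seq_along(v)) {
    if (v[i] >= params$v_set) cur_w <- params$w_max
    if (v[i] <= params$v_reset) cur_w <- params$w_min
    w[i] <- cur_w
  }
  g <- .current_of_w(w, params) / params$v_read
  data.frame(voltage = v, current = g * v, w = w)
}

#' Energy dissipated by a pulse train
#'
#' Integrates `|V(t) * I(t)|` over the train's piecewise trajectory: during a
#' pulse the state has already jumped (filament formation is fast relative to
#' the 200 ms slot) and holds, so each pulse contributes
#' `|V| * I(w_during) * duration`; gaps carry no voltage and no energy.
#'
#' @param train a `fibrc_pulse_train`.
#' @param params device parameters.
#' @param state optional starting state (defaults to baseline).
#' @return list with `energy` (joules), `mean_power` (watts, energy over the
#'   train's total duration) and `final_state`.
#' @export
energy_of_train <- function(train, params = device_params(), state = reset_to_baseline(params)) {
  e <- 0
  for (i in seq_len(length(train))) {
    p <- pulse(train$amplitude[i], train$duration[i], train$gap_after[i])
    w_before_gap <- {
      # state during the pulse: post-update, pre-decay
      w <- state$w
      if (p$amplitude >= params$v_set) {
        dw <- params$a_write * (params$w_max - w)
        if (params$sigma_c2c > 0) {
          nd <- .draw_noise(state, params$sigma_c2c)
          dw <- dw * nd$mult
          state <- nd$state
        }
        w <- min(w + dw, params$w_max)
      } else if (p$amplitude <= params$v_reset) w <- params$w_min
      w
    }
    i_during <- .current_of_w(w_before_gap, params)
    e <- e + abs(p$amplitude) * i_during * p$duration
    state$w <- params$w_min + (w_before_gap - params$w_min) * exp(-p$gap_after / params$tau_decay)
    state$t <- state$t + p$duration + p$gap_after
  }
  tot <- train_duration(train)
  list(energy = e, mean_power = if (tot > 0) e / tot else 0, final_state = state)
}
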