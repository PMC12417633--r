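---
title: "Methods: device model, encoders, reservoir and synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: device model, encoders, reservoir and synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrc)
```

`fibrc` simulates a fiber-memristor physical reservoir computing (RC)
system for multimodal sleep monitoring. This vignette is the package's
account of its science: the device model and its assumptions, the encoders,
the reservoir and readout conventions, the synthetic-data design, and every
numerical choice a maintainer might question.

## 1. The phenomenological device model

No closed-form device equations or fitted parameter values are published
for the fiber memristor this package emulates; the model here is the
minimal phenomenology standard for diffusive (Ag-filament) memristors used
as reservoirs, chosen to reproduce three qualitative behaviours at once:
nonlinear pulse-driven current evolution, sixteen separable conductance
levels under 4-pulse programming, and fading memory.

One dimensionless state $w \in [w_{\min}, w_{\max}]$ abstracts the
filament extent. For each pulse (amplitude $V$, width $d$, trailing gap
$g$):

$$
w \leftarrow
\begin{cases}
w + a_\mathrm{write}\,(w_{\max} - w) & V \ge v_\mathrm{set} \\
w_{\min} & V \le v_\mathrm{reset} \\
w & \text{otherwise,}
\end{cases}
\qquad\text{then}\qquad
w \leftarrow w_{\min} + (w - w_{\min})\,e^{-g/\tau}.
$$

Read current follows a power law,
$I = i_\mathrm{off} + (i_\mathrm{on} - i_\mathrm{off})
\left(\tfrac{w - w_{\min}}{w_{\max} - w_{\min}}\right)^{p}$,
strictly increasing in $w$ and non-destructive.

Assumptions worth stating:

- **Instantaneous switching.** Filament formation is fast relative to the
  200 ms programming slot, so $w$ jumps at pulse onset and holds for the
  pulse width; decay happens only during the idle gap. This makes the
  closed-form energy $E = \sum |V|\, I(w_\mathrm{during})\, d$ exact
  against dense-time integration of $|V(t)I(t)|$.
- **Hard RESET.** A reverse pulse at or below $v_\mathrm{reset}$ ruptures
  the filament abruptly; gradual depression is not modelled.
- **Multiplicative cycle-to-cycle noise.** Optional log-normal noise
  $\exp \mathcal N(0, \sigma_\mathrm{c2c}^2)$ on the potentiation
  increment, seed-controlled. The default is $\sigma_\mathrm{c2c}=0$ so
  that every contract (level injectivity, exact image reconstruction) is
  testable deterministically.

### Default parameters

| parameter | default | unit | why |
|---|---|---|---|
| `a_write` | 0.3 | — | with $\tau$ below, separates all 16 4-bit levels by ≥ 1% |
| `slot_duration`, `slot_gap` | 0.2, 0.05 | s | 200 ms write pulses; short idle per slot |
| `tau_decay` | 0.5 (= 2 slot periods) | s | fading memory spans a frame but not much more |
| `v_set`, `v_reset` | +1, −1 | V | bipolar switching at ±1 V |
| `v_write`, `v_read` | 1.5, 1.0 | V | write pulses of 1.5 V; 1 V read |
| `i_off`, `i_on` | 10 pA, 0.5 nA | A | sub-nanoampere operating currents |
| `p_nl` | 2 | — | super-linear current map spreads the upper levels |

At these defaults the 16 programmed levels have a minimum adjacent
relative separation of ≈ 3.6%; the 1% margin defining "distinguishable" is
far above double-precision noise and below any realistic read resolution.
Energy accounting at this operating point gives tens of picowatts mean
read power — "picowatt-scale" in order of magnitude, and below the 1 nW
flag the energy report enforces (1 V × 0.5 nA bounds read power by 0.5 nW).

### Invariants the tests pin down

Fading memory (a later write pulse always leaves more current than an
earlier one), echo-state convergence (opposite initial states driven by
the same train with one ≥ 5τ idle segment converge to $|\Delta w| <
10^{-3}$), injectivity of the 16-level map, determinism per seed, and
exact equivalence of the vectorised reservoir recurrence with the scalar
`apply_pulse` composition (≤ 10⁻¹² relative). With cycle-to-cycle noise
enabled, the vectorised reservoir draws its noise once per run from the
device seed rather than per virtual device; trajectories remain exactly
reproducible per seed, which is the contract the tests assert.

## 2. Encoders

**MTF (EEG).** The epoch is quantile-binned into `n_bins = 8` states
(ties to the lower bin), the first-order Markov transition matrix $W$ is
estimated by counting with row normalisation, the full field
$M_{ij} = W_{q_i, q_j}$ is formed and block-averaged to
`out_size = 64` — 64×64 retains enough temporal layout for the reservoir
while keeping 64 rows × 16 frames = 1024 state components. Rows of $W$
for bins never left from are set uniform; a constant series degenerates to
the uniform matrix with a warning (normalisation is preserved, no division
by zero). Because binning is by quantiles, the MTF is invariant under
strictly monotone amplitude transformations — amplitude information is
deliberately discarded, temporal structure is everything.

**MFCC (audio).** Pre-emphasis 0.97, 25 ms Hann frames, 10 ms hop,
magnitude spectrum, 26 HTK-mel triangular filters, log with floor 10⁻¹⁰,
orthonormal DCT-II, first 13 coefficients: conventional speech-processing
settings. Gain changes only move $c_0$. The pipeline block-averages the
MFCC time axis to 64 columns so audio state vectors (13 × 16 frames) are
commensurate with EEG ones.

**Images.** Pixels above threshold become fixed 1.5 V / 200 ms write
pulses, others unstimulated slots; row-major order is preserved.

**Feature → pulses.** Each feature-matrix row becomes an independent pulse
train segmented into frames of `frame_k = 4` slots (zero-padded). In
`amplitude` mode (default for MTF/MFCC) the row is min–max rescaled into
[0, 1.5 V]; because potentiation is thresholded at $v_\mathrm{set}$, this
effectively writes where a row entry exceeds ⅔ of its row range. In
`binary` mode (images) entries above the row median are written. An
all-equal row maps to all-zero amplitudes.

## 3. Reservoir, fusion, readouts

Each frame of 4 slots drives a **fresh device from the common baseline**
(the fixed bank of 16 conductance states implies frame-wise programming
rather than one continuously running device per row); the current after
the frame's last slot is one state component, ordered row-major. The
vectorised implementation iterates over slots, not frames, so a 64×64
input costs four vector updates.

Fusion concatenates z-normalised per-modality state vectors (EEG first);
without normalisation the modality with the larger current spread would
dominate the readout. The raw sub-vectors are kept so `unfuse_modalities()`
is exact.

The **linear readout** is a multinomial softmax with L2 penalty on the
weights (not biases), fit by L-BFGS from a zero start — convex, so the fit
is deterministic without any seed. The pipeline default penalty is
`l2 = 10`: reservoir state vectors have ~10³ features against ~10²
training windows, and the class signal is distributed, so strong ridge
shrinkage is the right operating point (the function default is 10⁻³ for
low-dimensional use).

The **CNN readout** is conv 3×3×8 → ReLU → maxpool 2 → conv 3×3×16 → ReLU
→ global average pooling → dense softmax (≈ 1.3k parameters), trained by
full-batch gradient descent with heavy-ball momentum 0.9 at a fixed step —
deterministic given the seed; plain descent (momentum 0) with a small step
is provably non-increasing and is what the descent test uses. Grids too
small to pool fall back to one conv layer with a message.

**CAM.** For the linear head the feature scaler is folded into the
weights, so the class-c map on the raw state grid satisfies
$\sum \mathrm{CAM}_c + b_c^\mathrm{eff} = \mathrm{logit}_c$ exactly and a
zero state yields a zero map. For the CNN head the standard
global-average-pooling CAM (class-weighted sum of final conv maps,
bilinearly upsampled) is used.

**Quantisation.** Per-tensor symmetric uniform quantisation of weight
magnitudes onto 16 levels including zero — mirroring the device bank whose
all-zero frame reads $i_\mathrm{off}$ — with the sign carried by a
two-device differential pair, since physical conductances are
non-negative. Biases stay full precision (applied digitally). Per-weight
error is bounded by half the level spacing.

**Label modes.** Three tasks are built in: `snore2`, `stage3`, and
`joint6` = {wake, light, deep} × {snore, no-snore}; which class set sits
behind a fused multimodal system is genuinely ambiguous, so both the joint
mode and stage-only classification over fused inputs are supported.

## 4. Synthetic data: the stated world

No recordings are distributed; every experiment runs on generated data.
The generator's job is to emulate the statistical structure the pipeline
assumes, and its constants are synthetic design choices, fixed here:

- **EEG.** Each stage is a weighted sum of *narrowband* Gaussian
  processes (FFT-masked white noise) plus a white floor, scaled to 15 µV
  standard deviation (≈ ±50 µV excursions), 128 Hz, 30 s epochs (clinical
  convention). Narrow bands — delta 0.85–1.1 Hz, theta 5–6 Hz, alpha
  9.5–10.5 Hz, beta 19–21 Hz, spindles 13–14 Hz gated by ~1 s raised-cosine
  bursts — matter: a narrowband process is rhythmic with a coherence time
  of seconds, which is what gives each stage a stable signature in a
  transition-field image. Broadband band-noise (coherence below the MTF's
  0.47 s block) produces transition fields whose class differences average
  out; quantile binning additionally erases all amplitude cues, so
  dominant-rhythm timescale is the only axis the encoder can see. Stage
  weights: wake is alpha/beta dominated, light is theta/spindle dominated
  with intermediate delta, deep is slow-oscillation dominated; delta
  weight is ordered deep > light > wake by construction.
- **Audio.** Snore bursts at the 0.25 Hz breathing rate (90–180 Hz
  fundamental + 4 harmonics, jittered AM envelope) over low breathing
  noise; rain = pink-ish broadband noise; traffic = < 120 Hz rumble with
  slow swells; mixing at a requested SNR measured over the whole clip.
  Classification clips default to 10 s (2–3 bursts) to keep desk-scale
  runs inside a CPU budget; night streams use full 30 s epochs.
- **Nights.** A sticky 3-state Markov chain over {wake, light, deep}
  (rows ≈ 0.7–0.8 self-transition), snore events only in light (p = 0.4)
  and deep (p = 0.15) epochs, never wake; default plan length 10 min for
  tests, arbitrarily extensible. Stage set deliberately has no REM,
  mirroring the three reported stages.
- **Glyphs.** 8×8 stroke bitmaps of "W", "G", "6" with optional pixel-flip
  noise.

What a green end-to-end test establishes — and what it does not: the
synthetic classes are separable *by design*, so the 80%+ accuracies show
that the encoder → reservoir → readout chain transmits and linearises that
structure, not that the system would reach any particular accuracy on real
polysomnography. Real EEG has artifacts, inter-subject variability,
non-stationarity within epochs and annotation noise, none of which the
generator emulates. Accuracies published for physical fiber-memristor
systems on real recordings are therefore out of this simulator's reach by
construction, and no test claims them.

## 5. Numerical choices and degenerate inputs

- Quantile-bin ties go to the lower bin; collapsed quantile breaks merge
  bins rather than erroring.
- Level decoding in image reconstruction takes the nearest level in
  current space with ties toward the lower level — deterministic and exact
  for a noiseless injective bank.
- PCA is the eigendecomposition of the covariance; component signs are
  fixed by making each component's largest-magnitude loading positive, so
  projections are reproducible. Rank-deficient inputs return the
  informative components only.
- The optimiser convergence contract for the linear head is checked
  against a central finite-difference gradient (norm < 10⁻⁵ at the
  returned weights).
- All randomness flows from one global seed through named substreams
  (`substream_seed`), so adding a pipeline stage never perturbs another
  stage's draws; generators are pure functions of (parameters, seed).
- Timeline intervals are half-open `[start_s, end_s)` seconds from stream
  start; consecutive identical stages merge on rendering and re-expand
  exactly on parsing.

## 6. Known limitations

- The device model is phenomenological: no electrochemical filament
  physics, crossbar parasitics, temperature, or mechanical strain; device
  mismatch beyond a scalar noise s.d. is not modelled.
- Amplitude-mode encoding is effectively a thresholded (ternary-ish) code
  because potentiation is threshold-gated; a device with
  amplitude-proportional potentiation would transmit more of the feature
  scale.
- The CNN is intentionally tiny and full-batch; it is a readout, not a
  deep-learning baseline.
- The 24 h tracking scenario is represented by the (scaled-down) night
  generator plus hypnogram rendering; no temporal smoothing of predictions
  is applied by default.
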