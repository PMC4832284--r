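---
title: "Estimating tonic sympathetic arousal by matching pursuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tonic sympathetic arousal by matching pursuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfmp)
```

## The model

Skin conductance shows transient rises in the absence of any external
stimulus — spontaneous fluctuations (SF). Their frequency indexes tonic
sympathetic arousal (tSA): the more aroused the central state, the more
sudomotor-nerve (SN) firing bursts reach the sweat glands, and each burst
evokes one SF. `sfmp` inverts a two-stage generative model of this chain:

* **Neural stage.** tSA sets the *number* of compact SN bursts per minute.
  A burst is a Gaussian bump in time with SD 0.3 s; its amplitude is the
  burst strength in SN units.
* **Peripheral stage.** The skin transforms SN activity into conductance
  linearly: SF = SN \* SCRF, where \* is convolution and SCRF is the
  canonical skin conductance response function. We realize the SCRF as a
  third-order cascade of first-order lags with time constants
  `(0.3, 0.7, 6.0)` s, giving a nonnegative, single-peaked response that
  peaks about 2 s after the burst centre, recovers to half its peak about
  5 s later, and decays below 1e-4 of the peak within 60 s. These constants
  are a documented stand-in for the full peripheral ODE published
  elsewhere; every analysis function accepts replacements through
  `scrf_params()`.

The overall gain is calibrated so that a unit-amplitude SN burst evokes an
SF with a 1 µS peak. Calibration is resolved at the sampling rate in use
(`gain = "auto"`), which makes the unit-burst peak exactly 1 µS on any
analysis grid; a fixed scalar gain would drift by about a tenth of a
percent between 10 and 100 Hz because the sampled peak moves with the grid.

```{r calibration}
p <- scrf_params()
max(canonical_response(p, fs = 10, horizon = 60)$values)
```

Because the onsets of SN bursts are unknown, inversion is combinatorial
rather than linear. The package uses matching pursuit (MP): an overcomplete
dictionary enumerates every SF that could occur — one atom per candidate
onset, from 9 s before the window (so that tails of earlier SF are
explained, not misattributed) to 1 s after it, in 0.1-s steps — and a
greedy search picks, on each iteration, the atom with the largest
normalized signed inner product with the current residual, subtracts its
optimal contribution, and repeats.

Three rules stop the search:

1. **Residual rule** — the residual ℓ2 norm falls below
   ε = √(0.001·N), N the number of samples (ε ≈ 0.775 µS·√samples for a
   60-s trace at 10 Hz).
2. **Capacity rule** — at most `ceiling(30 × minutes)` atoms, the SF
   capacity of the generative model. Non-integer durations round the cap
   up (a conservative reading of "per minute of data").
3. **Positivity rule** — negative SF are biophysically impossible, so the
   search maximizes the *signed* inner product and stops, without applying
   the atom, when the best coefficient is nonpositive.

Greedy selection mis-splits amplitude between overlapping SF, so after the
search all selected atoms are regressed jointly on the data (no intercept —
the high-pass preprocessing removes baseline level) and the least-squares
weights replace the greedy coefficients. The number of SF whose
reestimated amplitude reaches the 0.1 µS threshold, per minute, is the tSA
estimate.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `time_constants` | (0.3, 0.7, 6.0) | s | SCRF shape; see above |
| `gain` | `"auto"` | — | unit-burst peak = 1 µS |
| `burst_sd` | 0.3 | s | width of an SN burst bump |
| `eps_factor` | 0.001 | — | residual stopping norm √(0.001·N) |
| `max_rate` | 30 | SF/min | model's SF capacity |
| `amp_threshold` | 0.1 | µS | counting criterion with the best predictive validity on training data |
| `normalize` | `TRUE` | — | argmax uses <g,R>/‖g‖; see below |
| `conduction_delay` | 0 | s | subtracted when central SF times are wanted |

The selection criterion deserves a note. With unit-amplitude (rather than
unit-norm) atoms, the plain inner product <g, R> systematically
favours or disfavours window-edge atoms whose norms are truncated, and
subtracting <g, R>·g would not minimize the residual. The default
therefore maximizes <g, R>/‖g‖ and applies a = <g, R>/‖g‖², the optimal
one-dimensional projection, so coefficients stay in SN-amplitude units
(≈ µS of evoked SF peak by calibration). The plain criterion remains
available via `mp_config(normalize = FALSE)`.

## The simulator: what it emulates, and what it does not

`sim_spec()` fixes the synthetic study conditions: 60-s traces at 10 Hz,
1–30 bursts, amplitudes uniform on [0.1, 2.0] SN units, inter-burst
intervals exponential with mean 60/rate seconds plus a 1-s refractory
period (so bursts are separable, as physiological SN firing is), rendered
noiselessly through the same forward model the inversion assumes.

`generate_corpus()` bins traces by their *realized* burst count. The
refractory period makes realized counts fall short of the nominal rate
(a target rate r realizes on average 60r/(60 + r) bursts in 60 s), so the
generator draws candidate trains for each still-unfilled bin k at the
matched rate 60k/(60 − k) per minute, cycling over unfilled bins, and
assigns every train to the bin of its realized count. Conditional on the
realized count and the fixed window, the onset-pattern distribution of
this renewal process is essentially independent of the generating rate, so
bin statistics are unaffected while every bin fills in bounded time.
Unreachable bins (e.g. 30 bursts under a 3-s refractory) raise an error
naming the bin after a bounded number of draws.

Passing tests on this corpus shows that the *inversion* works when the
peripheral model is correct and noise-free. It does not exercise
measurement noise, skin-conductance level drift, motion artifacts,
inter-individual SCRF variability, or model mismatch — all present in real
recordings. The preprocessing module (band-pass 0.0159–5 Hz, causal
Butterworth, decimation to 10 Hz) handles level and high-frequency noise
in real data, but validity there must come from condition contrasts
(`score_methods()`), not from ground-truth recovery.

## Numerical choices

* **Exact discretization.** The LTI cascade is discretized per sample with
  the matrix exponential (zero-order hold), not a generic ODE stepper, so
  step size is never a source of test flakiness; responses are then
  superposed by FFT convolution of the sampled burst train with the
  discrete kernel. Agreement with a tight-tolerance ODE integration is a
  few percent at 10 Hz (the hold error of the 0.1-s grid) and an order of
  magnitude tighter at 100 Hz.
* **Burst truncation.** Gaussian bumps are truncated at ±4 SD (< 1e-4 of
  mass), giving atoms compact support; the truncation boundary carries a
  1e-9-sample slack so that integer-sample shifts commute exactly with
  rendering.
* **Bursts before the window** contribute their within-window tail: the
  simulation grid is extended back to the earliest bump support with zero
  state there, matching the dictionary's negative onsets.
* **Ties** in the greedy argmax go to the earliest onset; ties in
  nearest-in-time benchmark matching go to the earlier true onset, then
  the earlier estimated onset. Both are conventions chosen for
  determinism.
* **Numerically-zero coefficients.** Once an atom's optimal projection is
  removed, its inner product with the residual is float noise (~1e-16).
  The positivity stop therefore treats a best normalized inner product
  below 1e-10·‖R‖ as nonpositive; otherwise MP would reselect the same
  atom with a ~0 coefficient and burn the capacity budget without
  progress.
* **Rank-deficient regressions** (duplicate or collinear atom sets) fall
  back to the minimum-norm SVD solution and are flagged
  (`rank_deficient`). Duplicate onsets are merged into one predictor
  before regression. Negative reestimated amplitudes are retained in the
  result but never counted; there is no re-fitting loop.
* **Degenerate statistics.** Zero-variance contrasts raise an error
  rather than returning an infinite t; a zero RSS yields −Inf NLL with a
  warning; NLL comparisons across methods require identical n.

## Known limitations

Under dense SF (10 or more per minute of a 60-s window) the greedy,
positive-only search underestimates the SF count: early selections
overshoot where responses overlap, and the positivity constraint cannot
undo the overshoot. On our corpus the mean estimated count is within a few
percent of truth at 2 and 5 SF, about 20% low at 10, and roughly half of
truth at 20 — the underestimation regime is expected of this algorithm
class, and joint reestimation repairs amplitudes but not missed onsets.
The ε rule has a second effect in the same regime: a single SF at the
minimum permitted amplitude (0.1 µS) carries less residual energy than ε
for a 60-s trace, so trailing small SF can be absorbed into the stopping
criterion. Both effects are properties of the method, not tunables; users
needing unbiased counts at high rates should treat estimates above ~10 SF
per minute as lower bounds.

Amplitude RMSE in dense traces can be inflated by near-collinear selected
atoms (adjacent 0.1-s onsets): the regression weights are then poorly
conditioned even though the fitted curve, the residual and the
above-threshold count remain well-behaved.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script work at the scale a single CPU
handles comfortably while preserving the study conditions: 200 single-SF
traces for the recovery check; 100 traces per bin at true counts
{2, 5, 10, 15, 20}; 1,000 small randomized instances (≤ 50 atoms) for the
brute-force equivalence of the greedy selection; 500 traces for the
reestimation-optimality property; ~10,000 intervals and 100,000 amplitude
draws for the simulator's distributional checks; 1,000 random datasets for
the GLM/t-test equivalence. The full replication scale (1,000 traces per
bin over bins 1–30) is available through
`generate_corpus(1:30, n_per_bin = 1000, seed = ...)`.
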