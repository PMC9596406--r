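---
title: "Fractal and detrended cross-correlation analysis of BOLD signals: methods and design"
author: "fractalBOLD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal and detrended cross-correlation analysis of BOLD signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalBOLD)
```

## The problem and the model

Regional fMRI BOLD signals carry long-range temporal correlations whose
strength varies with cognitive state. Two complementary estimators quantify
that structure. Detrended fluctuation analysis (DFA) works in the time
domain: the mean-centred cumulative profile is cut into $2N_s$ segments of
length $s$ taken from both ends of the series ($N_s = \lfloor N/s \rfloor$),
an order-$m$ polynomial is removed from each, and the root-mean detrended
variance $F(s)$ scales as $s^H$ for fractal signals. The spectral route fits
$S(f) \sim 1/f^{\beta}$ to the raw periodogram; for fractal signals
$\beta = 2H - 1$, so the two estimates cross-validate each other. $H = 0.5$
means short-range correlation (shuffled or white data), $0.5 < H < 1$
persistence, and $H \gtrsim 1$ the nonstationary $1/f$ regime that
resting-state BOLD occupies.

Pairwise coupling at a chosen time scale is measured by the $q$-dependent
detrended cross-correlation coefficient. The per-segment detrended
covariance $F^2_{xy}(\nu, s)$ generalises the DFA variance (it can be
negative), the sign-preserving power mean
$F^q_{xy}(s) = \langle \mathrm{sign}(F^2_{xy}) |F^2_{xy}|^{q/2} \rangle$
filters fluctuation amplitudes, and
$\rho(q, s) = F^q_{xy} / \sqrt{F^q_{xx} F^q_{yy}}$ is bounded in $[-1, 1]$
for $q = 1$. With $q = 1$ the coefficient de-emphasises large-amplitude
segments relative to the Pearson coefficient and thereby picks up
correlation structure that amplitude outliers mask.

Whole-cortex coupling for one session is summarised by the region ×
region matrix of $\rho(q, s)$ (or Pearson) coefficients. Across many
(subject, time-of-day, task, phase) configurations, the matrices'
eigenvectors are pooled and clustered so that eigenvalues belonging to the
*same correlation pattern* can be compared across conditions, rather than
comparing the $i$-th largest eigenvalue of one matrix with the $i$-th
largest of another, which interindividual variability can scramble.
Because $v$ and $-v$ span the same pattern, clustering uses the
reflection-aware squared distance
$\tilde d(u, v) = \min(d(u, v), d(-u, v)) = 2 - 2|u^\top v|$ for unit
vectors.

## Assumptions

* Input sessions are frames × regions matrices at a fixed TR with no
  missing values; any voxel-level preprocessing happened upstream.
* DFA assumes the polynomial order $m$ dominates the smooth trends present;
  $m = 2$ throughout (shared between DFA and DCCA, one knob).
* The periodogram estimator assumes stationarity; strong nonstationarity
  biases $\beta$ downward while leaving the DFA-based $H$ usable, which is
  why the package treats DFA as primary and $\beta$ as corroboration.
* $\rho(q, s)$ matrices need not be positive semidefinite. Negative
  eigenvalues are legitimate and never clipped; they simply fall below any
  positive selection cut-off.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| DFA detrending order $m$ | 2 | – | quadratic absorbs linear profile trends; higher orders need larger minimum scales |
| DFA scale grid | ~20 log-spaced integers in $[6, N/4]$ | frames | $6 > m + 1$ keeps the fit determined; $N/4$ leaves $\ge 8$ segments |
| DFA fit range | full grid | frames | configurable when a crossover is visible |
| PSD fit band | $[2, \lfloor N/8 \rfloor]$ | frequency index | drops the DC-adjacent bin and the high-frequency noise floor |
| $(q, s)$ | $(1, 10)$ | –, frames | $q = 1$ bounds $\rho$ in $[-1,1]$; $s = 10$ frames = 18 s at TR 1.8 s, the scale of trial dynamics |
| segmentation window | 12.0 | s | see below |
| eigenvalue cut-off | 2.0 | – | above the typical Tukey fence of a correlation spectrum; `eigenvalueFence()` reports the ensemble's own fence so the cut-off can be grounded per data set |
| clusters | 15 | – | of the order of the retained eigenvalues per configuration |

**The 12 s window.** Stimulus-locked windows are half-open,
$[t_0, t_0 + w)$, on the acquisition grid $t = k \cdot \mathrm{TR}$ with
0-based frames and the frame timestamped at acquisition start. A 10 s
window on a 1.8 s grid yields 5–6 frames, which is incompatible with
per-trial blocks of 6–7 frames concatenating to 400 frames over 60 trials;
$w = 12$ s yields exactly 6–7 frames per trial and a 400-frame total on
the default schedule, so 12 s is the default and the window remains
configurable. An optional onset shift (default 0) can model a
haemodynamic-lag offset; it is exposed rather than guessed.

**Fitting order.** Exponents are fit on session-averaged curves
$\langle F(s)\rangle$, $\langle S(f)\rangle$ (the pipeline's choice);
fitting per session and averaging exponents is available by applying
`fitScaling()` to individual curves. The averaged-curve route reduces the
fit's variance without tapering or Welch smoothing, keeping the estimator
itself exactly the raw periodogram / plain DFA.

## The synthetic-data module

The generators provide ground truth for every downstream stage:

* `generateFGN()` — fractional Gaussian noise by circulant embedding of
  the exact autocovariance
  $\gamma(k) = \tfrac12(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})$. The
  embedding of size $2n$ is checked for non-negative eigenvalues and
  doubled (up to three times) before failing with an explicit error.
  Exactness keeps recovery tests tight: the estimator, not the generator,
  is on trial.
* `generatePowerLawSignal()` — Fourier amplitudes $\propto f^{-\beta/2}$
  with i.i.d. uniform phases. This is the only route to $H > 1$, since
  stationary fGn is confined to $H < 1$; regions with target $H \ge 1$ use
  it with $\beta = 2H - 1$.
* `generateCoupledPair()` — $y = \rho x + \sqrt{1 - \rho^2}\, e$ with $x,
  e$ independent fGn($h$). Both marginals are exactly fGn($h$) and the
  expected Pearson coupling is $\rho$, including negative values; the
  symmetric shared-latent construction was rejected because it cannot
  reach $\rho < 0$.
* `generateROISurrogate()` — per region $r$ in block $b$:
  $x_r = \sqrt{1 - c_b}\, e_r + \sqrt{c_b}\, z_b$ with a latent $z_b$
  generated at the block's mean Hurst target. Within-block Pearson level
  is $c_b$, between-block 0. When members' $H$ targets differ from the
  block mean the marginal scaling is only approximately preserved — the
  price of controlling the Pearson level exactly. Defaults emulate the
  study structure: 116 regions, TR 1.8 s, 400 frames, $H$ spanning
  0.5–1.2, eight blocks at $c = 0.6$.
* `generateEventSchedule()` — trials every 22.8 s with the probe 9.8 s
  after encoding onset. 22.8 s is $12\tfrac23$ TR, so the onset phase
  cycles with period 3 and the 12 s windows contain 7, 7, 6 frames
  (encoding) and 7, 6, 7 (retrieval), each phase concatenating to exactly
  400 frames over 60 trials. That spacing is consistent with the printed
  trial arithmetic (1.2–1.8 s stimuli, 1.2–2.2 s distractor/mask, ~6 s
  delay, 2 s probe, 8.4 s intertrial interval, fixation); onsets are
  deterministic and only the encoding stimulus duration is jittered over
  1.2–1.8 s. A resting session's length before block shuffling is a
  parameter (default 400 frames).

What the surrogates do **not** emulate: haemodynamic response convolution,
cardiac/respiratory noise, motion artefacts, spatial (voxel) structure, or
task-locked mean activation. Passing tests therefore demonstrate that the
estimators recover known temporal and cross-correlation structure at
realistic sizes — not that real BOLD data satisfy the generators'
assumptions.

## Numerical choices

* Polynomial detrending is fit on the within-segment index $1..s$, not
  absolute time; backward segments are end-anchored
  ($X(N - js + k)$, $k = 1..s$), so for $N$ a multiple of $s$ the two
  passes coincide.
* Log-log fits use base-2 logarithms (slopes are base-invariant) via
  ordinary least squares; zero curve values are excluded with a warning,
  and fewer than three usable points is an error.
* Degenerate series (vanishing detrended variance) make $\rho(q, s)$
  undefined: the package raises an error naming the region rather than
  returning a silent 0 that would contaminate matrix summaries.
* DFA with $m = 2$ has a small positive bias at the smallest scales
  (white-noise input over $[6, 256]$ reads $\hat H \approx 0.52$); this is
  a property of the estimator, shared with any faithful implementation,
  and stays well inside the ±0.05 recovery band used in the tests.
* The Ward clustering applies the `ward.D` update to the stored $\tilde d$
  values, which are already squared distances; after reflection
  minimisation $\tilde d$ is not guaranteed Euclidean-embeddable, so this
  is deliberately the stored-dissimilarity Ward rather than textbook
  Euclidean Ward.
* Deduplication ties (equal eigenvalues in one configuration) keep the
  first entry in input order; the alignment reference is the member with
  the largest eigenvalue, and the global sign of an aligned mean is
  reported only up to ±. Alignment and averaging operate on the
  deduplicated ensemble.
* The Mexican-hat scalogram pads by symmetric reflection and truncates the
  kernel at $|t| \le 8$, where the wavelet is ~1e-12, keeping the discrete
  kernel effectively zero-sum; positions within one kernel radius of an
  edge are flagged as the boundary cone and treated as display-only.
* The Scheffé comparison is implemented from its closed form
  ($F = \Delta^2 / (\mathrm{MSE}\,(1/n_1 + 1/n_2)(k-1))$ on $(k-1, N-k)$
  df); stepwise mixed-model selection is out of scope — the package emits
  tidy per-cluster eigenvalue tables any stats package can consume.

## Problem sizes

The test suite and the acceptance script run at desk scale by design:
Hurst recovery uses 100–200 replicates of length 1024–4096; estimator
closure uses $n = 4096$; oracle-equivalence checks run exact brute-force
reimplementations at $n \le 256$; the end-to-end pipeline checks use 2–3
synthetic subjects with 12–116 regions. These sizes were chosen so that
Monte-Carlo spreads are a few times tighter than the asserted tolerances.

## Known limitations

* $\beta$ estimates from single sessions are noisy (raw periodogram);
  trust the session-averaged fits or the DFA-based $H$.
* Surrogate marginals with $H \ge 1$ come from spectral synthesis and are
  periodic by construction; their endpoint artefacts are negligible for
  the scale ranges fit here but the series are not truly self-similar
  beyond the synthesis band.
* The AAL-to-network grouping shipped in `extdata` is an editable
  reporting approximation, used only to aggregate per-region summaries.
* `rho_q` with $q \ne 1$ is computed but unbounded; the package defaults
  to $q = 1$ and does not sweep $q$.
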