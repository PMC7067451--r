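---
title: "Amplitude demodulation of ventilation signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplitude demodulation of ventilation signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csrdemod)
```

## The model and its assumptions

Cheyne-Stokes respiration (CSR) shows a crescendo–decrescendo envelope
on top of the ordinary breathing cycle. `csrdemod` treats ventilation
as an amplitude-modulated (AM) signal: the carrier is the breathing
cycle at $f_c \in [0.25, 0.33]$ Hz, the modulation a slow sinusoid at
$f_m \in [8, 30]$ mHz,

$$y(t) = \mathrm{env}(t)\, H(\mathrm{env}(t)) \cos(2\pi f_c t), \qquad
\mathrm{env}(t) = A_c\left[1 + h \cos(2\pi f_m t + \varphi_m)\right],$$

with $H$ the Heaviside step. The modulation index $h \ge 0$ grades the
pattern: $h = 0$ steady breathing, $0 < h \le 1$ periodic breathing
(hypopneas only), $h > 1$ over-modulation, where the clipped envelope
is exactly zero for
$\delta = (\pi - \arccos(-1/h)) / (\pi f_m)$ seconds per modulation
cycle — a central apnea. As $h \to \infty$, $\delta \to 1/(2 f_m)$,
half the modulation period.

The model assumes locally stationary parameters (over the 2-minute
estimation window), a single dominant modulation tone, and a
single-channel, baseline-centred ventilation signal. It does not model
the cardio-respiratory control loop that generates CSR; it only
describes the waveform, which is what the estimation needs.

## Breath detection by penalized change-point analysis

Breaths are found by segmenting the raw signal at the points where its
local linear behaviour changes. We minimise, over segmentations,

$$\sum_i \mathrm{RSS}_{\text{line}}\!\left(x_{t_i : t_{i+1}}\right) + \beta K,$$

where each segment's cost is the residual sum of squares about a
straight-line fit — one coherent cost covering both the local slope
and the local mean — and $\beta > 0$ prices each additional change
point. On a breathing signal the optimum places the breaks at
inspiration peaks and expiration troughs. The search is exact: a PELT
(pruned exact linear time) dynamic program in compiled code, with a
minimum segment length of 0.5 s (half the shortest physiological
inspiration). Two implementation points deserve note: the pruning test
must exclude the penalty term, and with a minimum segment length a
pruned candidate may still be optimal for targets closer than that
length, so removals are delayed accordingly. The search is verified
against exhaustive $O(N^2)$ dynamic programming in the test suite.

**The penalty default.** $\beta$ trades missed breaths (too large)
against split breath half-waves (too small). A noise-scaled penalty
(e.g. MAD-based) collapses to zero on noiseless signals and then
over-segments, so the default scales with the robust *signal*
amplitude instead:
$\beta = 0.05 \, f_s \, s^2$, with $s$ the 95th percentile of the
absolute detrended signal. The constant was fixed once on simulator
fixtures ($h \in \{0, 0.5\}$, cycle jitter 0.1): segment costs grow
like $f_s \cdot \text{amplitude}^2$, so this one constant transfers
across sampling rates and signal scales. With it, merging a breath of
relative amplitude $a$ costs roughly $40 a^2$ units against a penalty
of $2\beta = 2.5$, so breaths remain detectable down to
$a \approx 0.25$ of the typical amplitude — below that, a hypopneic
breath is treated as part of a ventilation gap. This is the main known
limitation of the segmentation: for $h \gtrsim 0.7$ the shallowest
breaths at the envelope minimum are absorbed into the gap treatment,
which slightly over-states the modulation depth there (it never flips
a periodic-breathing recording into the apneic class in our fixtures,
because unclipped envelopes keep the fitted DC term large).

Sections with fitted |slope| below $10^{-3}$ (units of the
amplitude-normalised signal per second) are discarded as noise, and a
peak is retained only when its flanking rising + falling sections span
more than 1 s, so sub-second spikes are not breaths. The peak's
amplitude is read at the signal maximum over those flanking sections —
the change-point boundary itself lags the true maximum on asymmetric
breath shapes. Before segmentation the signal is baseline-corrected by
subtracting a 30 s running median (with reflection padding, so the
first and last breaths are not flattened) and amplitude-normalised by
the 95th percentile of the absolute signal, making the slope threshold
scale-free.

## Envelope reconstruction

Ventilation interruptions are declared wherever consecutive breath
peaks are more than 3× the median inter-peak spacing apart (strict
inequality); the envelope is forced to zero inside such gaps. Between
peaks the envelope interpolates the peak amplitudes linearly and is
resampled at `fs_env` = 1 Hz — the envelope band ends at 30 mHz, so
1 Hz leaves a 16-fold Nyquist margin while giving 120 samples per
estimation window. Peaks only (not troughs) carry the envelope, and
values are clipped at zero.

## Matrix Pencil demodulation

On each window the envelope is written as three complex exponentials,
$f_1 = 0$, $f_{2,3} = \pm f_m$, with amplitudes $a_1 = A_c$ and
$a_{2,3} = (A_c h / 2) e^{\pm j \varphi_m}$. The Matrix Pencil method
estimates poles from the generalized eigenvalue problem of the pair of
Hankel data matrices (pencil parameter $L = N/3$, the standard
noise-robust choice), truncating the SVD at order 3; amplitudes follow
by linear least squares. Then
$\hat h = (|\hat a_2| + |\hat a_3|)/|\hat a_1|$ — equal to
$2|\hat a_2|/\hat a_1$ in the symmetric case — and $\hat f_m$ is the
mean absolute frequency of the conjugate pair. On noiseless
model envelopes the recovery is exact to numerical precision
(~$10^{-13}$ over the whole pathological grid), and with envelope
noise of SD $0.05 A_c$ the median error in $\hat h$ is about 0.012.

Numerical and degenerate-input choices:

* Windows are 120 s with 80 % overlap (24 s hop); a trailing partial
  window is skipped. Results on stationary envelopes are insensitive
  to window length over 2–4 min.
* Poles may lie off the unit circle; the frequency is
  $|\arg z|/(2\pi \Delta t)$ and damping is ignored (the model is
  undamped).
* Rank collapse (fewer than 3 singular values above $10^{-8}$ of the
  largest, e.g. a constant or all-zero window) returns a reduced-order
  fit; a DC-only window gives $\hat h = 0$ and stays valid.
* An estimate is *invalid* when no pole lies within 5 mHz of DC or
  when $|\hat a_1|$ falls below 10 % of the recording's median
  envelope. The index is a ratio and diverges as the DC amplitude
  collapses; on near-constant noisy envelopes the order-3 fit
  occasionally parks a tiny amplitude on the lowest-frequency pole,
  and the floor is what keeps such degenerate fits out of the
  detection stage. (A 1 % floor proved too permissive in exactly this
  scenario.)
* Windows overlapping envelope gaps are estimated as-is: the clipped
  regime is precisely where $\hat h > 1$ is informative.

**Clipping bias.** For $h > 1$ the clipped envelope is no longer the
three-term model; the order-3 fit then measures the ratio of the
fundamental to the DC Fourier coefficient of
$\max(0, 1 + h\cos\theta)$. For $h = 1.5$ that ratio is 1.2275 — the
estimate is biased low relative to the generating $h$, but stays above
1, so the apnea decision survives. Individual 120-s windows cover only
1.2 modulation cycles at $f_m = 10$ mHz and scatter visibly with
window phase; the track median is the stable summary and agrees with
the quadrature value to < 0.01.

## Detection and classification

A window is pathological when valid, $\hat h \ge h_0 = 0.12$ and
$\hat f_m \in [8, 30]$ mHz — both inclusive, since only the bare
values are prescribed. Maximal runs of pathological windows become
zones spanning first window start to last window end; zones shorter
than 60 s are discarded (persistence against short false positives)
and zones separated by less than one hop are merged, so a single
invalid window inside an episode does not split it. With $T$ the total
zone time, $E$ the longest zone and $\bar h$ the duration-weighted
mean of per-zone mean $\hat h$: $T > 600$ s and $E \ge 360$ s gives
CSR-CSA if $\bar h > 1$, else periodic breathing; otherwise non-CSR.
The parenthetical cycle counts that accompany these durations in
clinical guidance are treated as commentary on the durations at the
slowest pathological $f_m$, not as an independent rule. For overnight
recordings the total-duration rule can be applied per hour
(`per_hour = TRUE`); the default suits half-hour laboratory
recordings.

## The simulator, and what passing its tests shows

`build_recording()` concatenates piecewise-constant regimes with a
modulation phase that is continuous across boundaries (no spurious
envelope jumps from phase resets), an optional breath-shaped carrier —
a raised half-sine inspiration over 40 % of the cycle followed by a
longer expiration half-sine, with per-cycle period jitter — additive
Gaussian noise, and per-minute ground truth (a minute is *oscillating*
when ≥ 30 s of it lies in a regime with $h \ge 0.12$ and in-band
$f_m$). The pure-cosine carrier makes segmentation trivially easy, so
the breath-shaped carrier is the default fixture hardening.

The simulator emulates: AM structure with clipping apneas, breath
asymmetry and cycle irregularity, wideband sensor noise. It does not
emulate: baseline wander and movement artifacts, obstructive events,
amplitude drift between regimes, erratic non-periodic breathing, or
multi-tone envelopes. Passing the simulator-based tests therefore
demonstrates correctness of the algorithms under the model's own
assumptions — not clinical performance on hospital recordings, which
no distributed data allows us to measure.

Validation problem sizes were chosen to keep the whole suite and the
acceptance script comfortably within a coffee break on one CPU:
30-minute recordings at 25 Hz (the carrier at ≤ 0.33 Hz is still
75-fold oversampled; clinical acquisitions at 200 Hz are handled
identically), 15-recording diagnosis cohorts and 10-recording ROC
cohorts.

## Evaluation choices

Minute-level scoring compares zone coverage (≥ 30 s of a minute, the
majority rule) against per-minute reference labels; reference minutes
marked *erratic* are excluded from the binary scores and tallied
separately. Two "specificity" variants are reported side by side:
`sp_as_printed` $= TP/(TP+FP)$ (a positive predictive value, kept
under the name its formula is usually printed with in this
literature) and `specificity_conventional` $= TN/(TN+FP)$. ROC
threshold selection uses the conventional variant — a ROC axis is
undefined without a TN-based quantity — sweeping $h_0$ over a grid,
rebuilding zones and minutes per recording at each value, and
returning the smallest grid value that maximises the Youden index.
On the default noisy ROC cohort (whole-recording oscillations at
$h \in [0.3, 1.5]$ against whole-recording normals, noise SD 0.05)
the selected threshold lands at 0.14–0.18 depending on the seed,
bracketing the operational default of 0.12.

One measured limitation is worth stating plainly: on the mixed
15-recording diagnosis cohort the per-minute *sensitivity* is 100 %
and the three-class confusion matrix is exactly diagonal, but the
per-minute conventional specificity sits near 94 %. All false-positive
minutes are single transition minutes at oscillation-episode
boundaries: a 2-minute window overlapping an episode by as little as
20 s is decisively pathological (at $h = 1.5$ such windows estimate
$\hat h$ of 0.5–1.8), and the zone inherits the window's full
support. This window-support smearing is intrinsic to scoring 2-min
windows on a 1-min grid; shortening the window would trade it against
estimation variance in the 8 mHz band, where a 120 s window already
spans less than one modulation cycle.

## Tunables

| parameter | default | units | role |
|---|---|---|---|
| `beta` | auto ($0.05 f_s s^2$) | cost units | change-point penalty |
| `min_seg_s` | 0.5 | s | minimum change-point segment |
| `slope_min` | 1e-3 | 1/s | noise-section threshold (normalised signal) |
| `min_section_s` | 1.0 | s | minimum flanking span of a breath peak |
| `gap_factor` | 3 | — | gap rule vs median inter-peak spacing |
| `detrend_s` | 30 | s | running-median baseline window |
| `fs_env` | 1 | Hz | envelope resampling rate |
| `window_s`, `overlap` | 120, 0.8 | s, — | sliding estimation grid |
| `pencil_ratio`, `order` | 1/3, 3 | — | Matrix Pencil geometry and model order |
| `amplitude_floor_frac` | 0.1 | — | validity floor on $|\hat a_1|$ |
| `h0`, `f_band` | 0.12, [8, 30] mHz | — | pathological window rule |
| `min_zone_s` | 60 | s | zone persistence |
| `total_min_s`, `episode_min_s`, `h_apnea` | 600, 360, 1 | s, s, — | diagnosis rule |
| `min_cover_s` | 30 | s | zone-to-minute majority rule |

All of them live in `csr_control()`, which validates ranges, rejects
unknown keys, and round-trips through YAML for reproducible runs.
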