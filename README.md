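# csrdemod

Early detection of Cheyne-Stokes respiration (CSR) and periodic
breathing from single-channel ventilation recordings, by amplitude
demodulation.

CSR is a sleep-disordered breathing pattern — cyclic
crescendo–decrescendo tidal volume alternating with central
hypopneas/apneas — prevalent in severe heart failure and associated
with worse prognosis. Its early stage, periodic breathing, produces
only hypopneas and is easy to miss with event-counting measures such
as the apnea–hypopnea index. `csrdemod` is aimed at researchers and
engineers working with polygraphy/polysomnography ventilation signals
(pneumotachograph flow, thoracic belts) who want a continuous,
quantitative index of the oscillation rather than an event count.

## The model

Ventilation is modelled as an amplitude-modulated carrier. The carrier
is the breathing cycle at rate *f<sub>c</sub>* ∈ [0.25, 0.33] Hz; the envelope
oscillates at the much slower rate *f<sub>m</sub>* ∈ [8, 30] mHz:

    y(t) = env(t) · H(env(t)) · cos(2π f_c t),
    env(t) = A_c [1 + h cos(2π f_m t + φ_m)]

where *h* ≥ 0 is the **modulation index** and *H* the Heaviside step.
For *h* ≤ 1 the envelope never clips: steady breathing (*h* = 0) or
periodic breathing (0 < *h* ≤ 1). Over-modulation (*h* > 1) clips the
envelope at zero — a central apnea of duration
δ = (π − arccos(−1/h)) / (π f<sub>m</sub>) once per modulation cycle.

The pipeline estimates (*Â<sub>c</sub>*, *ĥ*, *f̂<sub>m</sub>*) directly from a raw
recording:

1. **Breath detection** — exact penalized change-point segmentation
   (linear-fit cost, PELT search in C++) puts breaks at inspiration
   peaks and expiration troughs; near-flat sections and sub-second
   spikes are discarded.
2. **Envelope reconstruction** — linear interpolation through breath
   peak amplitudes, resampled at 1 Hz; ventilation interruptions
   (inter-breath spacing > 3× the median) zero the envelope.
3. **Matrix Pencil demodulation** — on sliding 2-minute windows (80 %
   overlap) an order-3 complex-exponential fit (DC + conjugate pair)
   gives *ĥ* = 2|â₂|/â₁ and *f̂<sub>m</sub>* = |f̂₂|.
4. **Detection & diagnosis** — windows with *ĥ* ≥ 0.12 and *f̂<sub>m</sub>* in
   [8, 30] mHz, persisting ≥ 1 minute, form oscillation zones; a
   recording with > 10 min of zones (one episode ≥ 6 min) is classified
   CSR-CSA if the mean zone *ĥ* exceeds 1 (apneas), otherwise periodic
   breathing; anything less is non-CSR.

A simulator generates annotated synthetic recordings under exactly this
model (plus breath-shaped carriers, cycle jitter and noise) and is the
basis of all validation; no clinical data ships with the package.

## Worked example

Simulate a 15-minute recording that drifts from normal breathing into
early periodic breathing (*h* = 0.5) and then severe CSR (*h* = 1.5),
and demodulate it:

```r
library(csrdemod)
sched <- csr_schedule(start_s = c(0, 120, 660), end_s = c(120, 660, 900),
                      h = c(0, 0.5, 1.5), f_m = 0.01)
rec <- build_recording(sched, fs = 25, noise_sd = 0.02, breath_jitter = 0.05,
                       carrier = "breath", seed = 17)
fit <- csr_demod(rec)
summary(fit)
#> Recording: 900 s, 243 breaths (median interval 3.32 s), 3 gap(s)
#> Estimation: 33 windows, 100% valid, h_hat in [0.000, 7.820]
#> Oscillation zones:
#>  start_s end_s   mean_h    max_h
#>       96   888 1.141262 7.819635
#> Diagnosis: CSR_CSA
#>   oscillation: 792 s total, longest episode 792 s, 1 zone(s)
#>   mean modulation index over zones: 1.14
round(coef(fit), 4)
#>  h_bar    f_m    A_c
#> 1.1413 0.0101 1.2650
```

The breaths come 3.3 s apart (carrier ≈ 0.3 Hz); the envelope
oscillates at *f̂<sub>m</sub>* ≈ 10 mHz, matching the simulated 0.01 Hz. The
single zone covers the modulated regimes, and its duration-weighted
mean modulation index h̄ = 1.14 > 1 indicates over-modulation — i.e.
apneas — so the recording is classified CSR-CSA. `plot(fit)` draws the
signal with detected breaths and envelope, the *ĥ* track against the
0.12 threshold, and the *f̂<sub>m</sub>* track against the pathological band.

A command-line front end with `simulate`, `envelope`, `run`,
`evaluate` and `roc` subcommands lives at
`system.file("cli", "csr.R", package = "csrdemod")`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","csr.R",package="csrdemod"))') \
    run --input rec.csv --out-prefix rec
```

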