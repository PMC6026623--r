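---
title: "Regional dominant frequency and wave break rate: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional dominant frequency and wave break rate: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdfwave)
```

## The model

A circular mapping catheter records around ten bipolar intracardiac
electrograms (IEGMs) simultaneously from a region roughly 2.5 cm across.
During atrial fibrillation the activation delays between those channels
are time-varying: an organized wavefront activates all channels within a
few milliseconds of each other, while during a wave break the common
wavefront is lost and activations disperse across the cycle. The package
turns this into a scalar time series and two site-level metrics:

* each channel is conditioned into a smooth nonnegative **activation
  envelope** (band-pass, rectification, Gaussian smoothing, peak
  normalization) that marks *when* the channel is active without
  estimating activation times, which are notoriously unreliable for
  fractionated electrograms;
* the envelopes are **averaged** — the central modeling step. Aligned
  pulses reinforce into one tall peak per wavefront at the activation
  rate; dispersed pulses average into several small peaks whose spectral
  content sits well above the activation rate;
* the average is smoothed by a **two-sided exponential FIR kernel**
  `h[n] = exp(−|−1+(n−1)/90|)`, n = 1…180 (≈ 88 ms at 2034.5 Hz). Its
  low-pass response preserves the once-per-wavefront periodicity and
  suppresses the multi-peak break content, so that during a break the
  envelope loses its dominant oscillation;
* the **instantaneous regional dominant frequency** iRDF(t) is the
  argmax over 0.1–20 Hz of the short-time power spectrum of the
  mean-removed result (1-s Hanning windows, 95 % overlap), and
  **RDF** is the upper quartile of iRDF over the analyzed duration —
  robust to the transient drops that breaks cause;
* a **wave break** is a drop of iRDF more than 3 Hz below the RDF (or
  below 0.5 Hz) lasting longer than 100 ms; **WBR** is the number of
  such events per second.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `stft.window_s` | 1.0 | s | time/frequency trade-off; 1 s is short enough to see 100-ms-scale breaks |
| `stft.overlap` | 0.95 | – | 50-ms frame hop, the native resolution of event timing |
| `stft.grid_hz` | 0.05 | Hz | frequency grid; a 1-s window alone resolves only 1 Hz, the fine grid recovers sub-Hz peak position |
| `band_hz` | 0.1–20 | Hz | DF search band; extends below the 0.5-Hz floor so the floor trigger is observable, and above any physiological AF rate |
| `preprocess.band_hz` | 40–250 | Hz | deflection energy of bipolar atrial electrograms |
| `preprocess.sigma_s` | 0.02 | s | envelope pulse width, matching the ~tens-of-ms activation complex |
| `wb.drop_hz` / `wb.floor_hz` / `wb.min_dur_s` | 3 / 0.5 / 0.1 | Hz, Hz, s | the empirical wave-break definition |
| `fir` | 180 taps | – | fixed kernel; gain is irrelevant because argmax is scale-invariant |

The hop is 50 ms, so the strict `> 100 ms` duration gate requires at
least three consecutive below-threshold frames; an event's span is
`n_frames × hop`. Runs separated by a single recovered frame are distinct
events (no merge gap).

## Numerical choices

* **Spectral estimation.** The windowed spectrum is evaluated as the
  exact discrete-time Fourier transform on the 0.05-Hz grid (two real
  matrix products against cosine/sine bases). A heavily zero-padded FFT
  approximates the same estimator on an awkward grid; the exact grid
  keeps test tolerances meaningful. An independent brute-force
  direct-summation DFT serves as the oracle in the unit tests.
* **Frames** are placed on the hop grid in time and must lie wholly
  inside the signal, so `n_frames = floor((duration − T)/hop) + 1`
  holds exactly; timestamps are window centers.
* **Argmax ties** break toward the lowest frequency (deterministic).
* **Percentiles** (RDF, patient quartile flags) use the
  linear-interpolation convention (R's type 7) throughout, so
  `rdf(c(4,5,6,7)) = 6.25`.
* **Zero-phase filtering** uses forward–backward Butterworth with 0.5-s
  reflect padding; FIR smoothing is same-length convolution centered on
  the kernel maximum (no group delay).
* **Degenerate inputs.** Silent (all-zero) channels produce a flagged
  all-zero envelope/iEDF with a warning rather than an error, keeping
  the averaging denominator fixed; constant color ranges map every site
  to index 0 with a warning; patients with fewer than four sites get no
  quartile flags.

## The synthetic generator

`simulate_segment()` emulates what the method assumes about AF
electrograms: periodic wavefronts at a base rate (3.5–7.5 Hz is the
physiological fibrillatory range), per-channel activation offsets of
σ = 5 ms while organized, biphasic derivative-of-Gaussian deflections
(~8 ms) with ±20 % amplitude jitter and occasional short fractionated
complexes (probability 0.1), plus white noise at 10 dB SNR. All
randomness flows from one integer seed; a fixed seed reproduces a
segment bitwise.

A **wave-break episode** is rendered as the loss of the common
wavefront: within the episode interval each channel's activation time is
drawn with the much larger spread σ = 80 ms, *confined to the episode*
(the episode is by definition the interval of disorganization), and the
activation is rendered as a prolonged fractionated complex (3–5
sub-deflections at 8–15 ms spacing with amplitude decay 0.85). The
morphology change matters: timing dispersal alone conserves each
channel's envelope mass, so the averaged envelope during a dispersed
episode would keep the same local mean as organized segments and the
break would leave no deterministic low-frequency signature — its
detectability would ride on periodogram noise. Disorganized conduction
in real atria produces prolonged fractionated electrograms, and
rendering that morphology raises the local envelope mass during the
episode, which is precisely the low-frequency anomaly that survives the
FIR filter and pulls the iRDF down. With both ingredients the pipeline
recovers injected episode counts exactly (tested for 0–3 episodes and,
in the worked example, for two episodes only 0.5 s apart).

What the generator does **not** model: biophysical wavefront curvature
or tissue substrate, catheter contact and motion artifacts, far-field
ventricular components, baseline drift, respiration, and real AF's
cycle-length variability (wavefronts are exactly periodic so that
frequency-recovery assertions can be tight). Passing tests therefore
demonstrate that the estimators recover the constructs they are defined
on — not that those constructs capture every property of clinical
recordings.

## Statistics and duration analysis

`stability_curve()` answers the practical question of minimum recording
duration: for each candidate duration D the metric is recomputed from
only the first D seconds of each segment and Pearson-correlated against
the gold-standard duration (30 s for RDF, 50 s for WBR), with 95 %
confidence intervals from the Fisher z-transform (the CI method is a
standard choice; it degenerates to [r, r] at |r| = 1). A duration is
considered sufficient once r exceeds 0.85. On a 100-segment stationary
synthetic cohort the correlation between RDF(4) and RDF(30) is ≈ 1,
consistent with 4 s sufficing for stationary activity; real AF is only
quasi-stationary, so clinical thresholds must come from clinical data.

`cohort_stats()` wraps the standard reporting utilities — Spearman rank
correlation between RDF and WBR, Mann–Whitney comparison between two
patient groups, Anderson–Darling normality checks, mean ± sd summaries —
as library calls (`stats::cor.test`, `stats::wilcox.test`,
`nortest::ad.test`), not re-derivations.

## Design decisions that were genuinely open

* **The FIR kernel formula** as printed in the method's description is
  typographically corrupted; the implemented reading
  `exp(−|−1+(n−1)/90|)` is two-sided, exponential, 180 taps long and
  peaks at 1 mid-kernel, matching every stated property. The one-sample
  asymmetry between taps 1 and 180 is kept as the formula gives it. The
  kernel gain is not normalized — the subsequent argmax is
  gain-invariant.
* **Conditioning realization.** The envelope construction (40–250 Hz
  corners, σ = 20 ms, per-channel normalization) is a concrete
  realization of "smooth Gaussian-shaped pulses marking active
  intervals"; corners, σ and normalization are exposed in the
  configuration for sensitivity analysis.
* **Quartile conventions.** "Upper quartile range" is read inclusively
  (RDF ≥ Q3, WBR ≤ Q1, ties in); the duration gate "> 100 ms" is read
  strictly. Both choices are pinned by tests so changing them is a
  visible, deliberate act.
* **Per-segment problem sizes** used by the test-suite and the
  acceptance script (30-s segments, 100-segment cohorts, 1000 null
  simulations for the Mann–Whitney calibration) were chosen as the
  smallest sizes at which the statistical assertions are stable.

## Known limitations

* Averaging across the catheter trades spatial resolution for
  robustness: one metric per ~2.5-cm region.
* WBR needs long recordings (~25 s) to stabilize; RDF stabilizes within
  a few seconds.
* The wave-break definition is empirical (3 Hz / 0.5 Hz / 100 ms); the
  package treats the thresholds as configuration, not truth.
* The 64-level color scale is relative per patient and metric; maps from
  different patients are not comparable by color.
* iRDF is grid-quantized (0.05 Hz); assertions at ± one grid step are
  the tightest meaningful ones.
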