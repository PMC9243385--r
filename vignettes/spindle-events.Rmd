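---
title: "Detecting multichannel spindle events: models, parameters and design choices"
author: "spindleloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting multichannel spindle events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Sleep spindles are waxing-and-waning 9–15 Hz oscillations of N2 sleep that
appear quasi-simultaneously over many EEG sensors, MEG sensors, or — after
source reconstruction — cortical parcels. Because sensors and parcels do not
map onto each other one-to-one, `spindleloc` analyses spindles at two
levels: per-channel *spindle intervals*, and cross-channel *spindle events*
that can be compared between detection modalities. This vignette documents
the underlying models, every tunable parameter, the synthetic data the
package is validated on, and the design decisions taken where the procedure
admitted more than one reading.

## 1. The per-channel detector

For a channel $x(t)$, band-pass filtered to the spindle band, we convolve
with a complex Morlet wavelet centered at the band midpoint $f_c$. The
wavelet's Gaussian amplitude response in the frequency domain is constrained
to have full width at half maximum equal to the band width $B$:

$$\sigma_f = \frac{B}{2\sqrt{2\ln 2}}, \qquad
  \sigma_t = \frac{1}{2\pi\sigma_f}.$$

For the fast band (12–15 Hz) this gives $f_c = 13.5$ Hz,
$\sigma_f \approx 1.274$ Hz and a temporal envelope of
$\sigma_t \approx 0.125$ s. A single wavelet suffices — no filter bank —
because the FWHM-defined response already spans the band; the band edges sit
at exactly half the center response, which the test suite verifies
empirically to within 2%. The kernel is truncated at $\pm 5\sigma_t$ and
normalized so that a sinusoid of amplitude $A$ at $f_c$ yields a
steady-state output of $A$; convolution is FFT-based, and the
`n_boundary` attribute flags (but does not exclude) the samples influenced
by zero padding at the edges.

The coefficient magnitude is smoothed with a centered 0.1 s moving average
(`smooth_s`), shrinking at the series edges rather than padding. Detection
then thresholds the **smoothed wavelet energy** (the squared smoothed
amplitude): samples with

$$a(t)^2 > m \cdot \operatorname{median}\!\big(a^2\big), \qquad m = 9$$

that persist for at least `min_dur_s = 0.4` s form a spindle interval.

**Why energy rather than amplitude.** The 9× multiplier could in principle
apply to the amplitude itself. It cannot, on signal-processing grounds: for
narrow-band Gaussian background the envelope is Rayleigh-distributed with
median $\approx 1.02\times$ the band RMS, so a 9×-median *amplitude*
threshold sits near 9× the background RMS — above the peak envelope that
even a strong (10× RMS) spindle reaches after the wavelet's
$\sigma_t = 0.125$ s temporal smearing. An amplitude-thresholded detector
at $m = 9$ is inert. On the energy, $m = 9$ corresponds to 3× the median
amplitude ($\approx 3.5\sigma$ of the envelope), which detects strong
bursts reliably while keeping the background false-alarm rate low; it is
also consistent with measuring spindle duration on the wavelet *energy*
(below). The package therefore thresholds energy, and
`detect_channel()` documents this.

Further detector conventions:

* **Median scope.** The median is computed per channel over the entire
  stage-restricted series. Both the threshold and the amplitude scale
  linearly with the input, so detection is invariant under global rescaling
  $x \mapsto c\,x$ — thresholds transfer across amplifier gains and inverse
  solutions. This invariance is tested exactly.
* **Strict inequality; no merging.** Ties at the threshold end a run (so a
  constant series yields nothing), and supra-threshold runs separated by
  any sub-threshold gap remain distinct intervals.
* **Detection point.** The time of maximum smoothed amplitude within the
  run; `peak_amp` is the amplitude there.

**Duration.** Within a 2 s epoch (`dur_epoch_s`) centered on the detection
point, duration is the width of the contiguous region where the energy
$a(t)^2$ stays at or above half its peak, clipped at the epoch edge when no
half-crossing exists on one side. For a Gaussian amplitude envelope of
standard deviation $\sigma_t$ the closed form is
$2\sqrt{2\ln 2}\,\sigma_t/\sqrt{2}$, which the tests recover within 5%.

**Threshold calibration.** `calibrate_threshold()` applies Otsu's criterion
to a 256-bin histogram of pooled amplitudes: the absolute threshold
maximizes the between-class ("spindle" vs. "non-spindle") variance. When
well-separated classes leave the criterion flat across an empty histogram
gap, the plateau center is returned (the usual convention). The Otsu
*effectiveness* (between-class over total variance at the optimum) is
reported, with values below 0.8 flagged `low_separation` — a unimodal
amplitude distribution still has a maximizer, but the resulting multiplier
should not be trusted blindly.

## 2. From intervals to spindle events

Detections become a binary channels × samples matrix $y$ (half-open
intervals; overlaps union). The aggregate $Y(t) = \sum_i y_i(t)$ counts
simultaneously detecting channels. Events are local maxima of $Y$ smoothed
with a 0.5 s moving average (`smooth_s`), subject to:

* **Minimum separation** `min_peak_dist_s = 0.5` s. Competing maxima are
  resolved highest-first; exact ties keep the earlier maximum, and plateau
  maxima are located at the plateau's center sample (both unspecified in
  the underlying procedure; fixed here for determinism).
* **Minimum extent** `min_extent_frac = 0.01`: maxima whose *smoothed*
  height falls below $\lceil 0.01 \cdot N_\text{channels}\rceil$ are
  discarded as spurious. Applying the floor to the smoothed series — the
  series the maxima live on — matters: isolated single-channel noise runs
  barely longer than 400 ms smooth to a peak below 1 and are rejected,
  whereas a raw-extent floor of 1 would promote every such run to an
  event. The package's null-rate test quantifies the consequence: on pure
  1/f background at default settings the event-level false-alarm rate
  stays below one per minute. Only a lone detection lasting at least the
  full 0.5 s smoothing window can still form a single-channel event.
* **Windows.** Each surviving maximum defines a 1 s window (`window_s`),
  clipped at the record edges. The event's spatial extent is the maximum of
  the *raw* $Y$ inside the window (the peak number of co-detecting
  channels), and its channel set is every channel with $y = 1$ anywhere in
  the window.
* **Seams.** Stage extraction concatenates non-contiguous 30 s epochs;
  events whose window crosses a concatenation seam are flagged
  (`seam_crossing`) and their extent is computed only within the
  seam-bounded segment containing the center.

Event density is events per minute of analyzed sleep, making recordings of
different length comparable.

## 3. Comparing event lists across modalities

Two events are compatible when their windows overlap by at least
`overlap_frac` of the nominal window length — the denominator is the fixed
1 s window, so the default 20% means ≥ 0.2 s of shared time. Matching is
one-to-one: candidate pairs are taken in descending overlap (ties broken by
earlier centers), but a pair is only fixed if a maximum-cardinality
matching remains achievable, checked via bipartite matching
(`igraph::max_bipartite_match`). Plain greedy selection is *not* maximum —
with reference events at 0.0 and 0.6 s and test events at 0.55 and 1.2 s it
fixes the single largest overlap and strands both remaining events — and a
matching that leaves compatible pairs unmatched would understate agreement;
the constrained form keeps the intuitive "largest overlaps first" behavior
at full cardinality, and the tests verify equality with exhaustive
enumeration on every random instance.

Scores follow $f_P = TP/(TP+FP)$, $f_R = TP/(TP+FN)$,
$F_1 = 2 f_P f_R/(f_P+f_R)$ ($F_1 = 0$ when $TP = 0$). When both lists are
empty all scores are 1 — a recording without spindles, reproduced
perfectly, should not be penalized; when exactly one list is empty the
undefined ratio is set to 0. Swapping the lists swaps $f_P$ with $f_R$ and
FP with FN and leaves $F_1$ unchanged. When scores are aggregated over
several recordings, both micro-averaging (pooled counts) and
macro-averaging (mean of per-recording scores) are defensible; the package
reports per-comparison scores and leaves aggregation to the caller, who
should label which average they use.

Matched extents are compared by OLS of test on reference extent
(`extent_correlation`, requiring ≥ 3 pairs and nonzero variance). Events
unique to the test list are located with `fp_topography` (percent of FP
events involving each channel) and validated with `fp_sigma_power`: the
other modality's recording is band-passed to the spindle band, per-sample
power is the squared magnitude of the analytic signal, each FP window's
mean power (over time and channels) is z-scored against `n_baseline = 100`
randomly placed spindle-free windows of the same length — non-overlapping
with every event window and with each other, sampled without replacement
under a required seed — and `z > 1.69` (one-sided 5%) counts as elevated
sigma power. An FP with elevated sigma power likely reflects sub-threshold
spindle activity rather than a detector artifact.

## 4. Test-retest reliability

With a balanced design of $n$ subjects × $k$ sessions, the one-way
random-effects ANOVA gives $\hat\sigma^2_w = MS_w$ and
$\hat\sigma^2_b = \max\{0, (MS_b - MS_w)/k\}$; the ICC is
$\hat\sigma^2_b/(\hat\sigma^2_b+\hat\sigma^2_w)$ (0 when both vanish).
The closed-form method-of-moments estimator is preferred over an iterative
mixed-model fit because it is exactly testable and coincides with the
random-intercept model in the balanced case. Truncating the between
component at zero keeps the ICC in $[0,1]$; the estimator is invariant
under shifting or positively rescaling all densities.

The 95% CI resamples *subjects* with replacement (preserving the
within-subject session pairing) 1,000 times and takes the 2.5th/97.5th
percentiles, clipped to $[0,1]$. Resampling rows instead of subjects would
break the pairing that the ICC measures. The interval is reported as a pure
percentile interval — it is not widened to contain the point estimate, and
with `n_boot = 1` it degenerates to the lone resample's ICC. Coverage at
the study's scale (25 subjects, true ICC 0.8) is verified by simulation in
the test suite.

## 5. Source-label sign alignment

Dipole orientations fixed perpendicular to a folded cortical surface make
the sign of each within-parcel time course arbitrary, so plain averaging
cancels. `sign_align_average()` computes the SVD of the dipoles × samples
matrix; the first left singular vector holds one loading per dipole, and
rows whose loading sign disagrees with the largest-magnitude loading are
inverted before averaging (simple average, no singular-value weighting).
The SVD's global sign is arbitrary, so the output is defined up to one
global sign; referencing flips to the dominant loading makes the result
deterministic, and tests compare up to sign against a power-iteration
oracle. `aggregate_labels()` applies this per parcel via a manifest mapping
dipole rows to labels.

## 6. The synthetic-data generator

`generate_recording()` emulates exactly the statistical structure the
detector assumes — and nothing more:

* **Background**: per-channel $1/f^{\gamma}$ noise (default $\gamma = 1$)
  via FFT spectral shaping of white Gaussian noise, seeded and
  bit-reproducible; the measured spectral slope over 1–40 Hz matches
  $\gamma$ within ±0.2.
* **Bursts**: Hanning-windowed sinusoids (spindles wax and wane), default
  1 s at 13.5 Hz, with envelope peak = `amplitude_mult` × the channel's
  background sigma-band RMS × the modality gain. Anchoring amplitude to the
  per-channel band RMS makes the detector's scale invariance carry
  thresholds across channels and modalities. The default fixture is 100
  channels at 200 Hz for 10 min with 20 group-bursts at 10× and extents
  3–20 channels.
* **Modalities**: a `modality_profile` is a per-channel gain vector;
  `generate_two_modality_pair()` renders the same noise and bursts under
  two profiles, so unique-vs-common event counts are known by construction
  (identical profiles ⇒ F1 = 1; disjoint gain supports ⇒ F1 ≈ 0; a profile
  blind to half the bursts ⇒ recall ≈ 0.5).

What it does **not** emulate: realistic spindle morphology (frequency
chirps, asymmetric envelopes), volume conduction and field spread (bursts
land on channels independently, with no spatial correlation in the
background either), artifacts, stage dynamics, or forward/inverse physics.
Passing the recovery tests therefore shows the pipeline is correct on its
own model assumptions — not that those assumptions hold for any given real
recording.

## 7. Numerical conventions and degenerate inputs

* Time is in seconds, samples are 0-based at `t0`, and all intervals are
  half-open $[start, end)$; sample $k$ (1-based) lives at $(k-1)/f_s$.
* Moving averages use odd-length centered windows with edge truncation.
* Zero-phase filtering is forward–backward Butterworth (high-pass order 2 —
  stable at 0.3 Hz even at 600 Hz sampling — cascaded with low-pass order
  4, giving > 20 dB one octave above a 35 Hz edge). Resampling decimates
  directly when the ratio is integral (the pass-band lies below the output
  Nyquist by precondition) and interpolates linearly otherwise.
* The raw container stores float64 by default (bit-exact round trips);
  float32 is available where storage matters. EDF output quantizes to 16
  bits over a symmetric per-channel physical range that is encoded in the
  header's ASCII fields *before* scaling, so a round trip errs by at most
  one quantization step; EDF files with unequal per-signal rates are
  rejected. The EDF support is deliberately minimal (EDF, not EDF+).
* Degenerate inputs fail loudly and early: empty channel sets, bands
  outside Nyquist, signals shorter than the wavelet support, all-zero label
  matrices, single-valued calibration input, unbalanced ICC designs, and
  baseline sampling with insufficient spindle-free time are all explicit
  errors. Stochastic steps (baseline placement, bootstrap, simulation)
  require seeds and restore the caller's RNG state.

## 8. Problem sizes used in validation

The test suite favors many small seeded replicates over few large ones:
detector-oracle equivalence on fifty 10 s signals; scale invariance at
gains 0.1–1000; the full 100-channel, 10 min fixture for end-to-end event
recovery; 200 random instances against the exhaustive matching oracle;
ICC parameter recovery at 200 subjects and bootstrap coverage at 25
subjects × 200 replicates; 50-window sigma-power simulations; 100 random
label matrices for sign alignment. These sizes were chosen so each property
is measured with enough replication to be stable while the whole suite
remains quick to run.

## 9. Known limitations

* **The 400 ms rule is soft near threshold.** The supra-threshold run
  length of a burst is its smeared envelope's crossing width, and the
  wavelet's $\sigma_t \approx 0.125$ s plus background fluctuations
  dominate that width for bursts near the minimum duration. At realistic
  amplitudes (≈ 10× band RMS) the detector separates 1 s bursts from
  0.35 s bursts cleanly, but 0.45 s bursts fall in a noise-dominated
  transition zone: the duration cut-off is not a sharp classifier at the
  0.1 s scale, and the test suite documents this honestly rather
  than asserting otherwise.
* **Residual spurious events.** Single-channel background runs outliving
  the 0.5 s aggregate smoothing window still form events (well under one
  per minute at default settings, but nonzero). With hundreds of channels
  the 1% extent floor rises above one channel and suppresses these, as in
  parcellated source space (448 regions ⇒ floor 5); at ~100 channels the
  floor is 1 and exact event counts on long recordings should not be
  expected.
* **Percentile bootstrap CIs** can slightly undercover at small n; the
  coverage simulation bounds this at the study's scale but other designs
  should re-check.
* The detector assumes the spindle band was chosen sensibly for the data;
  no individualized band adaptation is provided, and slow-oscillation
  coupling, propagation patterns and within-event phase structure are out
  of scope.
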