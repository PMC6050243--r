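---
title: "Analysing the timing of electric organ discharges: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing the timing of electric organ discharges: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spitrain)
```

## The scientific problem

Mormyrid weakly electric fish emit brief, stereotyped electric organ
discharges (EODs). The waveform of a single EOD is species-specific and
fixed; the *timing* of successive EODs — the sequence of pulse intervals
(SPI) — is under volitional control and is a candidate carrier of
communication information. `spitrain` implements the statistical toolchain
for asking whether SPI timing is structured (species-specific interval
distributions, memory in the interval sequence) and whether receivers use
it (two-choice playback preference).

The pipeline operates on pulse *timestamps only*; waveform analysis and
playback synthesis are out of scope.

## Core quantities

**Inter-pulse-intervals.** For pulse times \(t_i\) (seconds), the interval
sequence is \(IPI_i = t_i - t_{i-1}\), reported in milliseconds. Interval
analyses operate on a declared analysis window, by default the first
120 s of a recording. Which excerpt of a longer recording is analysed is a
study decision, so the window start is a parameter rather than a constant.
Windows are half-open \([start, start+length)\) so adjacent windows never
share an event.

**Five-variable SPI summary.** Per windowed train: total EOD count; the
number of runs; the mode IPI; and the longest and shortest interval. The
mode is the centre of the tallest bin of the 2-ms interval histogram:
continuous-valued intervals have no meaningful raw multiset mode, and the
2-ms resolution matches the histograms the features accompany. A
consequence worth knowing: a perfectly regular 50-ms train reports mode
51 ms (the centre of bin \([50, 52)\)); the mode can sit up to one bin
width outside the observed interval range.

**Runs.** Adjacent interval pairs are classified as increasing, decreasing
or equal (ties at exact equality by default — acquisition hardware
quantises timestamps, here at 10 µs resolution, so exact ties are real; the
tolerance is configurable). A run is a maximal streak of one class. For
iid continuous intervals the expected run count for \(n\) intervals is
\((2n-1)/3\); positively correlated sequences drift below it. The drop is
strong for smooth memory (AR(1)-type trends reduce direction changes from
2/3 towards 1/2) and only marginal for state-switching memory whose
within-state draws are independent — a useful reminder that the run count
and the serial correlation probe different aspects of temporal structure.

**Serial correlation.** At lag \(i\),

\[
SC_i \;=\; \frac{\langle IPI_k\, IPI_{k+i}\rangle_{k=1..N-i} \;-\;
          \langle IPI\rangle^2}{\mathrm{VAR}(IPI)},
\]

where the mean and the (population) variance are taken over the full
sequence. Normalising with full-sequence statistics makes \(SC_0 = 1\)
exactly and treats the truncated lagged-product mean as the only
lag-dependent part. The lagged-product sums are evaluated via FFT
(\(O(N\log N)\) across all lags); the test suite verifies bit-level
agreement (≤ 1e-10) with a literal double-loop transcription of the
definition.

**Chance level.** The interval sequence is randomly permuted 250 times and
SC recomputed each time. Per lag, the band is the permutation mean ±
\(z_{1-\alpha}\) × permutation SD at one-sided \(\alpha = 0.01\); these
per-lag bounds are then averaged over all lags into a single horizontal
threshold per recording. Two constructions are deliberately left open as
configuration because "a confidence interval above the mean, averaged over
all intervals" admits both readings: the default normal-theory band, and an
empirical-percentile band (`method = "percentile"`). They agree closely at
250 permutations; the normal-theory form is the default because it is
stable at small permutation counts.

**SC duration.** The first lag \(\ge 1\) at which \(SC_i\) falls below the
*upper* chance bound, multiplied by the recording's median IPI. This
converts a lag count into a memory duration in milliseconds that is
comparable across individuals with different discharge rates. If SC never
falls below the band within `maxLag` the duration is reported censored at
`maxLag` × median IPI and flagged, rather than dropped — dropping censored
fish would bias group comparisons towards short memory. The default
`maxLag` is 150 (memory in these species extends to roughly 100 intervals),
capped at a quarter of the sequence length so the truncated products retain
reasonable sample sizes.

**PCA of the feature table.** The five features are log10-transformed
(features are positive and right-skewed; the base is immaterial after
standardisation and fixed for reproducibility), centred, scaled to unit
variance and decomposed by SVD. SVD component signs are arbitrary, so each
component is oriented to make its largest-magnitude loading positive —
tests and downstream reports are then deterministic. Note a structural
consequence of per-feature standardisation: if exactly two features
separate two cohorts, PC1 can capture at most about 2 of the 5 variance
units (~40%) no matter how wide the separation is; higher PC1 fractions
require several covarying features, as real species contrasts produce.

**Strength of preference.** For a two-choice playback session,
\(SOP = (t_B - t_D)/(t_B + t_D)\) over preference-zone times summed across
the playback intervals, after mapping physical zones onto stimulus
identity ("side-unswapping": playback sides are physically interchanged
across intervals to control side bias, so zone times are reassigned per
interval before summation). \(SOP \in [-1, 1]\); it is undefined (flagged,
excluded from tests) when the fish never entered a preference zone.
Responsiveness is the total time outside the neutral zone. Cohort SOPs are
tested against 0 with a one-sample t-test; conditions are compared with a
repeated-measures ANOVA (mixed model with individual as random factor,
`lmerTest`) followed by Tukey HSD (`multcomp`) when the omnibus test is
significant.

Two transforms are ambiguous in the field's usage and are exposed as
switches with documented defaults rather than silently fixed: "arcsine
transformed" SOP is read as \(\arcsin(SOP)\) (defined on the full
\([-1,1]\) range; the \(\arcsin\sqrt{(SOP+1)/2}\) variant is available),
and "square transformed" durations are read as the square-root transform
(the conventional variance stabiliser for times, defined at 0; literal
squaring is available).

## The synthetic generators

The recordings this kind of analysis is applied to are not publicly
deposited, so the package carries generators that emulate their
statistical structure; every pipeline stage is tested against them.

Three interval processes (`spiConfig`):

* **renewal** — iid draws from a mixture of gamma/lognormal components,
  each parameterised by mean and SD in ms. The memory-free null.
* **sticky_state** — a semi-Markov burst/pause mechanism: a hidden state
  selects the mixture component; at each interval the state is redrawn
  from the component weights with probability 1/dwell. Serial correlation
  decays as \((1-1/dwell)^{lag}\), mimicking alternating activity between
  long- and short-interval regimes.
* **ar1_log** — log-intervals follow a stationary AR(1) with coefficient
  \(\varphi\); the marginal distribution is independent of \(\varphi\), so
  memory strength can be varied with the interval distribution held fixed.
  This is the process used for parameter-recovery checks (SC duration is
  monotone in \(\varphi\)).

Two calibrated presets define the study conditions used in tests:

* `bimodal_burster`: sticky 3-state process — two sharp lognormal states
  with modes at 14 and 23 ms plus a long-interval pause state (mean
  148 ms, 15% occupancy), dwell 8 intervals. The pause state is required
  by arithmetic: a discharger with interval modes at 14 and 23 ms but only
  ~3150 events per 120 s must spend substantial time at long intervals
  (mean IPI ≈ 38 ms, maximum intervals of hundreds of ms), which is the
  burst/pause pattern these fish show. Calibration: the 2-ms histogram's
  two tallest separated peaks fall within one bin of 14 and 23 ms, and
  120-s event counts lie within 15% of 3157.
* `broadband_slow`: sticky 4-state process spanning 50–140 ms state means,
  dwell 40 intervals; ≥ 80% of interval mass in 25–150 ms, event counts
  within 15% of 1303 per 120 s, and long serial correlation.

The 15% count tolerance and one-bin mode tolerance are engineering
choices: the field reports population means ± SE, not generator
specifications. The generators are stationary over the simulated 120 s;
real fish need not be, and slow non-stationarity would inflate SC
durations. Playback cohorts (`simulatePlaybackCohort`) perturb the cohort
preference per fish on the Fisher-z scale (keeping preferences in
\([-1,1]\) with exact boundaries) and split each interval's active time
in proportion \((1\pm\theta)/2\) with balanced, randomised playback sides.

What passing tests do and do not show: the synthetic trains match the
interval *distributions*, *rates* and *memory* structure the analysis
assumes, but not individual idiosyncrasies, non-stationarity, or
short-timescale display patterns (scallops, rasps, cessations) of real
recordings — conclusions about the pipeline's correctness transfer;
conclusions about biology do not.

## Numerical and degenerate-input choices

* Timestamps are stored in seconds (recording-native); conversion to ms
  happens once, at the IPI boundary. Events closer than 10 µs (the
  assumed 100-kHz acquisition resolution) are rejected as duplicates.
* Histogram bins are left-closed right-open starting at 0 ms, so boundary
  values place deterministically.
* A constant interval sequence has zero variance: serial correlation is
  refused with a "degenerate" error rather than returning NaN.
* Zero-variance SOP cohorts are flagged degenerate rather than tested.
* All randomness (simulation, permutation, scrambling) flows through one
  integer seed per call and restores the caller's RNG state.
* Ties in the tallest-bin search resolve to the lowest bin
  (`which.max`), deterministically.

## Problem sizes used in the shipped checks

The test and acceptance runs use: 50 sequences (N ≤ 500, 100 lags) for
oracle equivalence; 100 iid plus 100 scrambled sequences of N = 3000 with
250 permutations for type-I control; 50 seeds per memory level (sticky
dwell 20/50/100, AR(1) φ 0.5/0.8/0.95, N = 3000) for parameter recovery;
1000 iid sequences of 1000 intervals for the runs expectation; cohorts of
12 + 12 preset trains of 120 s for the species contrast; and 500 simulated
cohorts (n = 12, θ = 0.4, SD 0.3) for preference-test power. These sizes
give Monte-Carlo standard errors well inside the asserted tolerances.

## Known limitations

* The chance-band construction averages per-lag bounds into one scalar
  threshold; lag-dependent bands (wider at long lags where fewer products
  enter) are computed and stored but not used for the duration by default.
* The repeated-measures ANOVA uses individual as the only random factor;
  designs with multiple stimulus exemplars per condition would want a
  crossed random term for the exemplar.
* SC durations of long-memory individuals censor at `maxLag`; group
  location comparisons (Kruskal-Wallis on durations) treat censored values
  as observed, which is conservative for detecting *longer* memory.
* No spectral or joint-interval statistics beyond the lagged product; no
  automatic burst/rasp/cessation pattern detection.
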