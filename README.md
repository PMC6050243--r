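# spitrain

Statistical analysis of electric-organ-discharge (EOD) timing in mormyrid
weakly electric fish.

Mormyrids emit brief electric pulses whose waveform is species-specific
and fixed, while the *sequence of pulse intervals* (SPI) is under
volitional control. Whether that timing carries communication information
is a statistical question about the inter-pulse-interval (IPI) series:
are interval distributions species-specific, is the sequence a memoryless
renewal process or serially correlated, and do receivers prefer natural
over scrambled timing in playback? `spitrain` is for neuroethologists who
have pulse timestamps (exported from acquisition software as plain text)
and two-choice playback occupancy logs, and want this pipeline as tested,
reproducible code.

## What it computes

For a pulse train with times $t_i$ (an S4 `PulseTrain`), the interval
sequence is $IPI_i = t_i - t_{i-1}$ (ms). On a 120-s analysis window the
package derives:

* **IPI histograms** (2-ms bins, relative frequency) and population
  averages with SEM/STD;
* the **five-variable SPI summary**: total EODs, number of runs (maximal
  streaks of increasing/decreasing/constant intervals, as in the runs
  test), mode IPI (tallest 2-ms bin centre), and the interval range;
* the **serial correlogram**
  $SC_i = (\langle IPI_k IPI_{k+i}\rangle - \langle IPI\rangle^2) / \mathrm{VAR}(IPI)$
  with a permutation chance level (250 shuffles, one-sided $\alpha=0.01$)
  and the **SC duration** — first sub-chance lag × median IPI — the scalar
  memory extent of a recording;
* **distribution-preserving scrambles** (renewal surrogates) of interval
  sequences;
* **PCA** of log-standardised feature tables with deterministic sign
  convention, Pearson correlation matrices, and standard group tests;
* **strength of preference** $SOP = (t_B - t_D)/(t_B + t_D)$ for
  two-choice playback sessions with side-randomisation bookkeeping,
  one-sample preference tests, and repeated-measures condition/
  responsiveness ANOVAs (mixed model + Tukey HSD);
* calibrated **synthetic generators** (renewal, sticky-state semi-Markov,
  AR(1) log-interval; two species presets) that emulate the discharge
  statistics so every stage is testable without recordings.

## Worked example

```r
library(spitrain)

## a synthetic burst-type discharger, 120 s
tr <- simulateSPI(speciesPreset("bimodal_burster", seed = 7)$config,
                  individualId = "demo")
tr
#> PulseTrain: 3242 events over 120.000 s (sticky_state, unknown, synthetic, id=demo)

extractFeatures(tr)
#> SPIFeatures [demo, sticky_state, unknown, synthetic]
#>   total EODs: 3242 | runs: 2059 | mode IPI: 15.0 ms | range: [9.4, 627.5] ms

## serial correlation with permutation chance level
s <- computeIPIs(extractWindow(tr, 0, 120))
serialCorrelogram(s, seed = 7)
#> SerialCorrelogram: lags 0..150, chance band [-0.0420, 0.0411] (250 permutations, alpha 0.01)
#>   first sub-chance lag: 18 | median IPI 20.66 ms | SC duration 371.9 ms

## two-choice playback cohort with true preference 0.4
sess <- simulatePlaybackCohort(12, 0.4, seed = 7)
sops <- sapply(sess, function(x) computeSOP(x)$sop)
pt <- preferenceTest(sops)
sprintf("cohort mean SOP %.3f, t = %.2f, p = %.2g",
        pt$mean_sop, pt$statistic, pt$p_value)
#> "cohort mean SOP 0.492, t = 7.15, p = 1.9e-05"
```

Reading the output: this simulated burster fires 3242 pulses in 120 s with
its most frequent interval near 15 ms; its interval sequence stays
correlated above chance out to lag 18, i.e. about 372 ms of memory. The
playback cohort's mean preference of 0.49 differs clearly from the
no-preference value 0.

A command-line wrapper over the same functions is installed at
`inst/scripts/spitrain.R` (`simulate`, `window`, `features`, `scramble`,
`sercorr`, `sop`).

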