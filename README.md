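# mmnstream

Simulation and ERP analysis of auditory statistical-learning triplet
streams.

## The problem

In statistical-learning oddball experiments, listeners are exposed to a
continuous stream of sound triplets whose last element follows its two-sound
root with high (p = 0.9) or low (p = 0.1) transition probability, while the
sound's spatial location independently switches sides with probability 0.2
at triplet endings. Low-probability endings can elicit a *statistical
mismatch negativity* (sMMN) and location changes a *location MMN* —
negative-going event-related potentials (ERPs) with a fronto-central
maximum. A central question is how these prediction-error responses depend
on temporal predictability: isochronous presentation (constant 300 ms
stimulus-onset asynchrony, timing entropy 0 bits) versus jittered
presentation (SOA uniform over 150–450 ms in 1 ms steps, timing entropy
log₂ 301 = 8.23 bits).

`mmnstream` is for methodologists and EEG researchers who want a fully
specified, ground-truth-controlled version of this paradigm: it generates
the stimulus streams exactly as designed, characterises them in
information-theoretic terms, synthesises multichannel EEG with injectable
ERP components, applies the standard preprocessing chain, and fits the
repeated-measures / mixed ANOVAs of the MMN contrasts — so every stage can
be validated by parameter recovery rather than by trust.

## What it computes

* **Design predictability.** Surprisal h(ending) = log₂(1/p) of each ending
  category, conditional entropy H(ending|root) = Σ p log₂(1/p) = 0.469
  bits, and the timing entropy H(ISIs) of the pause distribution
  (0 vs 8.23 bits).
* **Streams.** Blocks of 400 triplets with *exact* category quotas
  (0.72 / 0.08 / 0.18 / 0.02: standards, statistical deviants, location
  deviants, double deviants), at least three intervening triplets between
  low-probability endings, balanced AB/CD roots (transition probability
  0.5), per-block alternation of the standard loudspeaker side, cover-task
  targets with simulated button presses, and 12-trial two-alternative
  familiarity tests.
* **Synthetic EEG.** 59-channel 10-10 montage + mastoid + EOG at 500 Hz;
  Gaussian-bump ERP components (N50, P130, sMMN 180–260 ms, location MMN
  150–220 ms) with known topography and per-condition scaling; 1/f
  background; blink artifacts; BrainVision core format I/O.
* **Preprocessing.** Zero-phase 30 Hz Blackman FIR (2750 points),
  mastoid-mean re-referencing, 25 µV gliding-window rejection (200/800 ms
  windows, any channel incl. EOG), epoching −100..400 ms with 100 ms
  baseline and the cover-task (3 s) and proximity (200 ms) exclusion rules,
  nine-ROI averaging.
* **Statistics.** From-scratch balanced repeated-measures ANOVA with
  optional between-subjects factor (deviance × area × lateralisation ×
  block-group, ± isochronicity), classical and partial η², optional
  Greenhouse–Geisser correction, simple effects, and one-sample chance
  tests for the familiarity scores.

## Worked example

```r
library(mmnstream)

predictability_table()
#>   quantity                        symbol         probability  bits
#> 1 standard ending surprisal       h(ending)              0.9 0.152
#> 2 statistical deviant surprisal   h(ending)              0.1 3.32
#> 3 ending|root conditional entropy H(ending|root)        NA   0.469
#> 4 standard location surprisal     h(location)            0.8 0.322
#> 5 deviant location surprisal      h(location)            0.2 2.32
#> 6 timing entropy (isochronous)    H(ISIs)               NA   0
#> 7 timing entropy (jittered)       H(ISIs)               NA   8.23

cfg <- run_config(n_subjects_per_group = 4, n_triplets_per_block = 100,
                  n_blocks = 2, out_dir = tempfile("mmn_demo"), seed = 42)
report <- run_pipeline(cfg)
report
#> <pipeline_report> 4 subjects/group, 2 x 100 triplets
#>
#> smmn deviance x isochronicity: F(1, 6) = 4.91, p = 0.06869
#> locmmn deviance x isochronicity: F(1, 6) = 3.73, p = 0.1015

tidy(report$anova$isochronous$locmmn)
#>   term           sumsq    df sumsq_error df_error statistic p.value  eta_sq
#> 1 deviance       13.9       1      2.54          3    16.4   0.0271  0.594
#> 2 area            0.368     2      0.317         6     3.48  0.0992  0.0158
#> ...
```

(At this toy scale the run warns that double deviants — 2% of endings — have
no surviving epochs; they are not part of the two reported contrasts.)

The surprisal rows say that a statistical deviant carries 3.32 bits of
surprise against 0.15 for a standard, while the ending position as a whole
is highly predictable (0.469 bits given the root). In the demo run the
location-MMN deviance effect is recovered within the isochronous cohort
(F(1, 3) = 16.4, p = 0.027 at this toy size: 4 subjects, 2 × 100 triplets),
and the deviance-by-isochronicity interactions trend in the injected
direction (MMNs attenuated under jitter). The test suite exercises the same
machinery at n = 21 per group, where the injected interaction is detected
in ≥95% of simulations at α = 0.001 and the injected location-MMN amplitude
is recovered within ±10%. `autoplot(report$waves$isochronous, categories =
c("standard", "phys_deviant"))` draws the grand-average ROI waveforms.

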