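---
title: "Simulating and analysing statistical-learning triplet streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing statistical-learning triplet streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmnstream)
```

## The paradigm

`mmnstream` implements, as a tested simulation-and-analysis pipeline, an
auditory statistical-learning oddball design. Six sounds (labelled A--F) are
arranged into four triplets: the roots AB and CD are followed by one of the
two endings E/F with high (0.9) or low (0.1) transition probability
(AB→E high, AB→F low; CD→F high, CD→E low), and roots follow any ending
with probability 0.5 per family, a first-order Markov (bigram) structure.
Independently, each triplet ending is presented from the block's standard
loudspeaker side with probability 0.8 and from the opposite, deviant side
with probability 0.2 (roots: 0.95/0.05). Crossing the two manipulations
yields four ending categories with exact occurrence probabilities

| category            | transition p | location p | overall p |
|---------------------|--------------|------------|-----------|
| standard            | 0.90         | 0.80       | 0.72      |
| statistical deviant | 0.10         | 0.80       | 0.08      |
| location deviant    | 0.90         | 0.20       | 0.18      |
| double deviant      | 0.10         | 0.20       | 0.02      |

A block holds 400 triplets; an experiment holds six blocks. Presentation is
either isochronous (220 ms sounds + 80 ms pause, constant 300 ms SOA) or
jittered (150 ms sounds followed by a pause drawn uniformly from the 301
integer values 0--300 ms, so the SOA varies over 150--450 ms with mean
300 ms). In information-theoretic terms the ending given its root carries a
conditional entropy of $H = \sum_i p_i \log_2(1/p_i) = 0.469$ bits; the
surprisal $h = \log_2(1/p)$ of the individual endings is 0.15 / 3.32 bits
(transition) and 0.32 / 2.32 bits (location); the timing entropy is 0 bits
when isochronous and $\log_2 301 = 8.23$ bits when jittered.
`predictability_table()` collects these values.

## Stream construction

The generator is deliberately *quota-based* rather than i.i.d.: a block's
composition is built with exact category counts (288/32/72/8 at $n = 400$),
split evenly over the two root families, and then shuffled under the
constraint that any two triplets of the low-probability set (statistical and
double deviants) are separated by at least three other triplets. This
matches a design whose printed probabilities are exact per block and makes
the frequency tests sharp. The constrained order is produced by a uniform
shuffle followed by local swap-repair of violations (bounded retries, then
reshuffle); the result is approximately, not exactly, uniform over
admissible orders, which we consider irrelevant for every quantity analysed
downstream (all are exchangeable under the residual non-uniformity).
Separation is interpreted as *at least three intervening triplets*.

Odd per-family category counts (possible at small block sizes, e.g.
$n = 50$ where the double-deviant quota is 1) are balanced by randomly
assigning the extra triplet of each odd category to a family while keeping
both family totals at $n/2$; block sizes whose quotas are not integers are
rejected.

Pauses are integer milliseconds, so the jittered pause set has exactly 301
equiprobable values, consistent with the 8.23-bit entropy above. Onsets are
stored in milliseconds and snapped to the 2 ms grid of the 500 Hz recording
only at EEG-synthesis time. Cover-task targets are inserted *between*
triplets at a configurable rate (default 2/min; the design documents only
that targets occur, not their rate) and are followed by a simulated button
press with probability 0.979 (the default detection rate) at lognormal
latency. Root-location deviance (p = 0.05) is sampled i.i.d. rather than by
quota: the design fixes no count structure for roots.

The 12-trial familiarity test pairs each triplet with its opposite-ending
twin; each of the four pair types appears three times, the correct
(high-transition-probability) member is counterbalanced 6/6 across
positions, and consecutive trials never share a root family -- with 6
AB-root and 6 CD-root trials this forces strict alternation, which the
generator implements as a randomised interleave.

## Synthetic EEG

`simulate_subject()` renders a stream as a 59-channel 10-10 scalp montage
(plus right mastoid and four EOG channels; the left mastoid is the online
reference, hence implicit) at 500 Hz. Event-related activity is injected as
parametric Gaussian bumps rather than forward-modelled dipoles -- sufficient
to exercise every downstream contract while keeping the ground truth exactly
known:

* an N50 (-1 uV, 50 ms) and P130 (+1.5 uV, 130 ms) on every sound,
* an sMMN (-2 uV, 220 ms, sd 25 ms) on low-transition-probability endings,
* a location MMN (-2 uV, 170 ms, sd 20 ms) on deviant-side endings,

each with a per-channel topographic gain map (Gaussian over the 2D layout,
fronto-central maximum, normalised to 1 at the component's peak channel,
with a slight left bias for the location MMN). Double deviants receive both
MMN components additively. Per-mode multipliers inject
temporal-predictability effects; the defaults are 1/1 under isochronous and
0/0.6 (sMMN/location MMN) under jittered presentation, i.e. no sMMN and an
attenuated location MMN when timing is unpredictable. The exact component
amplitudes cannot be fixed from text descriptions of real recordings, so
they are order-of-magnitude ERP values and fully configurable.

The background is 1/f-shaped Gaussian noise (default SD 5 uV per channel,
exponent 1), synthesised in the frequency domain, independent across
channels -- including the mastoid, whose noise becomes a realistic common
mode after re-referencing. Blinks are 400 ms raised cosines (default
4/min, 150 uV on the lower vertical EOG) that propagate with decaying gain
to anterior scalp rows. The record is padded with 2 s of silence at both
ends so every epoch fits. Simulation is linear in the ground-truth
amplitudes and byte-reproducible from its seed.

## Preprocessing

The analysis chain mirrors standard MMN practice: a zero-phase 30 Hz
low-pass FIR (Blackman-windowed sinc, 2750 points; an even tap count is
extended by one so the group delay is an integer number of samples),
re-referencing to the algebraic mastoid mean, and artifact rejection that
marks every sample covered by a 200 ms or 800 ms gliding window (step one
sample) in which any channel -- EOG included -- exceeds 25 uV standard
deviation. The two window lengths are evaluated independently and
OR-combined, and the SD is computed per channel, not pooled. Visual
inspection of faulty channels is replaced by an automated screen for flat
or extreme-variance channels (`screen_bad_channels()`), a documented
deviation from manual practice.

Epochs are cut around triplet endings only, on the half-open window
[-100, 400) ms (250 samples), baseline-corrected over [-100, 0) ms. An
ending is excluded if it falls within 3 s after a target sound or button
press (the cover-task rule; "acoustical deviants" is read as target sounds,
with the horizon configurable), if any other stimulus onset lies closer
than 200 ms (onset-to-onset, either direction), or if its window overlaps
the rejection mask -- logged with that precedence so the tallies partition
the total. Epochs are averaged within subject, ending category and block
group (blocks {1,2}, {3,4}, {5,6}), then over the nine ROIs: the 3 x 3
grid of scalp area (frontal/central/parietal) by lateralisation
(left/middle/right).

## Statistics

`rm_anova()` is a from-scratch, fully balanced repeated-measures ANOVA with
an optional between-subjects factor, computed by inclusion-exclusion over
marginal means: the pure interaction effect of a term is the signed sum of
its marginal means, its sum of squares the squared norm of that effect.
Each within effect is tested against its own subject-by-effect stratum
(subjects nested in groups); the between effect against subjects within
groups. With balanced data this coincides with the classical projection
decomposition, and the test suite verifies agreement with `stats::aov`
Error-stratum fits to 1e-8 on random designs. Effect size is reported both
as classical eta squared (SS over total SS, the headline value, since
reported values of this design are far below what partial eta squared would
imply) and partial eta squared. No sphericity correction is applied by
default, matching the integer degrees of freedom convention in this
literature. Tests are two-sided at alpha = 0.05.

The MMN contrasts take window means -- sMMN 180--260 ms (plus an earlier
150--200 ms control window), location MMN 150--220 ms -- as
subject x deviance x area x lateralisation x block-group cell tables, fit
the within-cohort ANOVA, and `interaction_contrast()` adds isochronicity as
the between factor with per-group simple effects. Factors that do not vary
(for instance a single block group in a short run) are dropped from the
design automatically. `chance_test()` is the one-sample t test of
familiarity scores against 0.5 with Cohen's d, with an explicit degenerate
branch for zero-variance samples.

Injected amplitudes are recovered from cell tables with
`recover_amplitude()`: the per-ROI deviance simple effects are regressed
onto the per-ROI gains predicted from the known kernel and topography
(least squares over the nine ROIs), which is unbiased and down-weights ROIs
where the component is weak.

## Validation strategy and problem sizes

Because no real recordings ship with the package, validation is by
construction and parameter recovery:

* exactness checks on the stream (quotas, separation, SOA support) and the
  information-theoretic values;
* oracle agreement of the ANOVA engine with `stats::aov` on random
  balanced designs;
* calibration: the type-I error of the deviance effect is checked against
  [0.03, 0.07] over 1000 null cohort simulations at the cell-table level,
  and the power of the deviance-by-isochronicity interaction (sMMN injected
  only in the isochronous cohort, low noise) over 200 simulations at
  alpha = 0.001 -- these run on simulated window-mean tables because the
  operations under test consume cell tables;
* end-to-end recovery: 16 isochronous cohorts of 21 subjects, each with one
  100-triplet block at the default noise level, are synthesised and pushed
  through the full chain (filter, re-reference, rejection, epoching, ROI
  averaging, window means); the mean recovered location-MMN amplitude must
  match the injected -2 uV within 10%. One block of 100 triplets per
  subject -- rather than six of 400 -- is the package's chosen problem size
  for this check; it leaves the estimator unbiased and only widens its
  variance, which the 16 replicates absorb.
* a noiseless end-to-end identity: with zero noise the ROI difference waves
  must equal the injected kernel times the ROI topography within 0.05 uV
  (filter-transition and grid-quantisation error).

What passing these tests does *not* show: the generator has no volume
conduction, no correlated-across-channels background (other than the
reference common mode), no non-stationarity, no real blink morphology
variation, and its ERP components are stylised bumps. Conclusions about
real recordings therefore rest on the correctness of the *procedures*,
which is what the synthetic ground truth certifies.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(
  n_subjects_per_group = 4, n_triplets_per_block = 100, n_blocks = 2,
  out_dir = tempfile("mmn_demo"), seed = 42
)
report <- run_pipeline(cfg)
report$predictability
tidy(report$anova$isochronous$locmmn)
report$interaction$locmmn$interaction
autoplot(report$waves$isochronous,
         categories = c("standard", "phys_deviant"))
```

## Known limitations

* The constrained shuffle is only approximately uniform over admissible
  orders.
* The BrainVision writer/reader covers the core multiplexed IEEE-float
  subset only.
* Greenhouse-Geisser sphericity correction is not yet exposed; the balanced
  designs used here report uncorrected degrees of freedom by convention.
* Whether the root-location split (0.95/0.05) should be quota-balanced is
  undocumented in the design; it is sampled i.i.d. here.
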