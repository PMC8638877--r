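---
title: "The inhibitory touchscreen task toolkit: design, simulation and scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The inhibitory touchscreen task toolkit: design, simulation and scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecitt)
```

## The task and its measures

The Early Childhood Inhibitory Touchscreen Task (ECITT) measures response
inhibition -- the ability to overcome a prepotent motor response -- from
toddlerhood onwards. On each trial a smiley appears on one of two buttons.
It appears in one location on 75% of trials (24 of 32 per block; the
*prepotent* condition, which builds up the dominant response) and in the
other location on 25% (8 of 32; the *inhibitory* condition, which requires
suppressing that response). Which location is prepotent is counterbalanced
across participants and held fixed across a participant's longitudinal
sessions. The faster-paced variant for children and adults (ECITT-A) keeps
the identical structure over 3 blocks of 32 trials with a 1000 ms
inter-trial interval.

Session-level performance is summarised by difference scores:

* **AccD** = %correct(prepotent) − %correct(inhibitory), in percentage
  points; higher = poorer inhibition.
* **adjusted AccD** = AccD ÷ (prepotent proportion correct). Two sessions
  can share an AccD of 12.5 while one is at 62.5%/50% and the other at
  100%/87.5%; the divisor credits the stronger prepotency that the second
  participant overcame.
* **RTD** = median correct inhibitory RT − median correct prepotent RT,
  in ms.

## Constrained sequence generation

A block holds exactly `n_inhibitory` inhibitory trials, begins with a
forced prepotent lead-in (3 trials), and never contains more than 5
consecutive prepotent or 2 consecutive inhibitory trials. Run caps are
applied within a block; blocks are separated by breaks and each restarts
with its own lead-in, so runs do not carry across block boundaries. The
lead-in is implemented as exactly `lead_in` forced prepotent trials; the
constrained randomisation may still place further prepotent trials after
it, so "at least 3" holds by construction.

The original task software does not document its randomiser's
distribution over admissible sequences, so the distribution is a design
choice here: we sample **uniformly over the set of valid sequences**.
Rather than rejection sampling (which needs an iteration cap and whose
acceptance rate depends on the configuration), `generate_sequence()`
counts valid completions of every partial sequence with a memoised
dynamic program and draws each trial with probability proportional to the
completion counts. This is exactly uniform, runs in milliseconds for the
32-trial block, and detects unsatisfiable configurations (e.g. run caps
that no arrangement can satisfy, or a lead-in longer than the prepotent
run cap) as a zero count at the root rather than by looping. On a
miniature configuration small enough to enumerate exhaustively (6 trials,
2 inhibitory, caps 3/1), the test suite checks the empirical draw
frequencies against the enumerated valid set with a chi-square
goodness-of-fit test at alpha = 0.01.

`validate_sequence()` re-checks every constraint independently of the
generator and names the trial and rule for each breach, so externally
produced sequence files can be audited with the same rules.

## Cleaning and scoring rules

Trial validity mirrors the video-coding rules for toddler data:

* RT below the variant floor (300 ms toddler, 200 ms adult) →
  `invalid_fast`; excluded from *all* analyses. The floor difference
  reflects the faster manual responses of older participants.
* Externally coded events (finger on the screen at onset, caregiver or
  experimenter intervention indicating a response, accidental touches) →
  excluded from all analyses. These arrive as data flags; video coding
  itself is out of scope.
* The first trial of a toddler session is discarded (it is pointed to by
  the experimenter to establish the prepotency); ECITT-A uses a practice
  block instead and keeps trial 1. The discard is applied after sequence
  validation and before all counts, so the >60% inclusion rule below is
  computed on the post-discard trials.
* RT analyses additionally require a correct response and RT < 5000 ms
  (guarding against long distracted responses); such trials still count
  for accuracy.

Sessions are *included* only when prepotent accuracy is strictly above
60%: at or below that level no prepotent response tendency can be assumed
and the difference scores stop measuring inhibition. Exactly 60.0%
excludes. Excluded sessions still return their scores with
`included = FALSE` and a reason, so inclusion decisions remain visible.
Medians use the even-count convention (mean of the two central values)
everywhere, and RTD is left undefined -- never zeroed -- when a condition
has no scorable correct RT; downstream analyses drop such sessions
pairwise. The >3 SD screening used for longitudinal RT stability is an
explicit flagging step (`flag_outliers()`), never silent removal.

## The generative participant model

`participant_model()` emulates the regularities of coded sessions:

* **Accuracy**: Bernoulli per condition (`p_correct_prepotent`,
  `p_correct_inhibitory`).
* **Correct RT**: ex-Gaussian (Gaussian mu/sigma plus exponential tau),
  the standard descriptive model for right-skewed RT data; the task's
  reports print only group medians/means, so these parameters are
  calibrated to produce plausible toddler/adult medians, not fitted to
  full distributions. Inhibitory slowing is a location (mu) shift applied
  on correct inhibitory trials only; error-trial RTs are generated but
  never scored, matching the correct-trials-only RT analyses.
* **Trial noise**: anticipations (RT below the floor), distractions (RT
  above the ceiling) and externally coded invalid trials are injected at
  specified rates.
* In the unresponsive toddler variant the trial only ends on a correct
  touch; the simulator records the corrective touch count and scores the
  *first* touch, matching how a prepotent error followed by a correction
  is coded.

The profile library (`age_profiles()`) encodes the reported group
pattern: prepotent accuracy above 90% at every toddler age while
inhibitory accuracy rises from about 63% (18 months) through 76% (21
months, interpolated) to 89% (24 months) and 92% (30 months); children
and adults are near ceiling on accuracy with the condition effect carried
by RT (adult RTD around 57 ms, child around 100 ms). Toddler RT levels
(mu around 1.2--1.4 s) and noise rates (4--6% anticipations/invalid
trials) were chosen once as realistic for coded toddler touchscreen data.
Between-subject heterogeneity is Gaussian on logit(accuracy) and on
log(RT location), truncated to valid ranges; because averaging a
logit-normal distorts the mean, the individualisation step solves for the
logit intercept whose *population mean* equals the profile's stated
accuracy, keeping the presets interpretable as group means.

What the simulator does **not** emulate: session-level fatigue or
learning trends, serial dependence between trials, choice errors on go
trials in the stop-signal task, or the motivational differences between
lab and public-engagement settings. Passing calibration tests therefore
shows that the pipeline recovers what the generator encodes -- not that
the generator captures every property of real toddlers.

`simulate_cohort()` supports cross-sectional and longitudinal designs.
Longitudinally, each participant's inhibitory trait across visits is an
equicorrelated latent Gaussian with correlation `stability_r` (eigen
square root, so the boundary cases are admissible; any `r` below
−1/(visits−1) is rejected), while prepotent accuracy and speed
perturbations are stable traits. Simulating the same schedule at
`stability_r = 1` gives the reliability ceiling of the difference score,
and the attenuation identity (observed stability ≈ latent r × ceiling)
is used as the recovery oracle in the tests, with common random numbers
across the two runs to keep the comparison out of the sampling noise.

## Statistics layer

All analyses are re-runnable from the score table emitted by
`score_sessions()`. Conventions, fixed once:

* Sample (n−1) variances; two-tailed p-values throughout.
* `welch_t()` accepts raw vectors or (mean, SD, n) summaries; Cohen's d
  uses the pooled SD. The printed toddler group summaries (19.29 ± 29.72
  vs 5.37 ± 10.64) reproduce d = 0.64 under this convention. `paired_t()`
  fixes d = t/√n (mean difference over the SD of differences), which
  reproduces d = 0.87 from t(18) = 3.78.
* `cronbach_alpha()` uses the item-variance form on complete rows only
  (the 8-trial rule; a reduced-item analysis is just a column subset);
  `cohens_kappa()` is the standard chance-corrected agreement.
* `mixed_anova()` fits the balanced univariate designs via `stats::aov()`
  Error strata -- a two-level condition factor crossed with a
  between-subjects group, or fully-within two-factor designs -- with
  listwise deletion and partial eta squared taken against each effect's
  own stratum error. No sphericity correction is applied; the two-level
  contrasts of interest are unaffected, but p-values for three-level
  within effects are anticonservative under non-sphericity (a known
  limitation).
* `correlate()`/`partial_correlate()` return percentile bootstrap CIs
  with B = 1000 seeded resamples of participants (pairs); partial r
  projects both variables on the controls by least squares and
  correlates the residuals, with df = n − 2 − k.
* `age_trend()` compares linear and quadratic least-squares fits with
  the increment F test, the device used to contrast the linear toddler
  improvement with the u-shaped lifespan trend.

The published group-level F and t values on real children are *not*
reproduction targets: the underlying per-participant data are not
printed. The tests instead verify each statistic against independent
brute-force oracles (covariance-form alpha, hand-tabled kappa, textbook
sums-of-squares decomposition, the first-order partial-correlation
formula) and the analytic reductions (Welch → Student under equal
variances and sizes; between-effect F = t²).

## Stop-signal engine

The stop-signal task provides the convergent-validity anchor. Structure:
5 blocks × 4 sub-blocks of 16 trials (12 go, 4 stop) in seeded random
order with directions balanced within sub-block. Behaviour follows the
independent horse-race model: a stop trial is inhibited iff
`ssd + ssrt_true < ` the go finishing time (ex-Gaussian) and no trigger
failure occurs. The staircase raises the SSD 50 ms after each successful
stop and lowers it 50 ms after each failure, tracking the 50% stopping
point.

SSRT = median go RT − SSD at 50% stopping, both computed over the
**second half of sub-blocks** where the staircase has stabilised. "SSD at
50%" is operationalised as the mean SSD over second-half stop trials (the
tracking estimator); last-SSD and reversal-midpoint alternatives sit
behind `sst_config(ssd50_estimator=)`. The go-RT window is the same
second half, for internal consistency, since the source description
leaves the go window ambiguous. The starting SSD (250 ms) and clamping
bounds (0--1150 ms) are unstated in the source and are configurable
package defaults. Simulated go responses are always directionally
correct: choice-error modelling is out of scope, and omissions are
carried by the `responded` flag.

Recovery behaves as race-model theory predicts: the estimate is
translation invariant (shifting the go distribution and the true SSRT
together shifts the estimate equally), trigger failures bias it upward,
and with ex-Gaussian go RTs (mu 450, sigma 50, tau 100) and a 250 ms
true SSRT the mean estimate over 200 simulated participants lands within
±25 ms of truth (the mean-SSD tracker sits slightly below the true value
because the race is evaluated against the full go distribution rather
than its median).

## Numerical and interface choices

* Times are integer milliseconds end-to-end; percentages live on the
  0--100 scale, matching every printed threshold and value.
* Trial indices are 0-based in memory and 1-based in exported CSVs;
  session metadata travels in a JSON sidecar next to the trial CSV, and
  `read_session()` validates codes, signs and block structure with row
  numbers in the error message.
* Every stochastic operation takes an explicit seed and restores the
  caller's RNG state; cohort and CLI runs derive per-participant
  substreams deterministically from the master seed.
* Problem sizes in the test suite were chosen so statistical checks have
  comfortable power at desk scale: 10,000 draws for the uniformity
  goodness-of-fit, 400-session Monte-Carlo means, 200-participant SSRT
  recovery, 2000-stop-trial staircase convergence, 500-replication
  bootstrap-coverage calibration.

## Known limitations

* The uniform sampling law over valid sequences is this package's
  choice; the original app's distribution is undocumented.
* Simulator parameters are calibrated to printed group accuracies and
  plausible RT levels only; no trial-level empirical distributions were
  available to fit.
* The exact windowing of the commercial battery's SSRT computation is
  proprietary; the implementation follows the published verbal
  description.
* `mixed_anova()` expects balanced designs after listwise deletion and
  applies no sphericity correction.
* Intraclass correlation for RT-correction reliability, video coding of
  real footage, and fitting the race model to real data are out of
  scope.
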