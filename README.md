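# ecitt

Toolkit for the **Early Childhood Inhibitory Touchscreen Task** (ECITT)
and its faster-paced adult variant (ECITT-A) — a response-inhibition
paradigm usable from toddlerhood across the lifespan. The package is for
developmental and cognitive researchers who need the task's machinery
without the touchscreen: constrained trial-sequence generation,
generative simulated participants, the trial-cleaning/scoring pipeline,
the psychometric validation statistics, and a stop-signal task engine
for convergent-validity simulations.

## The measures

On 75% of trials the smiley appears in a fixed *prepotent* location
(building a dominant motor response); on 25% it switches to the
*inhibitory* location, which requires suppressing that response. Each
block of 32 trials holds exactly 8 inhibitory trials, starts with 3
prepotent trials, and never shows more than 5 prepotent or 2 inhibitory
trials in a row. Session scores:

- **AccD** = %correct(prepotent) − %correct(inhibitory) (percentage
  points; higher = poorer inhibition)
- **adjusted AccD** = AccD ÷ prepotent proportion correct
- **RTD** = median correct inhibitory RT − median correct prepotent RT (ms)

Sessions are included only when prepotent accuracy exceeds 60%. The
stop-signal module tracks the stop-signal delay (SSD) with a ±50 ms
staircase and estimates **SSRT = median go RT − SSD at 50% stopping**
over the second half of sub-blocks, under the independent horse-race
model.

## Worked example

```r
library(ecitt)

cb <- assign_counterbalance(c("t01", "t02"))   # alternate top/bottom
v  <- ecitt_variant("ECITT_S1")                # toddler variant
sq <- generate_sequence(v$config, cb[1, ], seed = 101)
table(sq$condition)
#> inhibitory  prepotent
#>          8         24

sess <- simulate_session(sq, v, age_profiles("18m")$model, seed = 102,
                         participant_id = "t01", age_months = 18)
score_session(sess)
#>  participant_id visit age_months  variant  accd accd_adjusted rtd_ms included
#>             t01     1         18 ECITT_S1 57.14         57.14  873.5     TRUE
#>  ...            prepotent_pct_correct 100   inhibitory_pct_correct 42.86 ...
```

This simulated 18-month-old was perfect on the prepotent trials but
correct on only 42.9% of inhibitory trials, giving an accuracy difference
of 57.1 points and an 873 ms slowing on correct inhibitory responses —
the weak-inhibition profile typical of the youngest toddlers. The
`included` flag confirms the session clears the 60% prepotent-accuracy
bar.

Stop-signal simulation and SSRT recovery:

```r
cfg   <- sst_config()                          # 5 blocks x 4 sub-blocks
specs <- build_sst_sequence(cfg, seed = 103)
run_staircase(specs, race_params(ssrt_true = 250), cfg, seed = 104)
#> <sst_result> 320 trials (80 stop); second half: 50.0% stopped,
#> SSD50 = 312 ms, median go RT = 525 ms, SSRT = 212 ms
```

The staircase settles at 50% stopping and the estimate tracks the 250 ms
ground truth (single sessions are noisy; averaged over 200 simulated
participants the mean estimate lands within ±25 ms — see the test
suite).

Analysis helpers work from score tables: `cronbach_alpha()`,
`cohens_kappa()`, `welch_t()` / `paired_t()` (with the pooled-SD and
t/√n effect-size conventions), `mixed_anova()` (partial eta squared),
`correlate()` / `partial_correlate()` (percentile bootstrap CIs, B =
1000), and `age_trend()` (linear vs quadratic model comparison). A thin
command-line interface (`inst/cli/ecitt.R`, or `ecitt_cli()` in R)
exposes `generate`, `simulate`, `score`, `sst` and `fixtures`
subcommands.

See the vignette (`vignettes/ecitt-toolkit.Rmd`) for the models,
conventions and design decisions.

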