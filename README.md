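# impulsim

Simulation and psychometrics for a mobile impulsivity assessment battery.

Impulsivity is multidimensional — risk taking, response inhibition, and
delay discounting dissociate across people and across measurement modes —
and measuring it *in daily life* requires short mobile tasks administered
repeatedly alongside momentary self-report. impulsim implements such a
battery end to end, with no real participants required: three behavioral
task engines with their standard scores, the self-report instruments, a
21-day morning/evening sampling protocol, a synthetic-participant cohort
whose latent structure is calibrated to published validation statistics,
and the analysis pipeline that validates the battery. It is intended for
methodologists designing experience-sampling studies of self-regulation,
and for anyone who needs a fully reproducible, generative test bed for
mobile behavioral measures.

## What is implemented

**Task engines** (mobile and laboratory presets):

* **Balloon risk task** — pop thresholds uniform on `{1..N}`; primary
  score is the *adjusted average* pumps over unexploded balloons. A fixed
  target of `t` pumps earns `reward · t · (N − t)/N` per balloon in
  expectation, the closed form the tests verify by Monte Carlo.
* **Cued go/no-go** — 75-trial mobile preset with the published timing
  (fixation 250 ms, blank 250 ms, cue at SOA ∈ {100…750} ms, target ≤ 500
  ms, ITI 250 ms) and 70% cue validity; scores commissions, omissions,
  joint error rate, go reaction time, response rate.
* **Adaptive delay discounting** — 5-choice adjusting-amount bisection
  per delay (start `A/2`, halving steps), money and time variants;
  indifference estimates bracket a deterministic agent's present value
  within `A/64`, and hyperbolic rates `k` in `V = A/(1 + kD)` are
  recovered by grid-search maximum likelihood.

**Instruments** — the 20-item bipolar semantic-differential scale scored
against its published six-factor structure (shipped as a CSV fixture),
its 10-item momentary state form, Cronbach's alpha, and a 4×4
photographic affect grid (valence × arousal with a documented circumplex
map to positive/negative affect).

**Protocol** — baseline + 21 days × {morning, evening} + day-21 closing
slot, each momentary slot carrying the state form, an affect reading and
one randomly assigned task; adherence scoring with the 80% bonus rule.

**Synthetic cohort** — six orthogonal latent trait factors per
participant; questionnaire scales, task parameters and momentary state
dynamics (AR(1) days, calibrated morning–evening correlations, signed
evening shifts, mood–state coupling) all derive from them. One root seed,
independent per-participant substreams.

**Psychometrics** — correlation-matrix PCA with Kaiser-normalized
varimax, explained-variance accounting, convergent-validity tables,
test–retest contrasts (person-level aggregation, paired *t*), and
mood–state correlation tables.

Task definitions are JSON step documents (instruction / question /
active-task), sessions are JSON Lines logs with a long-CSV export, and a
CLI (`inst/scripts/impulsim-cli`, or `cli_main()`) chains
`schedule → simulate → score → analyze`.

## Worked example

```r
library(impulsim)

## the published six-factor loading fixture reproduces its printed
## variance decomposition
ev <- explained_variance_from_loadings(sd_loadings())
round(ev$per_factor)
#> inefficient    negative        calm   unhealthy      thrill intentional
#>          20          18          13           9           7           7
round(ev$total)
#> [1] 74

## a deterministic hyperbolic agent (k = 0.01/day, 180-day delay,
## present value 3.57) walked through the 5-choice staircase:
blk <- run_staircase(hyperbolic_chooser(0.01, 180, 10, beta = Inf),
                     dd_config("mobile"), delay = 180)
blk$choices$choice
#> [1] "sooner" "later"  "sooner" "later"  "later"
blk$indifference_estimate
#> [1] 3.59375      # brackets the true 3.5714 within A/64

## simulate a small study and recover the diurnal correlation of the
## impulsive-intentional item
cfg <- cohort_config(n_participants = 30, seed = 9, n_days = 7)
ds  <- simulate_study(sample_cohort(cfg), config = cfg)
test_retest_contrasts(ds, items = 20L)
#> # A tibble: 3 × 7
#>   item_index pair                    r     t    df     p     n
#> 1         20 baseline_vs_morning 0.312 1.11     29 0.278    30
#> 2         20 baseline_vs_evening 0.211 1.47     29 0.153    30
#> 3         20 morning_vs_evening  0.847 0.758    29 0.455    30
```

The last table reads like the published test–retest layout: the
impulsive–intentional state item correlates strongly between morning and
evening person-means (its generator target is 0.872; at 30 participants
over 7 days the recovered value is noisier than at full scale), while
baseline "in general" reports track daily states only moderately.

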