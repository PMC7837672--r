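---
title: "Models and methods behind the impulsim battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the impulsim battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

impulsim simulates and analyzes a three-task mobile impulsivity battery
embedded in a 21-day morning/evening experience-sampling protocol. This
vignette is the package's account of its models: what each component
computes, which parameters matter and why their defaults were chosen, what
the synthetic cohort does and does not emulate, and the numerical choices
that a maintainer would otherwise have to reverse-engineer from the code.

## The task engines

### Balloon risk task

Each balloon hides a pop threshold drawn uniformly on `{1, ..., N}`. A
player who intends `t` pumps delivers `min(t, threshold)` pumps, loses the
balloon if `threshold <= t`, and otherwise banks `t * reward_per_pump`.
The primary score is the *adjusted average* — mean pumps over unexploded
balloons — along with explosion count, total pumps and earnings. Two
presets: the mobile game (15 balloons, `N = 12`, sized for a roughly
two-minute session) and the laboratory task (30 balloons, `N = 128`, the
convention of the classic computerized version). The uniform threshold and
the 0.05-per-pump reward are conventions: the mobile task's published
description names the balloon count but neither the threshold support nor
the increment. Under a fixed target `t` the expected per-balloon payout has
the closed form `reward * t * (N - t) / N`, which the tests use as an
independent oracle against Monte-Carlo play.

Players are abstracted to a *target-pump policy* (a function from balloon
index to intended pumps). Scoring depends only on pumps and explosions, so
pump-by-pump interleaving adds nothing for simulation purposes; a
stochastic policy around a person-level characteristic pump count is what
the cohort module uses.

### Cued go/no-go

Trial timing follows the published mobile sequence: fixation 250 ms, blank
250 ms, orientation cue for one of six stimulus onset asynchronies (100,
200, 300, 400, 500, 750 ms), then a go or no-go target shown until
response or 500 ms, with a 250 ms intertrial interval. Cues signal the
upcoming target with 70% validity. Validity is realized per-trial
Bernoulli rather than by exact-count balancing — 70% of 75 trials is not
an integer, and the published description states a probability. Cue
orientation is a fair coin, so the go rate is 50%: the mobile task's
go-target base rate is not in the public record, and a symmetric design is
the neutral choice.

The two published descriptions of the task disagree on the cue mapping
(horizontal cue signals go in the mobile description, vertical in the
laboratory one); both are preserved as presets rather than resolved. Lab
timing parameters are not published either, so the lab preset reuses the
mobile timings and differs only in trial count (250) and cue mapping.

Scoring counts *commissions* (response on no-go), *omissions* (no
in-window response on go), their joint error rate over all trials, mean
reaction time over correct go responses, and the response rate. A response
at exactly the window boundary counts as responded; beyond it the trial is
unanswered. The simulated responder omits go responses at a person-level
rate, draws lognormal reaction times (draws beyond the window become
omissions), and fails to inhibit on no-go trials with a probability that
is logistic in the SOA — shorter cue-target intervals produce more
commissions, the cue-dependence this task family is designed to elicit.
The exact form of that dependence is not published; the logistic-in-SOA
default (slope 0.3 logits per 100 ms) is a documented choice.

### Adaptive delay discounting

The adjusting-amount staircase titrates an immediate offer against a fixed
larger-later reward `A` (default 10 units; hypothetical dollars for the
money variant, hours of free time as a labeled stand-in for the time
variant). The first offer is `A/2`, and after choice `i` the offer moves
by `initial_step / 2^(i-1)` — down after a sooner choice, up after a later
one. This bisection rule is the standard convention for short titrations;
the published description says only that offers vary with the previous
response, and whether the first mobile offer was `A/2` is not printed.
After `n` choices the indifference estimate takes one more (virtual)
half-step: it is exactly the offer the staircase would have presented
next. For the 5-choice mobile preset the estimate therefore lands within
`A/64 = 0.15625` of a deterministic agent's true present value whenever
that value lies inside `(0, A)` — the bracketing resolution of the design.

The mobile preset runs exactly 5 choices per delay, with money delays
{30, 180} days and time delays {180, 365} days (one month, six months, one
year). The lab preset titrates up to 30 trials per delay, stopping once
the step falls below 1% of `A`; with halving steps that happens after six
choices, which is the designed behavior of convergence-stopped bisection,
and its delays {2, 30, 180, 365} are a convention (unpublished for the
source procedure). Probability discounting is out of scope.

Discount rates are estimated by grid-search maximum likelihood under the
hyperbolic value model `V = A / (1 + kD)` with a logistic choice rule
(fixed inverse temperature, default 2 per reward unit), on a log grid of
10 points per decade over `[1e-4, 10]` per day. Ties resolve to the
smaller `k`; all-identical choice sets only bound `k` and return a flagged
grid endpoint. For deterministic agents at the designed delays, recovery
is within one grid cell for the canonical rates {0.001, 0.01, 0.1}/day.
Across a cohort with lognormally distributed rates, a small fraction of
k-delay combinations have bracketing resolution slightly coarser than one
log cell, so the cohort-level property is stated statistically (at least
90% within one cell, all within two).

One point where this package deviates from a naive reading of the design:
for a titrating staircase the *later-choice propensity* is not monotone in
`k` — titration drives every non-extreme agent toward an alternating
choice pattern — so the monotone readout tested and recommended is the
indifference estimate, which decreases in both `k` and delay.

## Instruments

The 20 bipolar semantic-differential items are scored against the
published six-factor structure (inefficient, negative, calm, unhealthy,
thrill, intentional), shipped as a CSV fixture. Factor scores are
unit-weighted signed means: responses are midpoint-centered and half-range
normalized to `[-1, 1]` (making scores independent of whether a 0–100
slider or a 1–7 scale encoded the same positions), multiplied by the sign
of the item's assigned loading, and averaged within factor. Unit weighting
follows the convention of reporting factors by item assignment;
loading-weighted scoring is available as an option. The response scale
itself is unpublished; the 0–100 slider default is a documented choice.
The sign convention follows the printed loading signs — a full-right
response on Impulsive–Intentional (loading +0.908 on the intentional
component) scores +1 on that factor. Whether the Bored–Engaged item was
reverse-keyed before the original component analysis is unknown; the
fixture records only the sign of its printed loading.

The affect meter maps a 4 x 4 photo grid to valence (column) and arousal
(row). Its validated photo-to-affect calibration is in cited prior work
and not in the public record, so positive and negative affect use a
transparent linear circumplex stand-in
(`positive = ((valence-1) + (arousal-1))/6`, `negative = ((4-valence) +
(arousal-1))/6`), clearly labeled configurable. Under this map, negative
affect is non-increasing in valence at fixed arousal — the property the
tests pin down.

Internal consistency uses the standard Cronbach formula.

## Protocol

The plan is baseline (day 0: trait form, affect meter, all three tasks),
21 days of morning and evening slots (state form, affect meter, one task
drawn i.i.d. uniformly from the three — the published schedule says
"randomly display one", and balanced assignment is offered only as an
option), and a day-21 closing slot (trait form, all three tasks, no
affect meter). Slot identity is protocol-defined, not clock-derived. A
momentary slot is *complete* only when all of its components are logged,
matching the assessment-level 80% bonus rule; partial completions are
reported separately.

## The synthetic cohort

The generator's purpose is to produce study datasets whose analysis
reproduces the statistical structure the validation pipeline is meant to
detect — not to impersonate any real sample.

**Traits.** Six orthogonal standard-normal latent factors per participant
(orthogonality matches a varimax solution). Questionnaire scales are
linear trait combinations plus noise whose weights echo the published
sign pattern: inefficiency loads on attention/perseverance-type scales,
thrill on sensation seeking, intentionality negatively on most.

**States.** For each of the 10 momentary items, a participant has latent
general, morning-mean and evening-mean values sharing the item's trait
projection. The morning–evening correlation is set *directly* per item
from the published fixture; because person-level means are estimated from
21 noisy days, the latent correlation is inflated by the exact attenuation
factor `(1 + vbar)`, where `vbar` is the closed-form variance of the mean
of 21 AR(1) values (autocorrelation 0.4, marginal SD 0.5 — states as
mostly-stable attributes with moderate daily wobble). This calibration was
verified unbiased at large cohort size (recovered 0.872 at n = 20,000 for
the impulsive–intentional item); at the study's n = 100 the person-sampling
standard error of such a correlation is about 0.025, which is the
irreducible spread of any single recovered value. Evening means shift by
0.2 latent SD in the published directions (more impulsive, distracted,
aimless, tired, pessimistic, thrill-seeking in the evening; no shift for
boredom, loneliness, shame, frustration), a standardized diurnal effect in
the range implied by the published paired contrasts. The general-form
latent shares 32% of its variance with the momentary means, putting
baseline-versus-daily correlations in the published moderate band. Latent
values map to the 0–100 scale at 12 points per SD around 50, clipped at
the bounds (clipping is a < 0.3% tail event at these settings).

**Mood.** Latent valence and arousal are weighted sums of the current
standardized states plus noise (SD 0.8), with weights whose signs follow
the published mood–state table (tiredness lowers arousal, contentment
raises valence, and the impulsivity-specific items couple only weakly),
discretized onto the 4 x 4 grid at standard-normal quartiles. One
published cell prints a positive morning valence correlation for
Optimistic–Pessimistic while every neighbouring cell for that item is
negative; the package treats it as a sign typo and uses a negative
coupling.

**Task behavior.** Cross-modal links are linear in the traits with
independent noise: characteristic pumping `4.5 + 0.9 * thrill + noise`
(put near the explosion rates a 12-threshold game implies), inhibition
failure rising with inefficiency/impulsivity, go response rate falling
with thrill seeking, log discount rate `log(0.01) + 0.6 * impulsivity +
noise`. The published mobile-task correlations these defaults echo are
point estimates from one sample, so they anchor signs and rough
magnitudes, not exact targets.

**Seeding.** One root seed; every participant consumes an independently
derived substream (a deterministic integer hash kept below 2^31), so
growing the cohort never perturbs earlier participants, and the whole
study is bit-reproducible from the root seed.

**What the generator does not emulate.** Missingness and attrition
(adherence machinery exists, but the simulator skips nothing), response
styles and floor/ceiling abuse, practice and fatigue effects across the 21
days (the published mobile go/no-go showed drifting error-rate
reliability, which this model does not produce), within-day mood dynamics
beyond one reading per slot, and the demographics of any real cohort.
Passing recovery tests therefore show that the *analysis machinery* is
correct and calibrated, not that real data would behave this way.

## Factor-model data generation and the variance round trip

`generate_sd_from_factor_model()` simulates respondents from `X = F L' +
E` with standard-normal factor scores and per-item unique variance
`1 - communality` (floored at 0.05). The default noise rule places the
unique variance in the *orthogonal complement* of the component space,
built by alternating projections so that per-item noise variances are
preserved exactly. The reason is self-consistency: the shipped loading
matrix consists of principal-component loadings, i.e. the top of a PCA
spectrum. If unique noise were instead independent across items, the
leading six sample components would absorb roughly their share of it and
report about 81% explained variance instead of the 74% the loadings
imply — a property of PCA, not a bug. With complement-confined noise the
population eigenstructure below the retained components is untouched, and
the round trip (simulate at n = 5000, PCA, varimax) returns both the
published 74% total and the published item-factor assignment (at least
18 of 20 dominant loadings; in practice 19–20). The classic independent
noise rule remains available for consumers who want common-factor data.

## The analysis pipeline

PCA runs on the correlation matrix (items standardized internally), keeps
a fixed component count — six for the replication fixture, since the
original retention rule is unpublished — and applies Kaiser-normalized
varimax (tolerance 1e-6, deterministic initialization). Column signs are
fixed so each component's largest-magnitude loading is positive, and
components are ordered by rotated variance. Rotation preserves the total
explained variance of the retained components to machine precision, which
the tests assert.

Correlation cells are Pearson `r` with two-sided `p` from the `t`
transform on pairwise-complete observations (cells with fewer than three
pairs, or a constant margin, are reported as missing with their pair
count). Test–retest contrasts aggregate morning and evening responses to
person-level means first — the aggregation the published degrees of
freedom imply — then compute `r` and a paired `t` listwise per occasion
pair; identical conditions yield `t = 0` by convention rather than `0/0`.
Raw p-values are reported without multiple-testing correction, matching
the published tables; a Benjamini–Hochberg option exists but is off by
default. The mood–state table correlates person-level means of each state
item with each affect metric separately for morning and evening slots.

## Problem sizes and determinism

The shipped tests and the acceptance script use: 10,500 generated
go/no-go trials for the cue-validity check (binomial SE 0.45 percentage
points), 1e5 balloons per fixed-policy Monte-Carlo check, all 32 choice
sequences for the staircase oracle, n = 5000 respondents for the factor
round trip, and a 100-participant, 21-day study for pipeline recovery —
sizes at which every stochastic check resolves well inside its stated
tolerance while a full run stays in the minutes range on one core. All
randomness flows from explicit seeds through R's generator; identical
seeds give bit-identical schedules, sessions and datasets.

## Known limitations

Task timing is simulated, not measured: no display latency, touch
sampling, or hardware calibration enters the model. The affect map is a
stand-in pending the validated calibration. The discount-rate estimator
fixes the choice temperature rather than profiling it (5 choices per
delay cannot identify both parameters usefully). The generator's
cross-modal effect sizes are design defaults, not estimates. And the
published real-cohort validity coefficients are facts about undeposited
data; this package reproduces the machinery and demonstrates calibrated
recovery on synthetic cohorts, which is the strongest claim simulation
can support.
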