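---
title: "Simulating and evaluating hourly activity prompts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating hourly activity prompts: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`jitaipa` implements a complete in-silico version of a two-week, two-arm
just-in-time adaptive intervention (JITAI) for physical activity: wrist-worn
tracker minute streams, hourly prompt decisions against personalized (PIC) or
uniform (UIC) thresholds, and the multilevel evaluation of the prompts'
proximal (next-hour) and weekly effects. This vignette explains the models,
the tunable parameters, and the design choices made where the underlying
study protocol leaves details open.

## The intervention design

Each participant wears a tracker that reports, per minute: steps, distance
(m), calories (kcal), an intensity class (sedentary / lightly / fairly /
very active) and a wear state (worn / sleep / nonwear). At minute :34 of
every hour between 8 AM and 10 PM (14 decision epochs per day), the
preceding 60 minutes `[h-1:34, h:33]` are aggregated and a prompt is sent
when **both**

* hourly distance moved < `theta_distance`, and
* hourly sedentary time > `theta_sedentary`

hold strictly. Thresholds are one SD away from a mean so that ordinary
fluctuation around typical behaviour does not trigger prompts:

* **PIC** (personalized): `theta_distance = mean - SD`,
  `theta_sedentary = mean + SD` of the participant's *own* valid week-1
  hours;
* **UIC** (uniform): the same formulas applied to the pooled person-hours of
  a separate reference cohort (n = 47 by default), shared by all UIC-arm
  participants.

Week 1 is observation only; prompts run during week 2.

## Evaluation models

Both model sets are two-level linear mixed models fitted by REML
(`fit_mlm()`), with person-level random intercepts and, optionally, random
time slopes:

$$y_{ti} = \beta_{0i} + \beta_{1i}\,\mathrm{time}_{ti} + \varepsilon_{ti}$$
$$\beta_{0i} = \gamma_{00} + \gamma_{01}\,\mathrm{group}_i +
  \gamma_{02}\,\mathrm{BMI}_i + \gamma_{03}\,\mathrm{sex}_i + u_{0i}, \qquad
  \beta_{1i} = \gamma_{10} + \gamma_{11}\,\mathrm{group}_i\,[+\,u_{1i}]$$

* **Model set A** (proximal): `time` is the before/after-prompt phase; one
  before/after pair per delivered prompt (`build_prepost()`), the before
  hour being the decision window and the after hour the 60 minutes from the
  epoch.
* **Model set B** (weekly): `time` is week 1 vs week 2; observations are
  per-participant hourly means over valid decision-grid hours
  (`build_weekly()`).

Group is coded UIC = 0 / PIC = 1 and time before/week-1 = 0, so
$\gamma_{10}$ is the UIC change and $\gamma_{11}$ the PIC excess — the
difference-in-change that is the study's primary contrast
(`group_contrast()`).

Choices the protocol leaves open, resolved here:

* **Random vs fixed slope** is selected by AIC over two REML fits with
  identical fixed effects (`random_slope = "auto"`); ties resolve to the
  simpler fixed slope, which also makes selection deterministic on refits.
* **Degrees of freedom** use the between/within partition (SAS-style
  containment): person-level effects get $N - 4$, time-varying effects
  $n - N - 2$. Satterthwaite-type approximations are deliberately not used.
* **Cell means** (`cell_means()`) evaluate the fixed effects at BMI centred
  on the sample mean and sex at the sample proportion female; SEs come from
  the fixed-effect covariance. The interaction always equals the cell-mean
  difference-in-change algebraically, which the tests assert to 1e-8.
* **Within-group change p-values** are Tukey-Kramer adjusted over the four
  group-by-time cells (`adjust_tukey_kramer()`): the Kramer pairwise SE
  feeds $q = \sqrt{2}\,|d|/\mathrm{SE}$ into the studentized range
  distribution. With two cells this reduces exactly to the two-sided pooled
  t-test, which the tests check against a numeric-integration oracle.
* **Baseline comparisons** (`descriptives()`) use pooled-variance two-sample
  t tests ($df = n_1 + n_2 - 2$) and a chi-square test *without* continuity
  correction for sex — the uncorrected statistic is what reproduces the
  published p-value for a 9/5 vs 7/7 split.
* Overlapping pre/post pairs from prompts in consecutive hours are retained;
  hours with fewer than 50/60 worn minutes are excluded everywhere (see
  below).

## The synthetic cohort

`generate_cohort()` / `simulate_trial()` emulate the study conditions: 28
participants in a seeded 1:1 PIC/UIC split observed for 14 days, plus a
47-person reference cohort. Latent hourly activity for person $i$ in waking
hour $t$ is

$$a_{ti} = \max\!\big(0,\; b_i\, d(\mathrm{hour}) + e_{ti}\big) + \delta_i
  \,\mathbb{1}[\text{prompt in previous epoch}],$$

with $b_i \sim N(\mu, \sigma_b^2)$, $e_{ti} \sim N(0, \sigma_w^2)$, a
diurnal multiplier $d(\cdot)$ normalised to mean 1, and the behavioural
response $\delta_i$ equal to the arm's configured increment
(`response_pic` / `response_uic`), acting on the single following hour only
— the same horizon Model set A measures.

Latent distance is realized as minutes: steps = `a / stride` (stride
defaults to 0.414 x height), active minutes = `a / pace` (the *sedentary
link*: one active minute per `pace` metres), steps split over the active
minutes proportionally to Exp(1) weights with an exact-sum correction, the
per-minute intensity class assigned by step-rate cut points (0 sedentary,
1–79 lightly, 80–119 fairly, >= 120 very), and calories as 1.1 kcal resting
plus 0.04 kcal per step. Sleep fills 22:34–07:33 (the sleep window aligned
to the :34 decision grid so no analysis window is part-sleep); each waking
hour is wholly nonwear with probability `p_nonwear`.

Default parameters, with units and rationale:

| parameter | default | meaning / why |
|---|---|---|
| `mu_distance` | 250 m/h | mean hourly distance; matches the magnitude of published weekly hourly means (~230–260 m/h) |
| `sigma_between` | 30 m/h | SD of person baselines; moderate between-person spread (see below) |
| `sigma_within` | 100 m/h | hourly SD around the baseline; dominates the threshold width |
| `pace_m_per_min` | 15 m | distance per active minute; gives ~43 sedentary min/h at the mean, matching published magnitudes |
| `p_nonwear` | 0.05 | occasional nonwear hours (showers, charging) |
| `response_pic` / `response_uic` | 150 / 75 m/h | next-hour response; their difference (75 m) is the ground-truth interaction |
| `n_days` | 14 | two-week design, split 7 + 7 |

With these values the pooled reference thresholds come out near
(mean - SD, mean + SD) = (133 m, 51 min) — the same order as published
uniform criteria — and the derived personalized thresholds span the
published range.

**Why `sigma_between = 30`.** Threshold rules that fire when the past hour
sits one SD below the mean select unusually low hours, so the before-hour is
subject to regression to the mean. Personalized thresholds induce the same
selection depth (~1 SD) for everyone; a shared uniform threshold sits at
different depths for different people, and the two arms' selection effects
then cancel in the difference-in-change only approximately. An analytic
truncated-normal calculation shows the residual selection bias on
$\gamma_{11}$ grows with the between-person spread relative to the uniform
threshold; at $\sigma_b = 30$ it is a few metres, small against the 75 m
response contrast, so the pipeline's interaction estimate is interpretable
as the behavioural response. This is a property of the study design, not of
the estimator; the parameter was fixed by this analysis before the
simulation studies were run.

### What the generator does and does not emulate

Emulated: between-person activity levels, within-person hourly variability,
a diurnal profile, sleep structure, occasional nonwear, stride-based
distance, device-style intensity classes, and a configurable next-hour
response to prompts with full closed-loop feedback (a prompt raises the next
hour, which can prevent the next trigger).

Not emulated: the right skew of real activity distributions (hourly latent
activity is truncated normal, so simulated prompt rates run ~2/day versus
the ~4/day a skewed real cohort produces), the proprietary device
classifier (step-rate cut points are an invented stand-in), context
(weather, location), habituation or novelty effects, and clock details
(timestamps are a naive local clock; no DST). Passing tests therefore show
the pipeline recovers effects under the stated hierarchical model, not that
the model captures every feature of field data.

## Numerical and data-handling choices

* Missing minute rows are treated as nonwear zeros, which makes hourly
  aggregation additive over any partition of a window's minutes.
* An hour enters criteria, decisions or analysis only with >= 50 of 60
  worn minutes (`min_wear_min`); the protocol states only that sleep and
  nonwear data were excluded, so the 50-minute floor is this package's
  operationalisation.
* Sample SDs use the n-1 denominator; thresholds are clamped to [0, inf) m
  and [0, 60] min and kept at full precision internally (reports round to
  integers).
* UIC pools person-hours (grand mean/SD over the reference cohort) rather
  than averaging per-person criteria; the source protocol does not say
  which was used.
* Both trigger inequalities are strict, so an hour exactly at a threshold
  never prompts; consecutive-hour prompts are allowed (no refractory
  period).
* Steps are integers, so a zero-variance configuration reproduces
  `mu_distance` only to within half a stride (~0.4 m) — the quantization is
  visible in tests as a +-0.5 m tolerance.
* Determinism: a master seed drives a per-participant child-seed sequence
  (cohort growth does not reshuffle earlier participants); minute-placement
  draws live on their own child seed and cannot perturb aggregates; message
  selection is seeded over the sorted event log, so a `run_trial()` replay
  of simulated streams reproduces the closed-loop log bit-identically.

## Problem sizes

The simulation studies shipped with the package use 200 replicates of the
full trial (n = 28, 14 days, closed loop, criteria re-derived per
replicate) for interaction recovery and 95% coverage, and 500 replicates
with the response switched off for type-I error calibration; both run in a
few minutes on one CPU. The weekly model's null behaviour (no week effect
without a response) is checked on constructed data.

## Known limitations

* The evaluation assumes Gaussian outcomes; counts (steps) and bounded
  minutes are fitted on the raw scale, as in the original analysis.
* No imputation beyond hour-level exclusion; participants with under 3
  valid days in a week are flagged, not dropped.
* Between/within df are a convention; with 28 participants and hundreds of
  events the interaction test is mildly liberal (empirical size ~6% at
  nominal 5%), partly reflecting overlapping pre/post pairs.
* Live delivery (device APIs, schedulers, notifications) is out of scope;
  the decision engine is replay-first and a clock-driven wrapper would use
  the same functions.
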