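---
title: "Methods: wellbeing indicators around an acute crisis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wellbeing indicators around an acute crisis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(crisiswell)
```

This vignette documents the statistical model behind `crisiswell`, the
conventions of every analysis window, and the design of the synthetic cohort
generator, including the variance algebra that sizes the injected effects.

## Study design

The analysis targets longitudinal wellbeing data — smartwatch, smartphone,
and a short daily questionnaire — collected from a middle-aged-and-older
cohort across an acute armed-conflict episode. Four contiguous calendar
periods partition the study range:

| period | label | dates (2021)      |
|--------|-------|-------------------|
| B      | baseline  | Apr 26 – May 9  |
| W      | war       | May 10 – May 20 |
| R1     | recovery 1| May 21 – Jun 3  |
| R2     | recovery 2| Jun 4 – Jun 17  |

Each day is additionally a *work* or a *free* day. The default calendar uses
a Friday–Saturday weekend plus a configurable national-holiday list
(defaulting to Shavuot, May 17 2021). `study_calendar()` owns all of these
choices; `study_days()` enumerates the labelled days.

```{r}
head(study_days(study_calendar()))
```

Twelve daily indicators are analysed. Six arrive via the questionnaire
(mood, stress, sleep quality, sleep duration, sport time, encounters) and six
from devices (screen-on time, percent time still, steps, average heart rate,
awake time, sleep start hour).

## Period aggregation

Free days differ systematically from work days, and the four periods contain
unequal shares of them. Each participant–indicator–period is therefore
summarized by a reweighted mean: the mean over work days and the mean over
free days are combined with fixed weights

$$\bar y = \tfrac{5}{7}\,\bar y_{\text{work}} + \tfrac{2}{7}\,\bar y_{\text{free}},$$

restoring the long-run 5:2 weekly composition regardless of which days the
participant happened to record. A participant enters an indicator's test only
with at least one work-day and at least one free-day value in *every* period
the test needs (`apply_inclusion_filter()`), so the effective n differs per
indicator.

## The split-plot mixed ANOVA

`mixed_anova()` fits the classical split-plot decomposition for one
between-subjects factor (exposure group $g$, with subjects nested inside) and
one within-subjects factor (period $t$):

$$y_{st} = \mu + \alpha_{g(s)} + \pi_s + \beta_t + (\alpha\beta)_{g(s)t} + \varepsilon_{st}.$$

The total sum of squares splits exactly — balanced or not — into five parts
via subject-level projections:

* **group**: $a\sum_g n_g(\bar y_g - \bar y)^2$, tested against
  **subject(group)**: $a\sum_s(\bar y_s - \bar y_{g(s)})^2$;
* **period**: $S\sum_t(\bar y_t - \bar y)^2$ and the **period × group
  interaction**, both tested against the within-subject **residual**.

Only subjects with a complete set of period values are analysed (incomplete
subjects are dropped with a message). No sphericity correction is applied by
default; `gg = TRUE` adds Greenhouse–Geisser adjusted p values, with
$\hat\varepsilon$ computed from the pooled within-group covariance of the
period vectors and clamped to $[1/(a-1), 1]$.

Significant effects are followed up with `bonferroni_posthoc()`: two-sided
paired t tests on the baseline-containing period pairs (B–W, B–R1, B–R2),
multiplied by the family size $m = 6$ (all pairwise comparisons among four
periods) and clamped at 1. Effect sizes are the paired Cohen's d,
$\bar d / s_d$. A significant interaction is followed up by running the same
pairs separately inside each exposure group (`by_group = TRUE`).

## Exposure classification

Exposure is the distance from a participant's residence to a conflict
reference point (default 31.5017° N, 34.4668° E). Residence is inferred from
GPS (`infer_residence()`): baseline-period samples whose local clock time
falls in [03:30, 04:30) — when nearly everyone is home — are snapped to a
3-decimal-degree grid (~110 m) and the modal cell wins, ties going to the
earliest-observed cell. Participants without qualifying samples fall back to
their stated hometown. The great-circle distance (haversine, radius
6371 km) is cut at 60 and 110 km:

* **high**: < 60 km, **medium**: 60–110 km (both ends inclusive),
  **low**: > 110 km,

reflecting the time available to reach shelter after a siren sounds.

## Siren heart-rate response

For each siren in a participant's area, the acute response is

$$\Delta = \max_{[t-5', \,t+15']} \text{bpm} \;-\; \text{mean}_{[t-45', \,t-15')} \text{bpm},$$

with the baseline window half-open and the affected window closed. Two
filters precede it: the siren's local time must lie in [02:00, 06:00) —
minimizing physical-activity confounding — and no other siren of the same
area may fall in the open interval $(t-45', t-15')$, which would contaminate
the baseline. Participants are summarized by their mean $\Delta$, the cohort
by the median of those means. As a max-minus-mean statistic, $\Delta$ carries
a small positive bias on impulse-free noisy series; this is a property of the
estimator and is documented rather than corrected.

## Subgroup analysis of changes

`subgroup_anova()` models each participant's war-minus-baseline change
$\Delta_i = \bar y_{i,W} - \bar y_{i,B}$ with an additive between-subjects
ANOVA on exposure (restricted to the affected medium/high tiers), age group
(59 and below vs 60 and above), gender, income level (participants with
unspecified income are excluded from that factor), and baseline level (below
vs at-or-above the population median of the baseline weighted mean, ties
counting as at-or-above). Sums of squares are Type III — obtained by
deleting each factor's columns from the full design — which with only main
effects coincides with Type II and is contrast-invariant. Adjusted level
differences come straight from the model coefficients.

## The synthetic cohort generator

`simulate_cohort()` produces a full bundle — profiles, daily device
indicators, questionnaires (with evening submissions, occasional earlier
duplicates, and missingness), 15-minute GPS traces, siren events, and
minute-level heart rate — from a single `sim_config()` seed. Each stream
draws from its own derived seed, so regenerating one stream never perturbs
another.

A day-level value for participant $i$, indicator $k$, day $d$ is

$$y_{ikd} = \mu_k + b_{ik} + \delta_k\,[d \text{ free}] + s_{ik}\,m_k(d) + \epsilon_{ikd},$$

with a participant-level baseline offset $b_{ik}$, a free-day offset
$\delta_k$, day-level noise $\epsilon_{ikd}$, and a war shift $s_{ik}$ active
according to the period multiplier $m_k(d)$ (1 in W, decaying through R1/R2).
Self-report indicators are generated on a continuous scale — a deliberate
simplification over discrete response categories that keeps the injected
effect sizes exact; values are clipped to their instruments' ranges.

### Sizing standardized shifts

Configured war effects are standardized (Cohen's d), and the d the *analysis*
measures is on the paired difference of weighted period means, not on raw
days. The generator therefore converts d to indicator units with the analytic
scale `paired_diff_sd_ref()`. For day-level noise SD $\sigma$ and fill
probability $p$, the weighted period mean has variance

$$\sigma^2\left[\left(\tfrac57\right)^2 E\!\left[\tfrac1{n_w}\right] + \left(\tfrac27\right)^2 E\!\left[\tfrac1{n_f}\right]\right],$$

where $n_w \sim \text{Binomial}(N_w, p)$ counts recorded work days
(conditioned on $n_w \ge 1$, the inclusion rule) and similarly for free days;
the paired B–W difference adds the two periods' variances. Injecting
$s_{ik} = d \times \text{sd}_{\text{ref}}$ makes the recovered aggregate-level d
match the configured one in expectation, which the acceptance checks verify
at n = 700.

Siren responses are injected as exponential impulses
$A\,e^{-\Delta t/\tau}$ ($\tau = 6$ min) on a heart-rate series with a
cosine diurnal term whose nadir sits at 04:00 — flat across the 02:00–06:00
analysis window — so the windowed statistic recovers $A$ up to two small,
opposing distortions: decay between the siren second and the next minute
sample, and the positive noise-max bias.

## Worked example

```{r, eval = FALSE}
cfg <- sim_config(n_participants = 250, seed = 42)
bundle <- simulate_cohort(cfg)
res <- run_wellbeing_analysis(bundle, cfg$calendar,
                              indicators = c("mood", "stress"))
print(res)
summary(res$fits$mood$fit)
res$siren$median_delta_bpm
```

Archiving and re-reading a cohort reproduces the analysis exactly:

```{r, eval = FALSE}
dir <- tempfile(); write_cohort(bundle, dir)
res2 <- run_wellbeing_analysis(read_cohort(dir), cfg$calendar)
```

## Limitations

* The split-plot F tests assume sphericity; use `gg = TRUE` when the period
  covariance structure is in doubt.
* The siren statistic's positive noise bias means cohort medians sit close
  to, but not exactly at, the injected amplitude; overlapping sirens can
  inflate individual affected windows because the isolation filter guards
  only the baseline frame.
* The non-recovery flag (`flag_non_recovered()`) is a robust outlier rule,
  not a clinical threshold, and refuses to run below 10 participants.
* Exposure tiers inherit the uncertainty of residence inference near the 60
  and 110 km boundaries; `assign_exposure()` messages when participants fall
  within 5 km of a cut.
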