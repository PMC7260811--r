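---
title: "Quantifying visit irregularity in longitudinal data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying visit irregularity in longitudinal data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irregbin)
```

## The problem

Observational longitudinal studies rarely observe every subject at the same
times. Visit timings drift around a protocol schedule, scheduled visits are
missed, and in many cohorts the timing of the next visit depends on how the
patient is doing — sicker patients come back sooner. Standard repeated-measures
and mixed-model analyses assume the observation times are uninformative; when
the visit process depends on the outcome, ignoring it biases the estimated
outcome trajectory. Before choosing an outcome model one therefore needs an
answer to a descriptive question: *how far is this dataset from repeated
measures, and in which direction — missingness or irregularity?*

`irregbin` answers that question with bin-based summaries. The study period
$(0, \tau)$ is divided into bins; within each bin we record, among the
subjects under follow-up for the whole bin, the proportions with exactly 0,
exactly 1, and more than 1 visit. Perfect repeated measures put every subject
at exactly one visit per (anchored) bin: the proportions are $(0, 1, 0)$
whatever the bin width. Missed visits inflate the 0-visit proportion;
genuinely irregular timings inflate the $>1$-visit proportion. The package
also fits an Andersen-Gill model for the visit intensity and exports
inverse-intensity weights for use in downstream outcome analyses.

## Bins

Two constructions are provided.

**Schedule-anchored bins** (protocols with pre-specified visit times
$T_1 < \dots < T_k$): the bin around $T_j$ is
$[L_j, R_j) = [T_j - f_L (T_j - T_{j-1}),\; T_j + f_R (T_{j+1} - T_j))$,
with gap fractions $f_L, f_R \in (0,1)$ that may differ — a small left
fraction encodes "visits cannot happen early" (billing rules, minimum ages
for vaccination). Two conventions close the formula at the edges: the study
origin stands in for $T_0$ and the horizon $\tau$ for $T_{k+1}$. Both are
design choices of this package; they keep $L_1 > 0$ and extend the printed
rule symmetrically. Fractions of 0.5 make touching bins; anything larger is
rejected as overlapping.

**Uniform bins** (no pre-specified times): $[0, \tau)$ is tiled by $n$
equal-width, adjacent bins. Hand-crafted unequal-width bins are accepted via
`bin_set()`, but nothing optimises them.

All bins are half-open $[L, R)$. The choice is a tie-break convention: a
visit exactly at a cut-point must belong to exactly one side, and half-open
intervals make touching bins a partition. It is fixed package-wide rather
than exposed as an option, because mixing conventions across functions is a
reliable source of off-by-one-visit bugs.

### Censoring and the at-risk set

A subject counts toward a bin's denominator only when under follow-up for
every time in the bin: $\text{entry}_i \le L_j$ and $\text{end}_i \ge R_j$,
where `end` is the subject's *administrative* closure (dataset closure), not
their last visit. Subjects lost to follow-up therefore stay at risk beyond
their last visit — their absence of visits is signal, not censoring — while
bins before entry or after closure never penalise them. Bins with an empty
at-risk set are excluded from the across-bin means and reported.

The across-bin mean is unweighted by default. The alternative — weighting
each bin by its at-risk count — is available (`weight = "at_risk"`); with
staggered entry it shifts the means toward the well-populated bins. We default
to unweighted because the summary is meant to describe the pattern *per bin*,
not per subject-bin, and because it keeps the perfect-cohort identity exact
under any censoring pattern.

Visits falling between anchored bins are counted nowhere; they are tallied in
a diagnostic (`uncovered`) so that a narrow-bin analysis cannot silently
discard most of the data.

## The bin-width sweep and the decision rule

A single bin width can mislead, so both constructions are swept:
`sweep_schedule()` fixes $f_L$ (default 0.05) and varies $f_R$ over 1–95% of
the gap in 1% steps; `sweep_uniform()` varies the number of bins, by default
from 2 up to $\max(50, \lceil \tau / \tilde g \rceil)$ where $\tilde g$ is
the median inter-visit gap — wide enough to reach the repeated-measures
regime from above and the sparse regime from below.

`classify_visits()` implements a two-step rule on the sweep:

1. find the bin width maximising the mean 1-visit proportion (`width_star`;
   ties go to the smallest width, the more conservative reading since
   narrower bins are harder to satisfy);
2. at that width, if the mean $>1$-visit proportion exceeds $\varepsilon$
   the pattern is **irregular**; otherwise if the 0-visit proportion exceeds
   $\varepsilon$ it is **repeated measures with missingness**; otherwise
   **repeated measures**.

As supporting evidence the largest width keeping the $>1$-visit proportion
below $\varepsilon$ is reported with its proportions. The tolerance
$\varepsilon$ defaults to 0.01: sample proportions from a few hundred
subjects are essentially never exactly zero, and values of a few per mille
are indistinguishable from zero at realistic cohort sizes. $\varepsilon$
does not currently scale with cohort size; at very large $n$ a smaller value
is defensible and the argument is exposed.

```{r classify}
sched <- visit_schedule(c(2, 4, 6, 8, 10), tau = 12)
miss <- simulate_missing(150, sched, p_miss = 0.3, seed = 42)
classify_visits(sweep_schedule(miss, sched))
```

## The AUC irregularity score

`auc_irregularity()` condenses a sweep into one number: the trapezoidal area
under the curve of points (mean 0-visit proportion, mean $>1$-visit
proportion) as bin width varies. Perfect repeated measures pin every point at
the origin (score 0); a curve pinned at the top of the unit square scores 1.
Several conventions had to be fixed and are ours, not standard: points are
sorted by the $x$-coordinate, $y$-values at duplicate $x$ are averaged before
integration (which also makes the score invariant to row order), and no
normalisation by the $x$-range is applied.

Two properties of the score are worth knowing before using it.

* It measures *timing* irregularity at a given visit rate. Mechanisms that
  change the overall visit rate move both axes: in our simulations, making
  the intensity depend strongly on a latent outcome *raises* the total
  visit rate (the average of $e^{\beta y}$ exceeds 1), fills otherwise-empty
  bins, and can *lower* the score relative to an outcome-independent process
  at the same baseline rate. The score orders jitter levels cleanly and
  separates schedule-driven from process-driven visits; it is not a test for
  outcome-dependence — that is what the intensity model is for.
* On uniform (unanchored) bins even a perfect schedule scores above zero,
  because some bin widths straddle two schedule times for every subject.
  Comparisons are only meaningful within one sweep construction.

## The simulator

The generators produce cohorts with known ground truth spanning the regimes
the diagnostics are meant to separate. Defaults follow the reference
configuration used throughout the package's validation: 100 subjects,
schedule (2, 4, 6, 8, 10) months, horizon $\tau = 12$ months.

* `simulate_perfect(n, schedule)` — every subject at exactly the schedule.
* `simulate_missing(n, schedule, p_miss)` — each scheduled visit deleted
  independently (MCAR); `miss_coef` makes deletion logistic in a baseline
  covariate (MAR). Deletions can only create 0-visit bins, never $>1$-visit
  bins, which is what makes missingness and irregularity separable.
* `simulate_jitter(n, schedule, jitter_sd)` — truncated-normal timing noise.
  Draws are resampled until the visit order is preserved and times stay in
  $(0, \tau)$, capped at 100 attempts, after which draws are clipped into
  disjoint cells split at schedule midpoints. The cap keeps the generator
  total; at plausible jitter levels (sd well below half the schedule gap)
  clipping is essentially never reached.
* `simulate_irregular(n, tau, lambda0, beta, scenario)` — visit times from a
  counting process with intensity $\lambda(t) = \lambda_0 e^{\beta x(t)}$,
  drawn by Ogata thinning against the constant bound
  $\lambda_0 e^{|\beta| (|\mu| + 6\sigma_\infty)}$, where $\sigma_\infty$ is
  the stationary standard deviation of the latent score. The score follows a
  first-order autoregressive process updated at visits
  ($x' = \mu + \phi (x - \mu) + \sigma e$, defaults $\mu = 0$, $\phi = 0.7$,
  $\sigma = 1$) — the minimal structure in which a slowly varying disease
  activity can drive visits. The `scenario` argument selects what the
  intensity sees: nothing (VCAR, visiting completely at random), the score
  observed at the *previous* visit (VAR, visiting at random — the intensity
  is a function of observed history), or the score that will only be
  observed at the triggered visit itself (VNAR, visiting not at random).
  A baseline rate of $\lambda_0 = 0.5$/month over 12 months gives about six
  visits per subject, comparable to the five-visit schedule.
* `apply_censoring(cohort, admin_end, dropout_rate)` — truncates visits at
  the earlier of administrative closure and an exponential dropout time;
  dropouts are flagged `lost_to_followup` and keep their administrative
  window, so the at-risk rule treats them correctly.

What the simulator does *not* emulate: real protocols' age-dependent visit
spacing, seasonal intensity, measurement error in recorded dates, or
recruitment-at-visit dynamics. Passing the validation suite therefore shows
the measures behave correctly under the stated mechanisms, not that any
particular real cohort is well described by them.

## The visit-intensity model

When the diagnostics indicate irregularity, the next question is whether
visit timing is predictable from observed history (VAR) or wholly
uninformative (VCAR) — VNAR cannot be distinguished from VAR by any model on
observed data. `to_counting_process()` expands a cohort into (start, stop,
event] rows, one per inter-visit interval plus a censored tail, and lags
time-varying covariates by whole visits. With the default `lag = 1` the row
ending at visit $m$ carries the value observed at visit $m-1$, so the
modelled intensity depends only on already-observed history; the interval
before the first visit carries the baseline value, since nothing earlier was
observed. `lag = 0` gives plain last-observation-carried-forward.

`fit_andersen_gill()` maximises the Cox partial likelihood on the start-stop
data via `survival::coxph` with the Efron tie approximation (the accepted
default for recurrent-event fits; ties arise whenever two subjects share a
recorded visit time). The default timescale is the cohort's absolute time
axis (e.g. age), with a follow-up-time alternative. Wald 95% intervals and
p-values are reported; cluster-robust standard errors by subject are an
opt-in (`robust = TRUE`) — they guard against within-subject correlation but
are not forced, since the plain model-based errors are the usual starting
point.

`backward_select()` implements the retain-if-$p < 0.05$ rule literally as a
single step — fit everything, keep what passes, refit once — with iterative
backward elimination behind `iterative = TRUE`. Both log what was dropped.
If nothing survives, a null model is returned with a warning rather than an
error, so that weight computation (all weights 1) still composes.

`inverse_intensity_weights()` returns, per observed visit, the stabilized
weight $e^{-(x - \bar x)'\hat\beta}$ — the baseline intensity cancels, and a
subject at the covariate mean gets weight exactly 1 — or, unstabilized, the
same divided by the Breslow baseline-intensity increment at the visit time.
The weights are exported for downstream inverse-intensity-weighted outcome
models (e.g. weighted GEE); this package deliberately stops short of fitting
the outcome model itself.

```{r intensity}
irr <- simulate_irregular(300, 12, lambda0 = 0.5, beta = log(1.5),
                          scenario = "VAR", seed = 7)
cp <- to_counting_process(irr, covariates = "y", lag = 1)
fit_andersen_gill(cp, "y")
```

## Numerical and validation choices

* Proportions are exact ratios of counts; the perfect-cohort identity
  $(0, 1, 0)$ is asserted as exact equality, not to a tolerance.
* Bin-geometry checks allow touching bins up to $10^{-12}$ slack so that
  fractions like 0.5 tile exactly despite floating-point arithmetic.
* The counting kernel places visits by binary search over the interleaved
  bin boundaries; it is tested for exact agreement against a brute-force
  loop over every (subject, bin, visit) triple on randomized cohorts, and
  the Andersen-Gill coefficients against direct numerical maximisation of a
  hand-coded Efron partial likelihood on small tables.
* Validation problem sizes: 200 random cohorts (up to 30 subjects, 15 bins)
  for the counting oracle; 1000 subjects for hazard-ratio recovery (true
  hazard ratio 1.5 per unit of lagged score recovered within 3 standard
  errors; a null covariate stays within $|z| < 3$); 2000 subjects for the
  missingness calibration (0.30 deletion reproduces a 0-visit proportion
  within $\pm 0.03$); 20 replicates of a six-level irregularity ladder
  (perfect, jitter sd 0.1/0.25/0.5/1.0 months, outcome-driven intensity)
  for the AUC ordering, required monotone in at least 18.

## Limitations

* The classification is a descriptive heuristic, not a hypothesis test; no
  sampling uncertainty is attached to the label or to the AUC score.
* VNAR visiting can never be ruled out from observed data; a clean intensity
  model is evidence of VAR at best.
* The AUC conventions (axis ordering, duplicate handling, no normalisation)
  are this package's; scores should not be compared across tools without
  checking conventions.
* Calendar dates are out of scope: times are plain non-negative numbers and
  unit conversion is the caller's job.
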