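# irregbin

Bin-based diagnostics for visit irregularity in longitudinal data.

## The problem

Longitudinal cohorts collected during usual care rarely observe subjects on a
common schedule: visit timings drift, scheduled visits are missed, and —
critically — visit frequency often depends on how the patient is doing.
Outcome models that ignore an informative visit process (GEE, mixed models
run on unbalanced data) can be badly biased. Deciding how to analyse the
outcome therefore starts with a descriptive question: does this dataset look
like repeated measures, repeated measures with missingness, or genuinely
irregular visits?

`irregbin` answers it by dividing the study window $(0, \tau)$ into bins and
summarising, per bin $j = 1, \dots, k$ and among the subjects at risk for the
whole bin, the proportions $p_{0j}, p_{1j}, p_{>1,j}$ of individuals with 0,
1, and more than 1 visit. For protocols with pre-specified visit times
$T_1 < \dots < T_k$ the bins are anchored,

$$[L_j, R_j) = [\,T_j - f_L\,(T_j - T_{j-1}),\; T_j + f_R\,(T_{j+1} - T_j)\,),$$

with gap fractions $f_L, f_R \in (0,1)$; without a protocol, equal-width bins
tile the window. Perfect repeated measures give mean proportions
$(\bar p_0, \bar p_1, \bar p_{>1}) = (0, 1, 0)$ at every bin width; missed
visits raise $\bar p_0$, irregular timing raises $\bar p_{>1}$. Sweeping the
bin width and applying a two-step rule at the width maximising $\bar p_1$
yields a classification, and the area under the $(\bar p_0, \bar p_{>1})$
curve gives a single irregularity score. For irregular cohorts the package
fits the Andersen-Gill visit-intensity model
$\lambda_i(t) = \lambda_0(t)\, e^{X_i(t)'\beta}$ on counting-process data
with covariates lagged by one visit, and exports inverse-intensity weights
$e^{-(x - \bar x)'\hat\beta}$ for downstream weighted outcome analyses.

A simulator generates cohorts with known ground truth (perfect schedules,
per-visit missingness, timing jitter, history-dependent intensities with
VCAR/VAR/VNAR outcome-dependence, censoring and dropout) and backs the whole
validation suite.

## Worked example

Simulate a cohort whose visit intensity depends on the disease-activity
score observed at the previous visit (hazard ratio 1.5 per unit), then run
the full workflow:

```r
library(irregbin)

coh <- simulate_irregular(300, 12, lambda0 = 0.5, beta = log(1.5),
                          scenario = "VAR", seed = 7)
coh
#> Visit cohort: 300 subjects, 1779 visits (time unit: months)
#>   visits per subject: min 0, median 5, max 16
#>   follow-up window: [0, 12]

sw <- sweep_uniform(coh, tau = 12)
classify_visits(sw)
#> Visit-pattern classification: irregular
#>   max mean p1 at width 2: p0 = 0.423, p1 = 0.315, p2plus = 0.262
#>   largest width with p2plus <= 0.01: 0.2667 (p0 = 0.879, p1 = 0.112)
auc_irregularity(sw)
#> [1] 0.192
```

Even at the most favourable bin width only 31% of subjects average one visit
per bin while 26% average more than one — the pattern cannot be treated as
repeated measures. The intensity model then identifies the driver:

```r
cp <- to_counting_process(coh, covariates = "y", lag = 1)
fit <- fit_andersen_gill(cp, "y")
fit
#> Andersen-Gill visit-intensity model (1779 events / 2079 intervals; Efron ties)
#>  term  coef    se hazard_ratio ci_low ci_high p_value
#>     y 0.415 0.019        1.514  1.459   1.571  <1e-04

head(inverse_intensity_weights(fit, cp), 3)
#>     id visit_time    weight
#> 1 S001   2.151724 0.2912744
#> 2 S001   2.294547 0.7124130
#> 3 S001   7.112236 1.3973213
```

The fitted hazard ratio 1.51 (95% CI 1.46–1.57) recovers the generating
value 1.5: each unit of the previously observed score multiplies the visit
rate by about one half more, so high-scoring subjects are over-represented
among observations. The weights (small when the score was high, large when
it was low) rebalance the visits for an inverse-intensity-weighted outcome
analysis, which is performed downstream of this package.

A contrasting cohort with 30% of scheduled visits missing at random is
classified as `repeated_with_missingness`, and a perfect schedule as
`repeated_measures` — see `vignettes/visit-irregularity.Rmd` for the
decision rule, its tolerance, and the simulator's design.

A thin command-line front end over the same functions ships in
`inst/cli/irregbin.R` with subcommands `simulate`, `bins`, `sweep`,
`classify`, `intensity`, `weights`, `plot`.

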