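# neotherm

Multi-state Markov modelling of neonatal hypothermia recovery from
panel-observed temperature data.

## The problem

Hypothermic newborns in intensive care are scanned every 30 minutes until
their axillary temperature normalizes. Each scan classifies the infant into
one of three states — severe/moderate hypothermia (state 1), mild
hypothermia (state 2), normal (state 3) — and monitoring stops at the first
normal reading, so state 3 is absorbing. The scientific questions are *how
fast* infants move between these states, *how long* they linger in each
hypothermic state, and *which risk factors* (birth weight, 5-minute Apgar
score, pulse rate, ...) speed up or slow down recovery. Because the process
is seen only at scan times, the exact transition moments are interval-
censored: this is panel data, and naive event-time methods do not apply.

`neotherm` is for perinatal epidemiologists and biostatisticians who want
this analysis as a tested, reusable pipeline — including a synthetic-cohort
generator that emulates the whole study design, so every method can be
validated end to end without access to hospital data.

## The model

The thermal state follows a continuous-time Markov chain with generator
*Q*: off-diagonal entries *q_rs* ≥ 0 are transition intensities per minute,
rows sum to zero, and the normal row is zero (*q_31 = q_32 = q_33 = 0*).
The default structure allows 1 ↔ 2 and 2 → 3. Covariates act
proportionally on intensities, *q_rs(z) = q_rs(0) · exp(β_rs·z)*, so
exp(β) is a hazard ratio. Interval transition probabilities solve the
Kolmogorov forward equations, *P(t) = exp(Qt)*, and the log-likelihood of a
cohort is

    L(θ) = Σ_subjects Σ_scans log P[x(t_{j-1}), x(t_j)](t_j − t_{j-1}; z, θ)

maximized over log-intensities and β by quasi-Newton iteration, with Wald
intervals from the observed information. The mean sojourn time in a
transient state is −1/q_ss minutes. Model comparison uses AIC
(−2·loglik + 2p) and likelihood-ratio tests; absolute fit uses a
Pearson-type test comparing observed and model-expected transition counts
in covariate × time cells.

## Worked example

Simulate a study-sized cohort with a birth-weight effect on the
severe-to-mild transition (true hazard ratio 1.50 per birth-weight level,
baseline severe-state sojourn 48 minutes at very low birth weight), fit the
covariate model, and read off the estimates:

```r
library(neotherm)
cfg <- fixture_config("paper-effects", n_subjects = 391, seed = 1)
sim <- generate_cohort(cfg)
fit <- fit_msm(sim$dataset, model = covariate_model("birth_weight"))
fit
#> Three-state panel Markov model fit
#>   subjects: 243   observation pairs: 778
#>   log-likelihood: -694.3257   AIC: 1400.6513   parameters: 6
#>   baseline intensities (per minute):
#>     1->2: 0.02247
#>     2->1: 0.00616
#>     2->3: 0.02059
hazard_ratios(fit)
#>   transition    covariate    hr lower upper se_log
#> 1       1->2 birth_weight 1.449 1.047  2.01  0.166
#> 2       2->1 birth_weight 0.719 0.375  1.38  0.332
#> 3       2->3 birth_weight 0.864 0.693  1.08  0.112
sojourn_table(fit, data.frame(birth_weight = c("vlbw", "lbw", "normal")))
#>   birth_weight severe_minutes mild_minutes
#> 1         vlbw          44.51        37.37
#> 2          lbw          30.72        45.00
#> 3       normal          21.20        53.88
```

Reading: 243 of 391 simulated infants survive the study's inclusion filters
(at least three recorded scans; recovery within 3 hours). The estimated
hazard ratio on the severe-to-mild transition is 1.45 (95% CI 1.05–2.01),
covering the simulation truth of 1.50; the estimated mean time in severe
hypothermia falls from 44.5 minutes for very-low-birth-weight infants to
21.2 minutes at normal birth weight. Note `pearson_gof(fit, sim$dataset)`
rejects here (p ≈ 6e-4) — not a bug: the inclusion filters select on
outcome, and the goodness-of-fit test detects exactly that; see the methods
vignette (`vignettes/hypothermia-markov-model.Rmd`) for the analysis and
for calibration on unselected data.

The full pipeline — descriptive tables, null/covariate/epoch fits, AIC
ranking, likelihood-ratio tests, hazard ratios, sojourn tables, goodness of
fit, stay-probability curves, all serialized to an output directory — is
one call:

```r
report <- run_pipeline(pipeline_config(
  input = list(simulate = cfg),
  model = covariate_model("birth_weight"),
  models = c("null", "covariate", "epoch"),
  out_dir = "analysis-out", seed = 1))
```

A thin command-line wrapper is provided at
`inst/scripts/run_pipeline.R` (`Rscript run_pipeline.R --config cfg.yaml`).

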