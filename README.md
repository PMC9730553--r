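# fdd11

Rasch measurement tooling for the **WHO Functioning and Disability
Disaggregation tool (FDD11)** and similar short polytomous questionnaires.

The FDD11 is an 11-question instrument that asks adults about difficulties in
everyday functioning (seeing, hearing, walking, remembering, self-care,
sleeping, household tasks, community participation, emotions, relationships,
pain), each rated on a 5-point ordinal scale. Under the **Partial Credit
Model (PCM)** — the Rasch model for ordered polytomous items — the
probability that person *n* answers category *k* on item *i* is

```
P(X_ni = k | θ_n) ∝ exp{ Σ_{j ≤ k} (θ_n − τ_ij) },    k = 0, …, m_i,
```

where θ_n is the person's disability level and τ_ij are the item's
thresholds, all on a common logit scale. Because the recoded sum score is
sufficient for θ, every respondent's score maps to a maximum likelihood
ability with a standard error, which a fixed affine map (anchored at the
extreme-score abilities −3.71 and 4.18) converts to an intuitive 0–100
disability metric. Population cut-offs at 4.3 / 22.6 / 40.8 (mean ± 1 SD of
the metric) disaggregate respondents into *No / Mild / Moderate / Severe*
disability.

The package provides, for psychometricians and survey analysts:

- **Calibration** — `pcm_fit()`: conditional maximum likelihood (CML)
  estimation of item thresholds through log-space elementary symmetric
  functions, free of any assumption on the ability distribution, with
  threshold standard errors and convergence diagnostics. Methods:
  `print`, `summary`, `coef`, `vcov`, `logLik`, `residuals`, `predict`,
  `simulate`, `plot` (person–item map).
- **Scoring** — the published FDD11 calibration ships as a versioned JSON
  artifact (`fdd11_calibration()`); `score_persons()`, `pcm_score_table()`,
  the Table-style category recodes (`fdd11_recode_map()`), the emotion
  testlet (`emotion_testlet()`), the ≤2-missing retention rule
  (`filter_missingness()`), the 0–100 transform and level assignment.
- **Diagnostics** — standardized residuals, item/person infit mean squares,
  residual-correlation local dependence flags (0.2-above-mean rule),
  threshold-ordering checks with iterative collapse proposals, targeting
  summaries and the person separation index (PSI).
- **Dimensionality** — polychoric correlations, Horn's parallel analysis and
  an exploratory bi-factor (Schmid–Leiman) general-vs-specific loading
  comparison.
- **DIF** — per-item two-way ANOVA of residuals on group × ability class
  interval (group main effect, df = groups − 1).
- **Synthetic data** — `fdd11_simulate()`: model-true datasets with known
  truth, right-skewed ability mixtures, country-like groups with injected
  DIF, MCAR missingness and a twelve-question variant with a locally
  dependent emotion item pair.
- **Pipeline commands** — `fdd11_simulate_file()`, `fdd11_calibrate_file()`,
  `fdd11_score_file()` (CSV/JSON/YAML round-tripping), wrapped by the
  command-line script `inst/cli/fdd11.R`.

## Worked example

```r
library(fdd11)

cal <- fdd11_calibration()            # published FDD11 calibration
st  <- pcm_score_table(cal)           # full sum-score conversion table
st[st$sum_score %in% c(0, 2, 8, 9, 15, 30), ]
#>    sum_score  theta    se extreme score_0_100    level
#>            0 -3.710    NA    TRUE         0.0       No
#>            2 -2.181 0.731   FALSE        19.4     Mild
#>            8 -0.601 0.397   FALSE        39.4 Moderate
#>            9 -0.450 0.380   FALSE        41.3   Severe
#>           15  0.303 0.341   FALSE        50.9   Severe
#>           30  4.180    NA    TRUE       100.0   Severe
```

Each row maps a recoded sum score to its ML ability `theta` (logits) with
standard error, the 0–100 disability score, and the severity level implied
by the published cut-offs: a respondent scoring 9 or more of the 30
attainable points is classified with severe disability. Scoring survey data
and refitting the model on synthetic data:

```r
sim    <- fdd11_simulate(5, seed = 2026)       # synthetic respondents
scores <- score_persons(sim$responses, cal)
scores[, c("person_id", "sum_score", "theta", "score_0_100", "disability_level")]
#>  person_id sum_score theta score_0_100 disability_level
#>    P000001         1 -2.91        10.1             Mild
#>    P000002         4 -1.42        29.0         Moderate
#>    P000003         1 -2.91        10.1             Mild
#>    P000004         4 -1.42        29.0         Moderate
#>    P000005         0 -3.71         0.0               No

fit <- pcm_fit(fdd11_simulate(2000, seed = 7)$responses)
#> 11 items, 2000 persons (1651 informative, 349 extreme/uninformative dropped)
#> conditional logLik -11014.69; converged after 39 iterations
person_separation_index(fit$abilities)
#> [1] 0.743
```

From the shell:

```sh
Rscript inst/cli/fdd11.R simulate  --config config.yaml --output data.csv --truth truth.json
Rscript inst/cli/fdd11.R calibrate --input data.csv --output calibration.json --auto-collapse
Rscript inst/cli/fdd11.R score     --input survey.csv --output scores.csv --exclusions excluded.csv
```

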