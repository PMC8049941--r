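# apiat — adaptive Pitch Imagery Arrow Task toolkit

`apiat` builds and runs an item-response-theory based test of auditory
mental imagery: the adaptive Pitch Imagery Arrow Task (aPIAT). In each
trial a major-key context and a start note are established, arrows cue
stepwise pitch moves — first sounded, then silent (to be *imagined*) —
and the respondent judges whether a final probe tone matches the note
they were imagining. The package is for psychometricians and music
cognition researchers who need calibrated pitch-imagery items, a
computerized adaptive test over them, or a simulation harness for either.

The package covers the full measurement chain, with no human data
required at any step:

* **Automatic item generation** — bounded random arrow walks with
  matching or near-miss probes over a factorial design (difficulty level
  1–6 = number of imagined tones, 3–5 heard arrows, tonic/dominant start,
  correct/incorrect probe, five keys), including the 3000-item
  calibration design and its 600-item level-6 extension.
* **Explanatory 4PL response model** — the response probability is
  `P(θ) = c + (d − c)·logistic(a(θ − b))` with guessing floor `c = 0.3`,
  inattention ceiling `d = 0.95`, constant discrimination `a = 1`, and
  item difficulty `b = −η/s` predicted from item features through the
  published joint-model coefficients
  (`η = β₀ + Σ βⱼ·xⱼ`, with separate coefficient branches for
  correct- and incorrect-probe trials), so freshly generated items are
  calibrated without per-item estimation.
* **Calibration pipeline** — refit those coefficients from long-format
  `(participant, item, correct)` data: asymptote-profiled logistic
  mixed-effects fitting (Gauss–Hermite marginal likelihood),
  random-forest predictor screening, exhaustive BIC subset search,
  cross-validated accuracy.
* **Adaptive engine** — Bayes modal (MAP) interim ability estimates,
  Urry's-rule item selection (nearest difficulty), 25-item sessions,
  Warm's weighted-likelihood final score on a −4…+4 scale with its IRT
  standard error.
* **Respondent simulator** — Normal ability cohorts answering under the
  4PL model; recovery and reliability experiments as a function of test
  length.

## Worked example

```r
library(apiat)

bank  <- generate_bank(seed = 1)                      # 3000-item calibration design
ext   <- generate_bank(levels = 6, seed = 2)          # 600 level-6 items
full  <- combine_banks(bank, ext)
cal   <- calibrate_bank(full, piat_model_params(), bank_features(full))
cal
#> PIAT item bank: 3600 items
#>   levels: 1 (n=600), 2 (n=600), 3 (n=600), 4 (n=600), 5 (n=600), 6 (n=600)

summary(cal$items$difficulty)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#> -0.1609  0.4585  0.9368  1.0500  1.5390  3.4717
```

Item difficulties are in ability-SD units: the median item suits a
respondent about one SD above the mean, and level-6 incorrect-probe
items reach `b ≈ 3.5`. Now run an adaptive session for a simulated
respondent of true ability θ = 0.7:

```r
session <- run_session(cal, simulated_respondent(0.7, cal$params),
                       n_items = 25, seed = 42)
session
#> aPIAT session: 25 items (urry selection)
#>   final WLE theta = 0.0076 (se = 0.5927)

tail(session$records[, c("position", "difficulty", "response",
                         "interim_theta", "interim_se")], 3)
#>    position  difficulty response interim_theta interim_se
#> 23       23 -0.16094500        1   -0.12300810  0.5292747
#> 24       24 -0.13474333        1   -0.05436884  0.5189448
#> 25       25 -0.05053667        1    0.01231972  0.5097784
```

Each record shows the selected item's difficulty, the 0/1 response, and
the updated interim MAP estimate with its shrinking standard error; the
final line of the session is the weighted-likelihood score. A single
25-item session carries a standard error around 0.5–0.7 ability units —
one unlucky session can sit an SD from truth, which is why reliability
is assessed over a cohort:

```r
recovery_experiment(cal, n_respondents = 50, lengths = c(10L, 25L),
                    retest = TRUE, seed = 7)
#>   length mean_se  rmse truth_cor retest_cor
#> 1     10   1.053 0.841     0.634      0.539
#> 2     25   0.669 0.556     0.851      0.768
```

Longer tests shrink the mean standard error and raise both the
truth correlation and the simulated test–retest correlation.

A thin command-line surface over the same functions lives at
`inst/cli/apiat.R` (subcommands `generate-bank`, `features`,
`calibrate-bank`, `calibrate`, `simulate`, `cat-session`).

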