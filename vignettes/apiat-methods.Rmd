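---
title: "Methods: the adaptive pitch-imagery test from item generation to adaptive scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the adaptive pitch-imagery test from item generation to adaptive scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apiat)
```

## The task and what the package models

The Pitch Imagery Arrow Task measures the ability to hear pitch "in the
mind". A trial establishes a major-key tonal context (an ascending
scale), sounds a start note (the tonic or the dominant of the key), then
shows a run of arrows. The first arrows are *heard*: each is accompanied
by a tone one diatonic step up or down from the previous one. The
remaining arrows are *silent*: the respondent must imagine the
corresponding stepwise moves. The final silent arrow carries the word
"hold"; one imagined note must be maintained until a probe tone sounds,
and the respondent judges whether the probe matches the held image.

`apiat` implements the whole measurement chain around that trial:

1. **Item generation** (`generate_walk()`, `assign_probe()`,
   `generate_bank()`): random arrow walks within a bounded pitch range,
   with matching or near-miss probes, over a factorial design of
   difficulty level (number of silent arrows, 1-6), heard-arrow count
   (3-5), start degree, probe accuracy, and key (C, C#, D, Eb, E major).
2. **Feature extraction** (`bank_features()`): the cognitive-model
   covariates that predict how hard an item is.
3. **An explanatory 4PL response model** (`piat_model_params()`,
   `easiness()`, `calibrate_bank()`): item difficulty is not estimated
   per item but predicted from the features through published regression
   coefficients, so newly generated items are calibrated for free.
4. **A calibration pipeline** (`fit_model()`, `optimize_asymptotes()`,
   `screen_predictors()`, `subset_search()`, `cv_accuracy()`) to re-estimate
   those coefficients from long-format response data.
5. **An adaptive engine** (`map_estimate()`, `select_next()`,
   `wle_estimate()`, `run_session()`): a fixed-length computerized
   adaptive test.
6. **A respondent simulator** (`simulate_cohort()`,
   `simulate_responses()`, `recovery_experiment()`) so that every stage
   can be validated without human data.

## Item generation: coordinates, bounds and tight cells

Offsets are integers in *scale steps* relative to the start note (0 =
start note); pitches are integer semitones (MIDI convention, middle C =
60). This makes the range bound and all probe arithmetic exact. Walks
are sampled uniformly, by rejection, among all sign sequences whose
cumulative positions stay within ±4 steps of the start note. The probe
can never be the start note; an incorrect probe is one or two steps from
the true imagined final note, and we also keep incorrect probes inside
the ±4 range (the range constraint is stated for the notes of the trial,
and the probe is one of them; `probe_in_range = FALSE` flips this
reading). Correct-probe items additionally need a walk with non-zero net
displacement, since probe = final note and the probe may not be the
start note.

Two register/structure choices are configuration rather than fact, since
the source design does not pin them down: the octave placement of start
notes (default: tonics in the octave at middle C, `piat_keys(register=)`)
and whether the "hold" arrow counts as one of the `level` silent steps
(we count it — the final silent arrow carries the hold cue).

Some design cells are genuinely tight: a level-1/3-heard/correct-probe
cell has exactly 10 admissible (walk, probe) pairs, which is precisely
the number of variations the calibration design asks for. The generator
therefore samples with rejection until it has the requested number of
*distinct* variations, and raises an explicit error naming the cell after
10,000 failed tries rather than silently duplicating items.

The parity property falls out of the coordinates: for a correct probe,
probe − last-heard-note equals the sum of the silent steps, so its parity
always matches the number of imagined tones. The test suite checks this
across the full 3600-item bank.

## The features

For each item we compute:

* `level` — the number of imagined tones; the dominant difficulty driver.
* `heard_range` — the number of unique tones sounded during set-up,
  start note included. (An alternative reading of "range" as the
  min-to-max span exists; the unique-tone count is the definition we
  implement, and for stepwise walks the two are identical anyway, since
  every visited offset between the extremes is sounded.)
* `probability_probe_last_heard` — the empirical relative frequency,
  over a reference bank, of the item's *signed* distance between probe
  and last heard note. The signed (not absolute) distance is used
  because both parity and direction carry information about plausible
  probes; `distance_table(type = "absolute")` is available. Unseen
  distances score 0: the feature is an empirical frequency, not a
  smoothed probability.
* `probe_trueim_absdiff` — |probe − true imagined note|: 0 for correct
  probes, 1 or 2 for incorrect ones (two-step mismatches are easier to
  reject).
* `probability_probe` — empirical frequency of the probe offset among
  bank items with the same total arrow count.
* `probe_is_startnote` — always `FALSE` for generated banks (the
  generator forbids it); retained because it was an important predictor
  in exploratory data where start-note probes were allowed.

By default the distance table for a combined bank (calibration + level-6
extension) is computed over the full combined bank. The original
3000-item table predates the extension; scoring extension items against
a table that contains them is the self-consistent choice, and
`bank_features(dist_table=)` lets you score against any reference table.

## The response model

The response model is a four-parameter logistic with constant
discrimination, guessing and inattention:

$$P(\text{correct} \mid \theta, b) = c + (d - c)\,
  \mathrm{logistic}\big(a(\theta - b)\big)$$

with defaults $c = 0.3$, $d = 0.95$ (the only published asymptote
values; the task floor is 0.3 rather than 0.5 because respondents show a
"match" bias, and the ceiling below 1 absorbs attention lapses),
$a = 1$ (the "modified Rasch" reading: a constant, unit discrimination in
the natural logistic metric, not the historical 1.7 scaling), and item
difficulty predicted from features:

$$b = -\eta / s, \qquad
  \eta = \beta_0 + \sum_j \beta_j^{(\text{branch})} x_j$$

where the branch is the correct-probe or incorrect-probe coefficient set
depending on the item's probe accuracy, and $s$ is the ability-SD scale
(1 unit of difficulty = $s$ units of the linear predictor). The default
coefficients are the published joint-model values
(`piat_joint_coefficients()`); the default scale is $s = 1$ until a
calibration sample supplies an estimate. There is no correct-branch
coefficient for `probe_trueim_absdiff` because the feature is
identically zero on correct-probe trials.

## Calibration fitting

`fit_model()` maximizes the marginal likelihood of
$P = c + (d - c)\,\mathrm{logistic}(X\beta + u)$ with a
$\mathrm{Normal}(0, \sigma^2)$ random intercept per participant,
integrated by 21-node Gauss-Hermite quadrature and optimized by BFGS on
$(\beta, \log\sigma)$. Standard errors come from the numerical Hessian
at the optimum. The accuracy of the machinery is pinned by an exact
special case: with $c = 0$, $d = 1$ and $\sigma$ forced to zero the fit
must reproduce ordinary logistic regression to four decimals, which the
test suite enforces against `stats::glm`.

Asymptotes are profiled on a grid (`optimize_asymptotes()`, default $c
\in \{0, .05, \dots, .5\}$, $d \in \{.8, .85, \dots, 1\}$, with $d = 1$
nudged to 0.999 to keep error log-likelihoods finite) rather than
jointly optimized: the profile surface in $(c, d)$ is flat and bounded,
where a joint gradient ascent is fragile. `subset_search()` enumerates
feature subsets exhaustively and ranks them by BIC
($-2\log L + k\log n$); `screen_predictors()` reduces a large candidate
list first via random-forest permutation importance (one seeded
implementation stands in for the three importance variants of the
original workflow, which agreed with each other). `cv_accuracy()`
reports stratified k-fold accuracy at the 0.5 threshold, with or without
using fitted participant effects at prediction time — the two variants
bracket how much of the predictability is item-driven versus
person-driven.

## The adaptive engine

* **Interim estimate:** Bayes modal (MAP) under a standard Normal prior.
  The prior is a convention choice — the difficulty scale is defined in
  ability-SD units, so a unit-SD prior is the matching default — and is
  configurable. With no data the MAP is the prior mode 0, so the first
  item is the unused item with difficulty nearest 0.
* **Selection:** Urry's rule — the unused item minimizing
  $|b - \hat\theta|$, exact ties broken uniformly at random. No exposure
  control or content balancing is imposed.
* **Length:** 25 scored items by default.
* **Final score:** Warm's weighted likelihood estimate, the root of the
  bias-corrected score equation
  $S(\theta) + J(\theta)/(2I(\theta)) = 0$ with
  $J = \sum_i P_i' P_i'' / (P_i(1-P_i))$, located by a sign-change scan
  refined with `uniroot`. For the plain logistic case ($c=0$, $d=1$)
  this equation is exactly the derivative of
  $\log\!\big(L(\theta)\sqrt{I(\theta)}\big)$ — the familiar
  "information-penalized likelihood" characterization — but with
  asymptotes the two differ, and we solve the corrected score equation
  itself. When the corrected score has no sign change in $[-4, 4]$ (an
  extreme response pattern), the estimate is clamped to the boundary and
  flagged. Scores are therefore always in $[-4, 4]$, the reporting scale
  of the test. The standard error is $1/\sqrt{I(\hat\theta)}$ from
  expected information (an observed-information variant would differ
  only in the third decimal for typical 25-item sessions).

Numerical choices worth knowing: MAP maximization uses a 161-point scan
of $[-4,4]$ followed by golden-section refinement, so it is
deterministic and immune to local plateaus; the WLE scan uses 401
points; if the corrected score crosses zero more than once the root with
the highest likelihood is taken.

## What the simulator does and does not emulate

Simulated respondents are stationary 4PL responders: ability constant
across the session, responses independent Bernoulli draws given
difficulty. Real respondents warm up, fatigue, and drift; observed
retest correlations in humans are depressed by day-to-day variation that
the simulator does not contain. Passing recovery and reliability tests
therefore demonstrates that the *machinery* is correct and internally
consistent — that the engine extracts the information the model says is
there — not that human data will reach the same reliability. In
particular, simulated test-retest correlations are optimistic upper
bounds for human ones.

Problem sizes used by the validation suite, chosen to mirror the source
study designs: calibration recovery uses 200 respondents by 30 items (6
per level, quasi-random without replacement, the calibration session
design) over 20 seeded replicates; reliability curves use 200
respondents at test lengths 5-25 on the full 3600-item bank; asymptote
convergence checks use 10,000 Bernoulli draws at extreme abilities.
One recovery caveat is inherent to the generating values themselves:
the incorrect-branch probe-probability coefficient is small (0.228)
relative to its sampling error at this design size (the published
standard error is 0.768), so its *per-replicate* sign is close to a coin
flip no matter how correct the fitter is; sign recovery is accordingly
asserted on the mean coefficient vector across replicates, while the
3-standard-error coverage holds per replicate.

## Known limitations

* The package generates symbolic item descriptions and timed event
  schedules (`trial_schedule()`); it does not render audio or video
  stimuli, deliver tests to humans, or implement the legacy staircase
  design.
* The published asymptotes for the joint calibration model and the exact
  ability-SD used for difficulty scaling were not printed; `c = 0.3`,
  `d = 0.95`, `s = 1` are defaults, all configuration-exposed.
* Difficulties from the default coefficients span roughly $-0.2$ to
  $+3.5$: the bank is information-rich around and above average ability
  and thinner far below it, so standard errors for very weak respondents
  stay larger — visible in simulated reliability curves.
* `probability_probe_last_heard` is bank-relative; items scored against
  different reference banks get different feature values (and hence
  difficulties). Persist and reuse the table of the bank you calibrated
  against.
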