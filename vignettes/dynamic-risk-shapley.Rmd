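---
title: "Dynamic short-term cancer risk models and the Shapley decomposition of discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic short-term cancer risk models and the Shapley decomposition of discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Electronic primary-care records are longitudinal: symptoms, test results
and diagnoses accrue over time, and a person's short-term cancer risk
changes as they do. `landshap` implements a pipeline for *dynamic*
two-year colorectal-cancer (CRC) risk modelling on such records, and for a
question that a single model fit cannot answer: **how much does each kind
of information contribute to the model's discrimination?** Candidate
predictors arrive in natural groups — core demographics, a polygenic score
(PGS), presenting symptoms, medical history, common blood tests, lifestyle
questionnaire fields — and the incremental value of any one group depends
on which others are already in the model. The package therefore evaluates
Harrell's C-index for *every* subset of the six predictor sets and
averages each set's marginal contribution over all join orders: its
Shapley value, an inclusion-order-agnostic attribution that satisfies
efficiency, symmetry, dummy and linearity.

# The super-landmark design

Risk is re-assessed at landmark ages 40, 41, ..., 74. A person enters the
landmark-age dataset on the *index date*, the first day of the month in
which they reach that age, provided they are alive, have at least 6 months
(183 days) of continuous record coverage within the previous two years,
and have no prior cancer diagnosis other than non-melanoma skin cancer
(NMSC). Coverage is "continuous" across registration gaps of up to 90 days
(a gap of exactly 90 days does not break a run — the rule is *no gaps
strictly longer than 90 days*); where several runs intersect the two-year
window, the most recent (latest-ending) run must satisfy the 183-day
minimum. Predictors are derived from records strictly before the index
date — the lookback window is half-open, `[index - 730d, index)`, so an
event on the index date itself is future, not history. The outcome is the
first CRC diagnosis within 730 days; follow-up is censored at the first of
any other incident cancer (NMSC ignored), death, two years after the end
of primary-care data availability, or 730 days. All landmark-age datasets
are stacked into one *super-landmark dataset*, so a person contributes up
to 35 rows; models must treat `person_id` as a cluster.

Boundary conventions the package fixes deliberately:

* "6 months" is 183 days — an unambiguous day count rather than a
  calendar rule.
* A 29 February birthday anniversaries on 1 March in non-leap years.
* A CRC diagnosis *on* the index date is an event at time 1 day, not a
  prior cancer; an eligible person's follow-up time is always positive.
* Ties among censoring candidates resolve in the order CRC, other cancer,
  death, record-end + 2y, administrative 730 days.
* Whether the qualifying coverage run must extend to the index date
  itself is switchable (`require_coverage_to_index`); the default only
  requires 183 covered days inside the window.

# Predictors

A declarative codebook (`default_codebook()`) maps raw streams to 46 named
predictors in six sets: core (8: age at index, sex, birth year, BMI,
ethnicity, smoking status, Townsend deprivation, age at baseline
assessment — the eighth member is a design choice, since baseline age and
birth year are distinct pieces of calendar information in a dynamic
cohort), PGS (1, standardized per SD), symptoms (16: eleven named
gastrointestinal presentations plus five configurable placeholders),
medical history (12), blood tests (4) and lifestyle (5). Event-sourced
predictors are binary "any matching code in the lookback window";
colonoscopy uses a 10-year window and chronic conditions (diabetes, IBD,
gallbladder disease) use the full prior history. Blood tests use a dual
encoding per test family — *measured* (any test in the window) and
*abnormal* (any abnormal result) — so `abnormal <= measured` always.
Missing smoking status and ethnicity become an explicit `missing`
category; any other missing baseline value drops the row (complete case).

The *symptomatic subcohort* is defined from the data: AIC-based
bidirectional stepwise selection of a Cox model over the 16 symptom
indicators picks the qualifying symptoms, and the subcohort keeps rows
with at least one of them in the two years before the landmark age. A
sensitivity definition (`any_except_fatigue`) uses every symptom except
fatigue, which is not specific enough to define symptomatic status.

# Models and evaluation

`fit_cox()` fits the Cox proportional-hazards partial likelihood with
Efron tie handling — month-start index dates make event-time ties heavy —
and the cluster-robust sandwich covariance over persons (`survival`
provides both). AIC is `-2 log PL + 2p` with `p` the number of estimated
coefficients. Convergence follows `coxph` with a partial-likelihood
tolerance of 1e-9 and at most 100 iterations. A singular design is an
error; a monotone likelihood (e.g. a rare category with no events) is
flagged as non-convergence rather than failing, and stepwise selection
simply discards such moves when they do not lower AIC.

`stepwise_aic()` starts from the full candidate model (start point is
switchable) and repeatedly applies the single add-or-drop move that most
decreases AIC, breaking ties by candidate order, so selection is
deterministic given the data and the candidate ordering. No terms are
protected by default; a `protect` argument exists.

Evaluation uses a person-level bootstrap: training persons are drawn with
replacement, and the out-of-bag persons — in expectation a fraction
`exp(-1)` of about 36.8% — form the test set, so train and test are
ID-disjoint by construction. Per replicate, a Cox model for every one of
the 2^6 = 64 subsets of predictor sets is fitted on the training rows and
scored by Harrell's C-index on the out-of-bag rows; the empty subset is
assigned 0.5 (chance). The C-index here counts a pair as comparable when
the strictly shorter follow-up ends in an event (tied times are not
comparable) and scores tied risk scores 0.5. Stepwise selection is run
*once* on the full dataset and frozen; each subset uses the selected
terms intersected with its own predictors. Re-selecting inside all
64 x 200 training fits (`selection = "per_fit"`) is available but
disproportionate, and the reference analysis reports a single selected
model. A subset left with no terms after intersection scores 0.5 — a
model with no information discriminates at chance. Terms constant within
a training fold are dropped from that fit (a constant column cannot
contribute to discrimination), and factor levels unseen in a fold are
scored at the fold's reference level rather than discarding the
replicate.

Calibration at two years compares mean predicted absolute risk —
`1 - exp(-H0(730) * exp(lp))` with the Breslow baseline centred on
training means — against the Kaplan-Meier complement within deciles of
predicted risk, with percentile intervals over the bootstrap replicates.
When predicted risks are heavily tied, coinciding quantile breaks merge
adjacent groups with a warning.

# The Shapley decomposition

Each bootstrap replicate's 64 C-indices form a value function `v` over the
six sets with `v(empty) = 0.5`. The Shapley value of set `j` is

$$\phi_j = \sum_{S \subseteq N \setminus \{j\}}
  \frac{|S|!\,(|N|-|S|-1)!}{|N|!}\,\bigl[v(S \cup \{j\}) - v(S)\bigr],$$

computed exactly (no sampling at `|N| = 6`), with an independent
oracle that averages marginal contributions over all 720 orderings
(`shapley_permutation_oracle()`); the two agree to 1e-12. Percentage
contributions divide by the full model's gain over chance,
`100 * phi_j / (v(full) - 0.5)` — normalizing by the C-index *above 0.5*
rather than its absolute value, since 0.5 is what a model with no
information achieves; percentages can be negative (a set can hurt
out-of-sample discrimination) and sum to 100.

Two aggregation decisions matter for the intervals. Shapley values and
percentages are computed **per replicate** and then summarized (mean point
estimate, percentile 2.5/97.5 intervals); decomposing the replicate-mean
grid instead would give no valid uncertainty statement. Replicates with
any failed subset fit are dropped whole, so every retained replicate
satisfies efficiency, `sum(phi) = v(full) - 0.5`, to 1e-12 — this is
asserted, not assumed. Fewer than 10 usable replicates is an error.

# The synthetic cohort generator

Real linked primary-care/registry data cannot be redistributed, so the
package ships a generator (`simulate_cohort()`) that emulates the record
structure with known ground truth, making parameter recovery and
discrimination attribution testable. Each person draws from an
independent RNG stream derived from `(seed, person_id)`, so cohorts are
bit-identical under a fixed seed and reproducible under parallel
generation.

The simulated world: births 1936-1970; primary-care registration at a
uniform age 25-45; records end in 2018 with registry linkage to 2020;
Poisson registration gaps (0.08/person-year, exponential mean 120 days,
so some gaps exceed the 90-day continuity tolerance). Recurrent coded
events and blood tests are Poisson processes within yearly age bands with
a linear age slope (0.02/year) on the log rate, so older people present
more — base rates are order-of-magnitude choices calibrated so two-year
lookback prevalences land near commonly reported primary-care frequencies
(constipation about 17%, recent blood test about 85%). Baseline
questionnaire fields carry small missingness rates (smoking and ethnicity
about 0.3%, alcohol 2%, education 1%) to exercise the missing-data
policy.

The CRC outcome is a piecewise-constant proportional-hazards process: the
linear predictor is re-evaluated at every change of the person's simulated
state (state onsets, lookback windows opening and closing, birthdays for
the age term), with default log hazard ratios log 1.4 per SD of PGS,
log 3.9 for iron-deficiency anaemia, log 2.7 for rectal bleeding and
log 1.06 per year of age (centred at 60). The baseline hazard, 0.004
events/person-year at the covariate reference, is deliberately above
population CRC incidence so cohorts of simulatable size carry enough
events for stable model fits; all rates are configuration, not hard-coded
truth. Competing other-cancer, NMSC and death processes are independent
age-sloped Poisson processes resolved by earliest date, with records
truncated at death.

The two hazard-bearing record streams are modelled as **persistent
disease states**: iron-deficiency anaemia and a bleeding condition switch
on (onset 0.006 and 0.0028/person-year at 60) and then generate frequent
coded records — extra iron tests that are abnormal with probability 0.9,
and rectal-bleed codes — at 2/person-year while active. This makes the
2-year-lookback indicator an accurate proxy for the state that actually
drives the hazard, so the frozen-at-index landmark model is close to
well-specified and recovers the generating coefficients; with purely
episodic events whose effect expires mid-follow-up, landmarking would
attenuate them by construction. Residual misclassification (an active
state with no record in the window, onset during follow-up, background
abnormal noise of 0.002 per test) biases the iron coefficient down by a
few percent — visible as a slight systematic shortfall at very large n,
and well inside the 3-standard-error recovery band at n = 20 000.
Blood-test abnormality is simulated directly as a flag; real analyte
thresholds live in laboratory-specific reference ranges the generator
does not model.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: clinical coding vocabularies and code-list
curation; correlated predictors (comorbidity clusters, socioeconomic
gradients in testing); non-proportional hazards; informative registration
or testing (sicker people tested more, beyond the two disease states);
secular trends. Results on synthetic cohorts validate the *machinery*,
not the epidemiology.

# Validation experiments and their problem sizes

The test suite exercises the pipeline at sizes chosen to keep Monte-Carlo
error well below the tolerances being asserted:

* Exact algebra (Shapley axioms, estimator equivalence on 1000 random
  games, a hand-enumerable 3-player game, C-index vs exhaustive pair
  enumeration on 200 random censored datasets with ties) at tolerance
  1e-12.
* Parameter recovery on 20 000 persons at landmark ages 58-66: each
  fitted log HR within 3 robust standard errors of its generating value.
* Coverage of the cluster-robust 95% interval for a null coefficient
  (sex) over 200 replicates of 600-person cohorts: accepted between 90%
  and 99%.
* A dummy-set experiment (5000 persons, B = 50): with PGS (HR 2.5/SD,
  chosen as a decisively strong single signal) the only true effect, the
  PGS set's phi interval excludes 0 and all five noise sets' intervals
  cover it. The noise "core" set uses Townsend, sex and BMI rather than
  age: record-end censoring is calendar-driven, so an age-linked score is
  weakly informative about follow-up time even with no hazard effect —
  Harrell's C is not invariant to covariate-dependent censoring, a real
  property of the estimand, not a bug.
* Calibration on held-out persons of the large cohort: decile
  observed-vs-predicted slope within 1 +/- 0.15; a cohort generated with
  twice the baseline hazard sits above the model's predictions in every
  decile.
* Bit-identical end-to-end reruns under a fixed seed.

The stepwise null-selection property uses the known behaviour of AIC:
under the null each candidate survives with probability about
P(chi-squared_1 > 2) = 0.157, so of 16 noise symptoms two to three are
expected by chance — "near-empty", not empty.

# Known limitations

* Harrell's C with covariate-dependent censoring rewards
  censoring-informative scores slightly; the package reports it because
  it is the field's standard summary, but comparisons across censoring
  regimes should be made with care.
* The frozen-selection grid conditions on one selected term list;
  selection uncertainty is not propagated into the intervals (per-fit
  re-selection is available at 64x the cost).
* Percentile intervals from 200 replicates have their own Monte-Carlo
  noise of a few percentage points on percentage contributions.
* The generator's independence assumptions (predictors, competing risks)
  are stronger than anything true of real records; see above.
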