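# landshap

Super-landmark survival models with a Shapley decomposition of
discrimination, for dynamic short-term colorectal-cancer (CRC) risk
prediction from longitudinal primary-care-style records.

## Who this is for

Biostatisticians and epidemiologists who want to (a) build two-year
dynamic risk models on stacked landmark-age datasets derived from coded
event streams, and (b) attribute the model's discrimination to *groups*
of predictors — core demographics, a polygenic score (PGS), presenting
symptoms, medical history, common blood tests, lifestyle — in a way that
does not depend on the order the groups are added to the model. Because
real linked primary-care/registry data cannot be redistributed, the
package includes a synthetic longitudinal cohort generator with known
ground-truth hazard parameters, so every step of the pipeline is testable
against truth.

## The method

**Super-landmark dataset.** At each landmark age 40, 41, ..., 74 a person
enters on the first of the month in which they reach that age (the *index
date*) if they are alive, have ≥ 6 months (183 days) of continuous
primary-care coverage (gaps ≤ 90 days tolerated) in the previous two
years, and have no prior cancer except non-melanoma skin cancer.
Predictors are derived from records in the half-open window
`[index − 730d, index)`; the outcome is the first CRC diagnosis within
730 days, censored at any other incident cancer, death, two years after
the records end, or administratively at 730 days. All ages are stacked;
people repeat across rows.

**Model.** Cox proportional hazards (Efron ties) on days since index,
with AIC-based bidirectional stepwise selection and cluster-robust
(sandwich) standard errors over persons:

&nbsp;&nbsp;&nbsp;&nbsp;λ(t | x) = λ₀(t) · exp(βᵀx),&nbsp;&nbsp;
AIC = −2 log PL + 2p.

**Evaluation.** 200 person-level bootstrap replicates; training persons
drawn with replacement, out-of-bag persons (≈ e⁻¹ ≈ 36.8%) form the
ID-disjoint test set. Per replicate, Harrell's C-index is computed for
**all 2⁶ = 64 combinations** of the predictor sets.

**Shapley decomposition.** Each replicate's 64 C-indices form a value
function v over the six sets with v(∅) = 0.5 (chance). Set *j*'s Shapley
value is

&nbsp;&nbsp;&nbsp;&nbsp;φⱼ = Σ_{S ⊆ N∖{j}} |S|!(n−|S|−1)!/n! · [v(S∪{j}) − v(S)],

verified against exhaustive enumeration of all 720 join orders.
Percentage contributions are 100 · φⱼ / (v(full) − 0.5), computed per
replicate (they can be negative; they sum to 100), with percentile
confidence intervals over replicates.

## Worked example

The `analysis/` directory is a numbered workflow over the package; running
it end to end reproduces every table under `results/`:

```sh
Rscript analysis/01_simulate.R        # synthetic cohort -> results/cohort/
Rscript analysis/02_build_landmark.R  # stacked dataset  -> super_landmark.tsv
Rscript analysis/03_fit_models.R      # selection + Cox  -> hr_table.tsv
Rscript analysis/04_bootstrap_grid.R  # 200 x 64 C-index -> combination_grid.tsv
Rscript analysis/05_shapley.R         # decomposition    -> shapley.tsv
Rscript analysis/06_calibration.R     # risk deciles     -> calibration.tsv
```

Step 1 simulates 4000 people (485 registry CRC events over ~25 years of
records); step 2 stacks landmark ages 60–64 into 8748 rows from 2035
eligible persons with 92 two-year CRC events. Step 3 selects 16 of 46
candidate predictors and prints the cluster-robust hazard ratios; the
strongest true effects are recovered in the right range on only 92
events:

```
term           hr    hr_lower hr_upper p
pgs            1.45  1.11     1.89     6.6e-03
iron_abnormal  3.02  1.56     5.85     1.1e-03
rectal_bleed   2.22  0.94     5.24     7.0e-02
```

(generating values: 1.4 per SD, 3.9, 2.7). Step 5 prints the
decomposition:

```
Full-model C-index: 0.594 (0.455 to 0.693), 200 replicates
             set     phi            phi_ci    pct
             pgs  0.0347 (-0.0277, 0.0845)  43.6%
     blood_tests  0.0388 (-0.0104, 0.0789)  48.0%
        symptoms  0.0159 (-0.0492, 0.0636)  15.1%
 medical_history  0.0155 (-0.0486, 0.0633)  15.9%
            core -0.0082 (-0.1239, 0.0581)  -9.7%
       lifestyle -0.0027 (-0.0837, 0.0752) -12.9%
```

The two set groups that actually carry signal in the generator — the PGS
and the blood tests (iron-deficiency anaemia) — receive over 90% of the
attributed discrimination between them, while the intervals on the noise
sets straddle zero. At this deliberately modest cohort size the intervals
are wide, and step 6's calibration slope (0.33) shows the expected
overfitting of aggressive stepwise selection on ~90 events: risk spread
is exaggerated relative to observed risk. At n = 20 000 with the
generating model the slope is ≈ 1 (see below).

## Package layout

- `R/` — simulation (`sim_config`, `simulate_cohort`), landmark
  construction (`coverage_runs`, `is_eligible`, `outcome_at`,
  `build_super_landmark`), predictor derivation (`default_codebook`,
  `derive_vector`, `apply_missing_policy`, `symptomatic_subcohort`),
  modelling (`fit_cox`, `stepwise_aic`, `predict_risk`), evaluation
  (`harrells_c`, `bootstrap_partition`, `combination_grid`,
  `calibration_deciles`), Shapley (`shapley_values`,
  `shapley_permutation_oracle`, `decompose_grid`), and delimited-text IO.
- `analysis/` — the numbered workflow above.
- `vignettes/dynamic-risk-shapley.Rmd` — the methods vignette: model
  assumptions, parameter meanings and defaults, what the generator does
  and does not emulate, numerical conventions and design decisions.
- `tests/testthat/` — unit, property and end-to-end tests, including
  independent brute-force oracles for the C-index, the Cox partial
  likelihood and the Shapley values.
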