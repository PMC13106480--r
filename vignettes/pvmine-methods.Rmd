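---
title: "Methods: signal mining, onset hazards and risk factors in pvmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal mining, onset hazards and risk factors in pvmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvmine)
```

## Scope

`pvmine` implements an integrated pharmacovigilance workflow for
spontaneous adverse-event reports in the FAERS quarterly-extract dialect,
together with a clinical-cohort arm. The stages are: report cleaning
(deduplication, primary-suspect selection, linkage), four-algorithm
disproportionality signal detection at preferred-term (PT) and
system-organ-class (SOC) level, Weibull time-to-onset (TTO) hazard
characterization, and a two-stage risk-factor analysis (univariate screen,
LASSO selection, multivariable logistic regression) usable both on the
case/non-case report data and on a patient cohort. A seeded synthetic-data
generator supplies FAERS-like tables and cohorts with known planted
structure, so every stage can be validated end to end without access to
the source databases. MedDRA content is licensed and therefore never
shipped: the PT-to-SOC mapping is always a user (or generator) input.

## Report cleaning

FAERS cases accrue follow-up versions under one `CASEID`. For each case
the record with the most recent `FDA_DT` is retained, ties broken by the
highest `PRIMARYID`; a missing `FDA_DT` sorts as the earliest possible
date so that an undated record never displaces a dated one. The operation
is idempotent and independent of row order, and input size always equals
output size plus the removal count.

Subject-drug reports are those in which any configured name variant of
the subject drug carries role code `PS` (primary suspect). Matching is
case-insensitive exact matching against a user-extensible synonym list —
deliberately no fuzzy matching, so every inclusion is auditable. Reports
where the subject drug appears only as concomitant (`C`) or interacting
(`I`) are excluded.

Assembly joins demographics with reactions, drugs, therapy dates,
outcomes and indications. Reports with no reaction PT (and optionally no
outcome code) are excluded with a logged reason; drug or reaction rows
pointing at a missing demographic record are counted as orphans and
skipped, never silently dropped. TTO is the event date minus the earliest
therapy start date, in whole days; a negative interval is logically
inconsistent, so the interval is withheld and logged while the report
itself is retained for non-temporal analyses.

Characteristics tables use the published binning conventions (ages `<19`,
`19-44`, `44-59`, `>=60`; onsets `<2`, `2-5`, `5-7`, `7-14`, `14-28`,
`>=28` days; all bins half-open on the right). Percentages within a block
are taken over the **sum of the tabulated category counts of that
block**, not over the report count. Outcomes and indications are
multi-valued, so one report can contribute several entries to those
blocks and their denominators legitimately exceed the number of reports;
this is what makes published characteristic-table arithmetic exactly
reproducible. Published indication percentages could not be reconciled
with any row-sum denominator we tried; the package applies the same
block-sum rule there and documents the discrepancy rather than guessing.

## Disproportionality statistics

All four algorithms work on the report-level 2x2 for a term (a report
counts once per term regardless of repeated PT rows, and once per SOC
however many of its PTs map there; the comparator is the complement of
the subject-drug reports within the supplied dataset):

|            | event | not event |
|------------|-------|-----------|
| subject    | a     | b         |
| all others | c     | d         |

* **ROR** = ad/bc with the Woolf interval
  exp(log ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d)). Signal: lower bound
  strictly above 1 and at least `min_n` (default 3) cases.
* **PRR** = [a/(a+b)] / [c/(c+d)] paired with the chi-square statistic.
  Signal: PRR ≥ 2, chi-square ≥ 4 (both non-strict) and at least
  `min_n` cases. The chi-square is the **Yates-corrected** Pearson
  statistic by default: published two-group p-values in this literature
  reproduce only under the correction (the uncorrected variant is
  available as an option).
* **Information component (IC)** via the Bate-style moment approximation
  with the customary prior constants; the reported IC is the posterior
  expectation in bits and the signal criterion is literally
  E[IC] − 2·√Var[IC] > 0.
* **EBGM** under the DuMouchel two-gamma mixture prior for the
  reporting-rate ratio λ, with a ~ Poisson(λE) and E = (a+b)(a+c)/N. The
  five hyperparameters are fitted by maximizing the negative-binomial
  mixture marginal likelihood over all drug–event pairs with the
  derivative-free Nelder–Mead simplex from the canonical start
  (0.2, 0.1, 2, 4, 1/3), on a log/logit scale so the optimum is interior
  and the optimizer deterministic. EBGM is the posterior geometric mean
  exp(E[log λ]); EB05 is the posterior 5th percentile found by bisection
  on the mixture distribution function to 1e-6. The criterion
  "EBGM 95% CI lower bound > 2" is interpreted as EB05 > 2, the standard
  equating in this field.

Numerical choices: when any cell of the 2x2 is zero the Haldane–Anscombe
correction (0.5 added to **all four** cells) is applied for ROR, PRR and
chi-square, keeping the estimates finite; the Bayesian statistics carry
their own priors and use raw counts. An empty margin (no subject reports,
or no background reports) yields an undefined-statistic marker rather
than an error. Tests verify the conjugate EBGM posterior against
brute-force numerical integration of prior × Poisson likelihood, and the
chi-square against `stats::chisq.test` on random tables.

The composite "positive safety signal" is *any* algorithm positive. Note
what that implies under the null: the ROR criterion alone fires for
roughly 2.5% of null pairs, so a composite false-positive rate of a few
percent is expected and is what the null-simulation tests check (< 10% of
pairs at 10,000 reports).

## Time-to-onset model

Onset intervals are described by their median and quartiles
(order-statistic quantiles with linear interpolation, `quantile` type 7)
and the standard bins, then modelled parametrically: a two-parameter
Weibull fitted by maximum likelihood over log-shape and log-scale
(deterministic BFGS from a moment-style start, relative tolerance
1e-12). A shape below 1 means the event hazard falls with time on
therapy — early-risk concentration, the expected pattern for
immune-mediated toxicity; above 1 it rises. The shape confidence interval
is the Wald interval on log(shape) from the observed information,
back-transformed, so it is always positive; the hazard is classified
"decreasing" when the whole interval is below 1, "increasing" when above
1, "constant" otherwise.

Zero-day onsets (event on the start date) lie outside the positive
Weibull support and are shifted to 0.5 days before fitting (configurable)
— same-day events demonstrably occur and discarding them would bias the
shape upward. There is no censoring model: only observed onsets are fit,
as is conventional for spontaneous-report TTO analyses; right-censoring
is out of scope.

Known numerical limitation: the generator (like real report data) records
onsets in whole days. This discretization biases the fitted shape upward
by roughly 0.02 for shape ≈ 0.8 and scale ≈ 30 days — negligible against
the sampling error at a few hundred observations, but detectable at very
large n. Recovery tests on rounded data therefore run at n ≈ 1,000–2,000,
while pure parameter-recovery checks use continuous draws (10,000 draws
recover the generating shape well within 3 standard errors; the 95%
interval covers the generating shape in about 94–95% of 200 replicates at
n = 500).

## Risk-factor pipeline

Cases are defined strictly as reports containing the exact target PT;
reports with related cytopenia terms are non-cases, keeping the case
definition unambiguous. The screen tests each candidate against the
label: Yates chi-square on 2x2 tables, Pearson on larger ones, Fisher's
exact test whenever any expected cell is below 5, Wilcoxon rank-sum for
continuous variables; candidates pass at p < 0.10 (strict). The Fisher
trigger is a pure function of the expected-count matrix — this exact rule
is what reproduces published small-cell p-values (e.g. a two-group sex
comparison at p = 0.665 with a two-patient cell).

Selection uses penalized logistic regression (glmnet) with the penalty
chosen by 10-fold cross-validated binomial deviance and the
one-standard-error rule — the largest penalty within one standard error
of the minimum deviance, favouring the sparser model (`rule = "min"` is
available). Folds are stratified by outcome; stratification is not stated
in the conventions this package follows, but unstratified folds can leave
a fold nearly event-free at these event counts, so stratified is the
default. Predictors are standardized to unit variance inside the penalty
and coefficients reported on the original scale — without standardization
the penalty would prefer variables merely for having larger numeric
range. All randomness flows from one explicit seed, making
screen → selection → fit bit-reproducible.

The final stage is plain maximum-likelihood logistic regression with Wald
intervals on the log odds ratio (matching the symmetric-on-log-scale
intervals this literature prints; profile intervals are deliberately not
used). Complete separation — a predictor level with no events — is
detected from the diverging coefficient/standard-error pattern and
**reported** as OR 0 or infinity with an unbounded interval and the
non-significant Wald p, never repaired (no Firth penalty) and never
thrown: that mirrors how such rows appear in published multivariable
tables. Missing data are handled by complete-case analysis with a logged
drop count. Ordinal stages are coded 0/1/2 with "Unknown" as the top
level by default, giving a single per-increment odds ratio; the coding is
exposed because treating "Unknown" as ordinal rank 2 is a questionable
but reconstructible convention — recoding by any affine map rescales the
coefficient exactly as expected (tested).

Multi-category cancer indications are encoded as non-mutually-exclusive
binary indicators (one report can carry several), with no single
reference category.

## Cohort stage

The clinical-cohort stage reuses the same association tests for the
baseline comparison ("Unknown" stage is a level, not missingness), then
reports incidence and CTCAE grade distribution as percentages of the
**full cohort**, and management/complication summaries as percentages of
the **event subgroup** — the two denominators that make published cohort
summaries reproducible. Percentages round half-up to 2 decimals,
p-values to 3, matching table conventions; `round_half_up()` is exported
because IEC 60559 banker's rounding in base `round()` differs exactly at
the printed tie cases.

## The synthetic-data generator

`generate_faers_tables()` emits DEMO/DRUG/REAC/THER/OUTC/INDI tables in
the "$"-delimited dialect with `YYYYMMDD` integer dates, plus a
ground-truth sidecar. Structure emulated: one designated subject drug
(always role `PS` where present, in about 10% of reports by default),
1–3 co-reported background drugs per report with roles `SS`/`C`/`I`, a
synthetic event vocabulary (`TERM_0001`…) with a generated PT-to-SOC map
(synthetic vocabulary avoids shipping licensed MedDRA content),
independent per-(report, term) event draws at a 2% baseline rate
multiplied by any planted relative risks, conditioning of every report on
carrying at least one event term (as in real spontaneous reports),
whole-day Weibull onsets (default shape 0.785, scale 30 days — median
about 19 days), about a third of event dates missing, and duplicate cases
(15% by default, comparable to the duplicate share removed from real
demographic tables) that copy every row of the original under a new
`PRIMARYID`, mutating only `PRIMARYID` and `FDA_DT` so the deduplication
rule's selection is checkable against ground truth.

With a planted relative risk of 5 at these defaults the implied
report-level odds ratio is about 5.4 (the odds transformation and the
at-least-one-term conditioning partly offset), which is why recovery
tests assert the empirical ad/bc in [4, 6].

What the generator does **not** emulate: realistic co-prescription
structure, free-text drug-name noise, country/reporter correlation
structure, event–event dependence beyond the at-least-one-term
conditioning, and reporting biases. Passing tests therefore demonstrate
algorithmic correctness under a clean generative model, not robustness to
the messiness of real spontaneous-report data.

`generate_cohort()` draws covariates independently from their stated
marginals, the outcome from a logistic model with specified log odds
ratios, and a CTCAE grade (multinomial, grades I–IV) only for patients
with the outcome. The default configuration emulates a 170-patient,
almost entirely male thoracic-oncology cohort (esophageal/lung cancer,
platinum-based chemotherapy) with true cisplatin OR 2.24, per-increment
M-stage OR 0.871, an intercept giving roughly two-thirds outcome
prevalence, and a conditional grade distribution of roughly
60/28/6/5% across grades I–IV. Covariate independence is a simplification:
real stage and drug variables are correlated.

Both generators use R's default Mersenne-Twister RNG through
`set.seed()`, so a fixed seed gives identical output across runs and
platforms.

## Orchestration and reproducibility

`run_config()` / `run_pipeline()` drive the stages behind one declarative
configuration: cleaned dataset and exclusion log, characteristics table,
PT- and SOC-level signal tables, TTO bins and Weibull fit, risk-factor
tables, cohort tables, and a manifest (package and R version, seed,
configuration hash, file list; no timestamps). Every artifact regenerates
byte-identically from the same inputs and seed. A stage failure leaves
partial artifacts in place and records the failing stage in the manifest.
The exported functions are the interface; the acceptance script under
`scripts/` is a worked example of driving them non-interactively.

## Problem sizes used in validation

The shipped tests validate: exact closed-form oracles and printed-table
arithmetic at trivial sizes; chi-square and Fisher selection against
`stats` on expanded published contingency tables; planted-signal recovery
on twenty seeded 50,000-report databases (all four criteria, ≥ 95%
required); null behaviour at 10,000 reports; Weibull recovery at
500–10,000; interval coverage over 200 replicates; odds-ratio recovery as
the mean log OR over twenty 5,000-patient cohorts (within 10% of truth);
and byte-level reproducibility of the full pipeline at a few thousand
reports. These sizes were chosen so each statistical check has comfortable
power against its stated band.

## Known limitations

* Disproportionality statistics quantify reporting associations, not
  incidence or causality; there is no exposure denominator in
  spontaneous-report data.
* The comparator is always "all other reports in the supplied dataset";
  reconstructing a full multi-database background is out of scope, so
  absolute signal magnitudes depend on the dataset handed in.
* No stratified or adjusted disproportionality, no MCMC BCPNN, no
  censoring/competing-risk TTO models, no imputation, no interaction
  terms, no Firth correction.
* The day-rounding shape bias and the generator's independence
  simplifications described above.
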