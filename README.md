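# pvmine

Pharmacovigilance signal mining and risk-factor analysis for spontaneous
adverse-event reports, with a clinical-cohort arm.

## What it is for

Spontaneous reporting databases such as the FDA Adverse Event Reporting
System (FAERS) are the primary post-marketing source for drug-safety
signals, but they arrive as raw quarterly "$"-delimited tables full of
duplicate case versions, multi-drug multi-event reports and missing
dates, and they carry no exposure denominator — so analysis proceeds by
*disproportionality*: comparing how often an event is reported with the
subject drug against the database background. `pvmine` implements that
workflow end to end for analysts studying a single subject drug (the
motivating use case is myelosuppression under a PD-1 checkpoint
inhibitor given with chemotherapy):

* **Ingest** — parse DEMO/DRUG/REAC/THER/OUTC/INDI tables, deduplicate
  cases (most recent `FDA_DT`, then highest `PRIMARYID`), keep reports
  where the subject drug is the primary suspect (`ROLE_COD = "PS"`),
  assemble linked report records with exclusion logging, and tabulate
  characteristics with the field's binning conventions.
* **Signal detection** — report-level 2×2 tables per preferred term (PT)
  or system organ class (SOC) and four algorithms with their standard
  criteria: ROR (Woolf CI; lower bound > 1, n ≥ 3), PRR (≥ 2 with
  Yates χ² ≥ 4, n ≥ 3), the Bayesian information component
  (IC − 2SD > 0) and the DuMouchel empirical-Bayes geometric mean
  (EB05 > 2), the latter with its two-gamma mixture prior fitted to the
  whole table set by marginal maximum likelihood.
* **Time to onset** — days from therapy start to event, described by
  median/IQR and standard bins, and modelled by a maximum-likelihood
  Weibull fit: shape β < 1 with its whole 95% CI below 1 means a hazard
  concentrated early in treatment.
* **Risk factors** — case/non-case design with a strict single-PT case
  definition, univariate screen (χ²/Fisher/Wilcoxon, p < 0.10), LASSO
  selection with 10-fold cross-validation and the one-standard-error
  rule, and multivariable logistic regression with Wald CIs and explicit
  complete-separation reporting.
* **Cohort analysis** — baseline group comparisons, incidence and CTCAE
  grade distribution (full-cohort denominator), and management summaries
  (event-subgroup denominator).
* **Synthetic data** — seeded generators for FAERS-like tables (planted
  drug–event relative risks, injected duplicates, Weibull onsets, missing
  dates) and logistic-model cohorts, with ground-truth sidecars, so the
  whole pipeline is testable offline.

MedDRA is licensed; PT→SOC mappings are always user input (the generator
ships a synthetic vocabulary).

## Worked example

Simulate a 20,000-report database with a planted fivefold reporting risk
for one drug–event pair, clean it, and mine it:

```r
library(pvmine)

cfg <- faers_sim_config(
  n_reports = 20000, seed = 42,
  planted_effects = data.frame(drug = "DRUG_0001", term = "TERM_0007",
                               rr = 5))
sim   <- generate_faers_tables(cfg)
dedup <- deduplicate_reports(sim$tables$demo)
subj  <- filter_primary_suspect(sim$tables$drug, "DRUG_0001")
fd    <- assemble_reports(dedup$demo, sim$tables$drug, sim$tables$reac,
                          ther = sim$tables$ther, outc = sim$tables$outc,
                          indi = sim$tables$indi, subject_ids = subj)
fd
#> <faers_data> 20000 reports (2067 subject-drug), 26514 reaction rows
#>   excluded: 0; orphan drug/reac rows: 6173/3974

sig <- signal_table(fd)
head(sig[, c("term", "n", "ror", "ror_low", "prr", "chi2",
             "ic_minus_2sd", "eb05", "signal")], 3)
#>        term   n      ror  ror_low      prr        chi2 ic_minus_2sd     eb05 signal
#> 1 TERM_0007 416 5.460486 4.799603 4.562778 804.3631980    1.5558215 3.326217   TRUE
#> 2 TERM_0006  97 1.093058 0.880529 1.088691   0.5623929   -0.2056848 0.919717  FALSE
#> 3 TERM_0017  96 1.030959 0.830137 1.029521   0.0483826   -0.2775184 0.919717  FALSE

fit <- weibull_mle(collect_tto(subject_reports(fd)))
fit
#> <weibull_fit> n=1373  shape 0.825 (95% CI 0.792-0.859)  scale 30.54
#>   hazard: decreasing over time
```

Reading the output: the planted pair — and only it — is flagged by all
four criteria (ROR 5.46 with lower bound 4.80, PRR 4.56 with χ² 804,
IC − 2SD 1.56 bits, EB05 3.33), with the empirical odds ratio sitting
near the planted relative risk of 5. The orphan counts are the drug and
reaction rows of the duplicate case versions removed at deduplication.
The Weibull shape of 0.825 with its whole CI below 1 classifies the
onset hazard as decreasing: event risk concentrates early in therapy
(the generator's truth is shape 0.785; onsets are recorded in whole
days, which nudges the fitted shape slightly upward).

`run_pipeline(run_config(...))` chains all stages behind one seeded
configuration and writes CSV/JSON artifacts plus a manifest; the same
inputs and seed reproduce every file byte-identically.

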