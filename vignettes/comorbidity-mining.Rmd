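---
title: "Mining comorbidity structure in cancer discharge cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining comorbidity structure in cancer discharge cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbidARM)
```

## The problem and the data model

Hospital-discharge registries record one row per discharge *episode*: a
principal ICD-10 diagnosis, a list of secondary diagnoses, ICD-9-CM
procedure codes, a main surgery code, demographics, and a treatment outcome.
comorbidARM analyses such cohorts restricted to malignancies (principal
diagnosis in C00–C97, adults ≥ 19 years) and asks two questions: which
chronic conditions — diabetes mellitus (DM), hypertension (HTN),
hyper-/hypothyroidism — cluster with which cancer sites, and how those
conditions relate to in-hospital death.

A deliberate modelling assumption, forced by the data: episodes carry no
person-level identifier, so every discharge is treated as an independent
observation. Repeat admissions of one patient are therefore counted once
per episode; associations must be read as episode-level co-occurrence, not
person-level comorbidity incidence.

## Phenotyping by code ranges

Codes are normalized (uppercased, dots stripped) and matched to inclusive
intervals with category/subdivision semantics: a bare-category endpoint
covers the whole category (C33 in C33–C34.9), and a bare category inside an
interval's span matches (E11 is in E11.0–E14.9). The shipped definitions:

* DM: E11.0–E14.9 (type 1, E10.x, deliberately excluded by the range start);
  HTN: I10; hyperthyroidism E05.0–E05.9; hypothyroidism E02–E03.9 and E89.0.
* Chemotherapy: procedure 99.25 *or* diagnosis Z51.1 — registries differ in
  which they record, so either marks the flag. Radiotherapy: procedures
  92.21–92.27 or 92.29 (the published range "92.21–9227 or 9229" read as the
  only self-consistent parse).
* Cancer sites: the four ranges with published definitions (stomach
  C16.0–C16.9, colorectal C18.0–C19, liver C22.0–C22.9, lung C33–C34.9) plus
  conventional ICD-10 categories for the thirteen sites whose ranges are not
  published (pancreas C25, bile duct C24, gallbladder C23, esophagus C15,
  small intestine C17, anus C21, larynx C32, kidney C64, ureter C66, bladder
  C67, prostate C61, multiple myeloma C90). These thirteen are assumptions;
  the whole map is overridable via a YAML file (`readCodeMap()`). Because
  the liver range C22.0–C22.9 contains intrahepatic bile duct (C22.1), the
  bile-duct label is restricted to C24 to keep the site partition disjoint —
  the partition (every episode gets exactly one site, with "other" as
  fallback) is enforced by the `CodeMap` validity method.

Comorbidity flags use *any* diagnosis position. In a cohort whose principal
diagnosis is a malignancy by construction, DM or HTN can only ever appear as
secondary diagnoses, so restricting them to the principal position would
erase them entirely.

## Prevalence tables and tests

`prevalenceTable()` produces stratum × condition counts with percentages
rounded half-up to one decimal (base `round()`'s round-half-even does not
match how such tables are printed). `chiSquareTest()` is the plain Pearson
χ² without continuity correction — the counts are registry-scale — and the
Bonferroni family size *m* is an explicit argument echoed in the result,
because which comparisons form a "family" is a reporting convention, not a
mathematical fact; making it explicit keeps any convention reproducible.
Both raw and adjusted p-values are reported.

## The Apriori miner and rule metrics

The miner is a from-scratch level-wise Apriori: frequent (k−1)-itemsets
sharing a (k−2)-prefix are joined, candidates with any infrequent subset are
pruned (anti-monotonicity), and survivors are counted against a boolean
incidence matrix. Every threshold is a *strict* inequality — support > 0.01,
confidence ("minimum reliability") > 0.1, lift > 1 — following the stated
exclusion of lift ≤ 1 as coincidence. Episodes with no items still count in
the denominator N: support is defined over all study participants.

Two numerical choices matter at the thresholds:

* Lift is computed as `n(AB)·N / (n(A)·n(B))`. Count products are exact in
  doubles at registry sizes, so a pair that is exactly independent yields
  lift exactly 1 and is excluded; the algebraically equal form
  `support/(P(A)P(B))` can round to just above 1 and leak through the strict
  threshold.
* The IS score is `sqrt(support × lift)`. The alternative plain product
  `support × lift` is inconsistent with every published IS value we
  reconstruct (e.g. √(0.069·2.629) = 0.426, while 0.069·2.629 = 0.181); the
  square-root form is the standard interest-support/cosine measure, and the
  identity IS = support/√(P(A)P(B)) is property-tested to 1e-12.

Consequents are restricted to single items by default (disease-pair mining;
all published rules have one-item consequents) with a switch for generality.
Ranking is by descending IS with ties broken by descending confidence —
the published table's own ordering of equal-IS bidirectional pairs — then
by descending count, then label, giving a deterministic total order. (The
accompanying text says rules are listed in "increasing" IS order; the table
is plainly decreasing, and the table is followed.) The "Other" site is an
item by default and excludable (`includeOther = FALSE`); it is part of the
transaction universe the analysis describes, but carrying a heterogeneous
catch-all item is a judgement call the configuration exposes.

## Mortality models

`fitMortality()` is maximum-likelihood logistic regression via IRLS
(`stats::glm`, binomial, convergence tightened to 1e-10, 100 iterations),
with SEs from the inverse observed information. Death is
`treatment_outcome == "death"` versus everything else. Controls are sex,
age group (categorical, reference 19–44 — age is never used continuously),
surgery, chemotherapy and radiotherapy; surgery is included by default
(`includeSurgery = FALSE` drops it) because the published table footnote
lists "operation" among controls even though the accompanying text omits
it. The all-cancer model does not adjust for cancer site by default; fits
within a single site need no such adjustment, and cross-site confounding is
a question the per-site models answer more directly.

Degenerate inputs are handled before fitting, not silently: zero-variance
columns and exposures with no events (or no survivors) among the exposed
are dropped with recorded reasons — this reproduces the "–" cells of
published per-site tables, where e.g. hyperthyroidism is inestimable in a
subset. Non-convergence and quasi-separation (|B| > 15 or SE > 100) are
flagged on the fit object. Reporting arithmetic is OR = exp(B), Wald CI
exp(B ± 1.96·SE), p = 2Φ(−|B/SE|), rounded half-up to 3 decimals.

## What the synthetic generator emulates

`generateCohort()` draws episodes matching, in expectation, the moments the
analysis consumes:

* the 17-site distribution and the site-conditional DM/HTN prevalences of
  the published prevalence table (defaults are the printed counts divided
  by the printed totals);
* overall marginals DM 12.9%, HTN 20.4%, hyperthyroidism 0.2%,
  hypothyroidism 1.1%; sex 53.9% male; age groups
  (14.5%, 44.6%, 25.7%, 15.2%); surgery 40.7%, chemotherapy 11.4%,
  radiotherapy 0.4%;
* a planted global DM–HTN lift of 2.629. With site-conditional prevalences
  active, each site's 2×2 joint is `λ·p(DM|s)·p(HTN|s)` with a single λ
  chosen so the *global* lift hits the target exactly in expectation
  (λ = L·p(DM)·p(HTN) / Σ w_s·p(DM|s)·p(HTN|s)); applying the target lift
  within every site would overshoot globally, because site-level DM and HTN
  prevalences covary across sites. Every per-site joint is checked against
  its Fréchet bounds at configuration time, and infeasible configurations
  error before any draw;
* a logistic death mechanism. Exposure coefficients default to the
  published all-cancer mortality model (DM −0.086, HTN 0.182, hypothyroid
  0.033, hyperthyroid 0.568); the control coefficients are not published, so
  the defaults are epidemiologically plausible choices made once (male 0.4;
  age 0.6/0.9/1.3 across the three older groups; surgery −0.8 — operated
  patients are fitter and earlier-stage; chemotherapy 0.2; radiotherapy
  0.1). The configured `baselineDeathRate` (default 0.061, the cohort-wide
  death fraction) is interpreted as the reference-group rate and sets the
  intercept at its logit; the marginal death rate therefore sits somewhat
  above 6.1% under the default positive age effects. Non-death outcomes are
  split improved / not improved / other at the published conditional
  proportions.
* Insurance-type and admission-route marginals are not published; defaults
  (national health 95/3/1/1; outpatient 70, emergency 25, other 5) are
  realistic assumptions for a Korean national registry and only feed
  pass-through fields.

Records are emitted as ICD *codes*, not flags — one representative code per
condition (e.g. liver → principal "C22.0", DM → secondary "E11.9", mixed
dotted and undotted forms) — so phenotyping is exercised end to end and
recovers the planted flags exactly; this round trip is tested. A single
seeded Mersenne-Twister stream is used with a documented field-by-field
draw order (site, DM/HTN, thyroid, sex, age, treatments, death, outcome,
administrative fields), so outputs are byte-identical for a given config
and seed, and appending new fields later cannot shift existing draws.

What the generator does *not* emulate — and hence what passing tests cannot
show about real registry data: higher-order dependence beyond the planted
pairwise and site-conditional structure (thyroid flags are independent of
everything), within-patient correlation across repeat episodes, secular
trends across survey years, sampling weights and hospital strata, coding
errors and rare/invalid codes, and any dependence of treatment variables on
site or stage.

## Problem sizes and tolerances in the test suite

The suite reconstructs all 22 published rule rows and all 19 estimable
OR/CI rows from printed inputs; printed OR/CIs were evidently computed from
unrounded coefficients, so the check allows exactly the uncertainty that
3-decimal rounding of B and SE propagates to each quantity (about 2.5 parts
per thousand) rather than demanding bit-level agreement with rounded
inputs. Miner correctness is established by exhaustive-enumeration
equivalence on 200 random toy instances (≤ 10 items, ≤ 200 transactions,
metrics to 1e-12). Stochastic recovery uses a 200,000-episode cohort for
the planted lift (within 5% relative) and forty 50,000-episode cohorts for
mortality-coefficient recovery (each term within 3 estimated SEs in ≥ 95%
of seeds) — sizes chosen to keep Monte-Carlo error comfortably inside
those bands while the whole suite runs in a few minutes.

## Known limitations

Episode-level analysis (no patient linkage), no temporal ordering between
comorbidity and cancer, operational disease definitions by diagnosis code
only, assumed code ranges for thirteen sites, no survival-time modelling
(logistic death at discharge only), and no significance testing of rules
beyond the threshold filters. These mirror the limitations of the study
design the package implements; the configurable code map and explicit
Bonferroni family are there precisely so alternative conventions can be
tried without touching code.
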