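---
title: "Disproportionality screening of spontaneous reports: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvror)
```

This vignette is the package's own account of its methods: the statistical
model behind each stage, the parameters that matter, the design choices that
were genuinely open and how they were resolved, what the synthetic-report
generator does and does not emulate, and the numerical conventions used
throughout.

## 1. The data model

A spontaneous adverse-event report carries one patient's demographics
(sex, age, country, reporter type), one or more drug mentions (name, role,
ATC codes, start date), one or more coded reactions (a preferred term, PT,
with an optional first-occurrence date), clinical indications, and outcome
flags. Because the drug and reaction sides are one-to-many, the canonical
container is relational: a `report_set` bundles a `cases` tibble with
`drugs` and `reactions` child tables keyed by `case_id`. A nested
one-row-per-case view is available via `as_tibble()`.

Adverse-event coding is hierarchical: each PT has one primary high-level
group term (HLGT) and one primary system organ class (SOC), and the
HLGT-to-SOC map must itself be functional. The licensed coding dictionary
cannot be redistributed, so the package ships a small **synthetic**
dictionary (24 PTs across 6 SOCs) with field-standard term names; any
user-supplied `pt,hlgt,soc` CSV with a functional hierarchy works in its
place.

Case seriousness is derived from the outcome flags with a fixed precedence:
*critical* (death or life-threatening) over *serious* (hospitalisation,
disability, other serious) over *non-serious*. The precedence makes
severity a single ordered factor suitable for regression; a multi-flag case
contributes to exactly one class.

Two ingestion conventions are fixed rather than configurable, because
dashboard-style exports vary and silent dialect guessing is worse than a
documented contract: sub-fields within a mention are separated by `|`,
list items by `;`, dates are ISO-8601, and the first line of a cases file
is a dialect marker comment. Drug names are normalized (lowercase, trimmed,
internal whitespace collapsed) before any matching, since brand and generic
mentions of one substance must pool. Any drug role other than `suspect`
(e.g. "interacting") collapses to `concomitant`: the analyses only ever
distinguish suspect drugs, and inventing a third role would suggest a
distinction the methods do not use. Malformed rows are never silently
dropped — they are diverted to a problem ledger (`case_problems()`).

## 2. Preprocessing

The stage order is fixed: **deduplicate → exclude → classify**.

**Deduplication** uses exact equality on a seven-field matching key: age
(rounded to whole years), sex, country, initial receive date, the sorted
set of suspect drug names, the sorted indication set, and the sorted
reaction-PT set. Within a key group the case with the lexicographically
smallest identifier is retained. Three sub-choices deserve note:

* *Suspect drugs only* enter the key. Concomitant lists are the least
  reliably coded field in spontaneous reports; including them would make
  true duplicates with ragged co-medication lists invisible.
* *Missing matches missing.* Duplicate submissions typically share their
  missingness pattern, so a missing age is treated as an ordinary matching
  token rather than a wildcard.
* Exact matching only — no probabilistic record linkage. This keeps the
  operation deterministic, order-invariant and idempotent, all of which are
  tested properties.

A consequence worth understanding: two *independently generated* reports
can be genuinely key-identical (same demographics, date, drugs, reactions).
Exact-key deduplication must and does collapse them; the generator's
duplicate ledger therefore equals the removed set only when the simulated
demographics are rich enough to make coincidental identity vanishingly
rare, and the ledger tests run in such a configuration.

**Exclusion** removes any case in which *any* drug mention (not only
concomitant ones) carries an ATC code with prefix N05, N06 or N07B —
psycholeptics, psychoanaleptics, and drugs used in addictive disorders.
Scanning all roles is the conservative reading: a psychotropic coded as
suspect confounds a psychiatric-event analysis at least as strongly as a
concomitant one. Prefix matching is a plain string-prefix test per code, so
N07A is not caught by N07B.

**Exposure classification** assigns each case to one mutually exclusive
category: one of the six fluoroquinolone monotherapies, `combination`, or
`non_fq` (the comparator stratum). Monotherapy demands exactly one distinct
fluoroquinolone and *no other drug mention of any role* — treating
single-drug and combination columns as mutually exclusive, as summary
tables in this field do. Combination cases are subtyped with precedence
`multiple_fqs` (≥ 2 distinct FQs) > `fq_plus_antibiotics` (any non-FQ drug
with ATC prefix J01) > `fq_plus_other_meds`.

Age groups bin at 0–17 / 18–34 / 35–64 / 65+ (lower bounds inclusive);
missing ages form their own `unspecified` level rather than being dropped.

## 3. Disproportionality screening

For an exposure stratum and a term at a chosen hierarchy level, cases are
cross-classified into the 2×2 table (a, b, c, d) described in the README.
Key conventions:

* **Case-level counting.** The report is the sampling unit: a case with two
  PTs under the same HLGT contributes once to `a` at HLGT level. Counting
  reactions would double-count patients and inflate every estimate.
* **Comparator = everything else.** Each stratum's comparator is every case
  not in the stratum, so `a + b + c + d` is always the total case count.
  Whether per-drug rows should instead count combination users as exposed
  to each constituent drug is genuinely ambiguous in field practice; the
  mutually exclusive reading is implemented because the strata then
  partition the data and per-term counts conserve exactly (a tested
  invariant). This is the main sensitivity point when comparing against
  analyses that chose otherwise. A pooled `all_fq` stratum (any
  fluoroquinolone exposure) is emitted alongside.
* **CI method.** No specific interval is canonical in the applied
  literature; the log-Wald interval with z = 1.96 is used, matching
  universal disproportionality practice. With all cells ≥ 3 (the display
  rule) its coverage is adequate, and the suite verifies 93–97% empirical
  coverage at n = 20000.
* **Zero cells.** The Haldane–Anscombe 0.5 correction is applied to all
  four cells only when some cell is zero, and flagged. Signals still
  require `a ≥ 3` *uncorrected* cases, so the correction can never create a
  signal out of sparsity.
* **No multiplicity adjustment on the screen.** Benjamini–Hochberg is
  applied to the time-to-onset comparisons and the risk-factor screen,
  not to the signal rule itself. The signal rule is a fixed decision
  criterion whose false-positive behaviour is instead characterised
  directly: under an all-null generator it fires for ≤ 4% of screened
  pairs. Users combining the screen with formal error control should adjust
  downstream, and the documentation says so rather than silently adjusting.

The 2×2 ROR is algebraically the odds ratio of a saturated univariate
logistic model, and the suite checks the two code paths agree to 1e-6 —
connecting the screening module to the regression module through an exact
identity rather than a convention.

## 4. Time to onset

Time to onset is `event_date − start_date` in whole days: the earliest
start among *suspect fluoroquinolone* mentions, to the earliest event date
among reactions mapping to the SOC under study. "First occurrence" fixes
the event side; the drug side is a choice, and the earliest start is used
as the conservative exposure origin. Day-0 (same-day) onsets are valid —
median onsets in this domain are 0–2 days, so excluding them would bias
every summary. Negative intervals are data inconsistencies and are
*dropped, not clamped*: clamping to zero would manufacture mass at the most
clinically interesting value. Cases lacking either date are dropped with
reason `missing`. All drops are returned as data with per-reason counts.

Group comparisons use the Wilcoxon rank-sum test (exact enumeration when
both groups have ≤ 20 tie-free observations, otherwise the tie-corrected
normal approximation with continuity correction) and the tie-corrected
Kruskal–Wallis test with a chi-square reference. Pairwise post-hoc
comparisons reuse Wilcoxon with one Benjamini–Hochberg family — not Dunn's
test, keeping the post-hoc statistic identical to the two-group statistic.
Degenerate input (all observations identical) returns H = 0, p = 1 by
convention rather than NaN. With two groups, Kruskal–Wallis and the
Wilcoxon approximation agree asymptotically, and the suite checks this at
n = 100 per group.

One step-up subtlety: Benjamini–Hochberg adjustment is *not* idempotent
(applying it to already-adjusted values changes them again), so the suite
asserts the true properties — agreement with the hand-applied step-up rule,
element-wise `adjusted ≥ raw`, permutation equivariance — and nothing more.

## 5. Risk factors: imputation and univariate logistic screening

Missing age and unspecified sex are completed by k-nearest-neighbour
imputation before regression. Distances are Gower (range-scaled absolute
difference for numerics, 0/1 mismatch for categoricals, averaged over the
features available for each recipient) over sex, age, country, reporter,
exposure category and severity class; defaults are k = 5 donors, median
aggregation for age, mode with alphabetical tie-break for sex. All
settings are exposed in the API. The implementation is deterministic: ties
in donor distance break by case identifier order. A rectangular
recipient-by-donor Gower routine is implemented in the package, processed
in blocks to bound memory. Observed values are never altered, and the
imputation report lists every imputed record.

The regression stage is deliberately **univariate**: one logistic model per
factor (maximum likelihood via iteratively reweighted least squares),
per-level odds ratios `exp(coef)` with Wald 95% intervals, reference levels
fixed at ciprofloxacin (exposure), monotherapy (therapy type), male (sex),
0–17 (age group) and non-serious (severity). Reference rows are emitted
with OR ≡ 1 for readability. The phrase "adjusted for the other factors"
is often ambiguous between covariate adjustment and multiplicity
adjustment; here the models are explicitly univariate and the adjustment is
Benjamini–Hochberg across *all non-reference levels of all predictors as
one family*. A multivariable model is intentionally out of scope, and the
documentation is explicit so users do not mistake the screen for one.
Quasi-separation (a level with zero or all events) and non-convergence are
flagged in the output, never silently dropped. Records whose other fields
remain unspecified after imputation keep `unspecified` as a modelled level.

## 6. The synthetic-report generator

`simulate_reports()` exists so that every downstream stage can be tested
against known truth. Per case it draws an exposure category, demographics,
one outcome flag, a drug panel realising the category, and per-PT events
with odds `ψ × baseline odds`, where `ψ` is the planted reporting odds
ratio (1 unless planted). Onset days are log-normal, rounded to whole days;
`event_date = start_date + onset`; the receive date follows after a short
reporting delay. Field-level missingness, psychotropic co-medication (for
the exclusion stage) and duplicate emission (clones of the full matching
key under a fresh, lexicographically larger identifier) are applied last.
The truth ledger records the planted table, realized per-pair counts among
clean core cases, the duplicate pairs, and per-case assignments.

Defaults were chosen once to mirror the marginal shape of a
fluoroquinolone adverse-event cohort: exposure shares dominated by
ciprofloxacin/levofloxacin with a large combination stratum and a non-FQ
comparator majority; sex ≈ 54% female; age groups peaking at 35–64 with
agent-specific profiles (moxifloxacin cohorts skew older, ciprofloxacin
younger — which also gives the imputation stage a genuinely informative
neighbourhood structure); ~2.6% fatal outcomes; onset medians of ~2 days
(log-normal meanlog = log 2, sdlog = 1.1); 5% duplicate emission; 4%
psychotropic co-medication; and a planted signal landscape with shared
psychiatric/ocular signals across several agents plus
moxifloxacin-specific anterior-segment terms. Planted magnitudes are scaled
to be observable at simulation size: a real database's most extreme RORs
(thousands) arise from baseline odds of ~10⁻⁵ against tens of millions of
comparator cases and cannot be reproduced in a 10⁴-case simulation, so the
generator plants ψ up to 60 on baselines where 3+ cases are expected.

What the generator does **not** emulate — hence what passing tests do not
show about real data: PT–PT correlation within a case (events are
independent given exposure; sufficient for validating a marginal 2×2
method), reporting-delay dynamics and stimulated reporting after regulatory
warnings, notoriety and channeling biases, fuzzy rather than exact
duplicates, free-text drug-name noise beyond case/whitespace, and missing
data mechanisms other than MCAR. Results on real spontaneous reports
inherit all the usual caveats of disproportionality analysis — no incidence
denominator, reporting biases, and signals that are hypotheses rather than
causal effects.

## 7. Numerical conventions and validation sizes

* Printed percentages use half-up rounding to 2 decimals (matching how
  summary tables are typeset), not banker's rounding.
* Result TSVs are written with ratios at 6 significant digits; identical
  configuration and seed give byte-identical outputs, which is tested.
* All randomness flows from a single integer seed per run; the generator
  restores the RNG state afterwards (`withr::with_seed`).
* Chi-square tests are uncorrected Pearson (no Yates correction), with an
  advisory flag recommending Fisher's exact test when any expected cell is
  below 5 — "where appropriate" is operationalised as that standard rule.
  The two-sided Fisher p uses the probability-ordering definition.
* Validation problem sizes were chosen as the smallest that make the
  Monte-Carlo checks sharp: null calibration and interval coverage at
  n = 20000 (100 and 500 replicates), planted-ROR recovery at n = 100000
  (100 replicates, band 4.5–5.5 chosen from the Wald standard error at
  those counts), logistic age-effect recovery at n = 50000, onset-median
  checks at ~10⁴ onset samples.

## 8. Known limitations

* Exact-key deduplication cannot distinguish true duplicates from
  coincidentally identical independent reports; with sparse demographics
  this is a real (if rare) event, and the package makes no probabilistic
  attempt to separate them.
* The comparator convention (mutually exclusive strata) means per-drug RORs
  are not directly comparable to analyses that count combination users as
  exposed to each constituent drug.
* Screening provides no formal multiplicity control by design; the null
  firing rate (≤ 4% per pair under the all-null generator) is a
  characterisation, not a guarantee across arbitrary dictionary sizes.
* The imputation quality claim (beats marginal-median under MCAR) is
  conditional on informative neighbourhood structure; with features
  independent of age, k-NN imputation adds noise and the median is the
  better estimator.
* Time-to-onset analysis treats onsets as fully observed; there is no
  censoring model, survival machinery, or competing-risk handling.
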