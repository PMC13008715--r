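---
title: "Methods: disproportionality screening of spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem and the data model

Spontaneous adverse-event databases (FAERS and its peers) collect individual
case safety reports: one case carries demographics, one or more drugs with
role codes (Primary Suspect, Secondary Suspect, Concomitant, Interaction),
one or more event terms coded as MedDRA Preferred Terms (PTs), outcome codes,
and dates. The data are voluntary reports, not incidence data — there is no
denominator of exposed patients, reporting is biased by publicity and time on
market, and a case may be submitted repeatedly as follow-up versions.

`faersignal` works on this data model for a configurable set of *target*
drugs (the defaults are the three oral endothelin receptor antagonists used
in pulmonary arterial hypertension: bosentan, ambrisentan, macitentan).
Because the raw quarterly tables are versioned, analysis starts with the
standard deduplication rule: within each `CASEID`, keep only the row with
the most recent FDA receipt date (`FDA_DT`). The rule leaves a tie
unspecified, so we break ties deterministically by the largest `primaryid`;
this choice only matters for byte-reproducibility, not for counts.

Partial dates are common. We parse `YYYY` and `YYYYMM` values to the start
of their period and record a precision (`"year"`, `"month"`, `"day"`).
Consumers decide what precision they need: receipt years are usable at any
precision, while time-to-onset requires day precision on both dates.

Ages arrive in mixed units; the unit codes `YR`, `MON`, `WK`, `DY`, `HR`,
`DEC` are converted to years (÷1, ÷12, ÷52.18, ÷365.25, ÷8766, ×10), and
values above 120 years are treated as missing rather than propagated.

## Cohort construction

Drug names are free text. Rather than fuzzy matching, normalization goes
through an explicit lexicon (`raw_name → INN`), shipped with the brand names
of the three default targets and extensible by the user; matching is
case-insensitive after whitespace collapsing, and unmatched names pass
through unchanged with a tally. This makes normalization deterministic and
its failure mode observable.

A report enters a drug's cohort only when that drug is the **Primary
Suspect** — the strictest role filter, trading sensitivity for specificity.
A case in which two distinct targets are both PS is emitted once per target:
each drug's scan then counts it once, and no scan double-counts a case. The
targets are oral drugs, so a missing route on the target record is imputed
as `"oral"`; reported routes are kept verbatim (lower-cased).

Events are *per-case sets*: a PT listed twice in one case counts once, and
at SOC level a case counts once per SOC no matter how many of its PTs fall
there. This matches the "number of reports" semantics of the counting unit
throughout. PT→SOC coding uses a user-supplied two-column dictionary
(MedDRA itself is licensed and cannot be shipped); PTs missing from the
dictionary are carried with SOC `"UNMAPPED"`.

Reports with no events cannot contribute to any contingency cell and are
dropped from the scan set (tallied).

## The four statistics

For a drug–event pair, with `a, b, c, d` the deduplicated case counts
(target with event, comparator with event, target without, comparator
without; the comparator is the whole database minus *all* target drugs,
so one target never sits in another's background):

* **ROR** = ad/bc with the Wald interval
  exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d)).
* **PRR** = a(c+d)/(c(a+b)) with
  SE(ln PRR) = √(1/a − 1/(a+b) + 1/c − 1/(c+d)).
* **χ²**: the reporting convention prints a chi-square without naming its
  form; we use the Yates-corrected Pearson statistic, the customary choice
  in this literature, with plain Pearson available via `correct = FALSE`.
* **BCPNN IC** = log₂(aN/((a+b)(a+c))) with Bayesian posterior moments
  E(IC), V(IC) under a Dirichlet-style prior (α = β = 2,
  α₁ = β₁ = γ₁₁ = 1 — the standard constants, configurable through
  `bcpnn_priors()`), and the lower bound IC025 = E(IC) − 2√V(IC). The
  two-standard-deviation form is what this field reports under the IC025
  name, and we keep that column name.
* **EBGM** (closed form) = aN/((a+c)(a+b)) with a Wald interval on the log
  scale. This is the simplified observed/expected ratio form — *not* the
  DuMouchel gamma-mixture fit — and it satisfies EBGM = 2^IC exactly, an
  identity the tests assert on every table.

Zero cells leave a statistic undefined; we report it as missing with the
affected flag negative rather than silently correcting, with the
Haldane–Anscombe +0.5 correction available as an explicit option
(`zero_cell = "haldane"`).

Two threshold presets ship because screening rules circulate in two forms:
`"methods_text"` (CI-bound rules only: ROR and PRR lower bounds > 1,
IC025 > 0, EBGM05 > 0) and `"table2"` (point-estimate floors added:
ROR ≥ 3, PRR ≥ 2, EBGM05 > 2). The default is `"methods_text"`, the
operative prose rule; the other is one switch away, and the pipeline records
which was used in its manifest. In both, a **consensus signal** needs at
least two of the four algorithms positive — the conjunction is what controls
false positives, not any single threshold. `min_case_count` defaults to 1
(no floor) and can be set to the customary 3.

A subtlety the tests document: with b, c, d fixed, ROR and PRR are strictly
increasing in `a`, but the observed/expected ratio (IC, EBGM) is only
monotone while `a` stays below the comparator margins — the expected count
grows with `a` too. The monotonicity property is asserted in that regime.

## Time-to-onset

TTO is the day difference between the case's event onset date and the
*earliest day-precise* therapy start date of the target drug. We use the
onset date from the demographics table, not the FDA receipt date, because
receipt would confound reporting lag with onset. Records with missing or
imprecise dates, or a negative difference (event recorded before therapy),
are `Unknown` — negative differences are real in FAERS (pre-existing events
reported under a later therapy) and imputing them would bias the left tail.

The printed bin labels in this literature overlap at the edges
(`91–121`, `121–150`, `151–181`); we bin half-open on the edge set
{0, 31, 61, 91, 121, 151, 181, 361} so each day maps to exactly one bin and
keep the conventional labels. Quantiles use linear interpolation
(`stats::quantile` type 7).

## Demographic strata and the sex volcano

Per-drug summaries count sex, age band ([0,18), [18,65), [65,∞) in years),
reporter occupation, outcome codes, country, route and receipt year, with
percentages of the drug total rounded *half-up* to 2 decimals (commercial
rounding, matching how such tables are printed; base R's banker's rounding
would disagree on boundary values). Outcomes are the one non-partitioning
variable: a case counts under every outcome code it carries. The
serious-outcome total sums death, life-threatening, disability and
required-intervention counts — the combination that defines the published
serious totals; hospitalization, other-serious and congenital anomaly are
tabulated but not included in it.

The sex-stratified volcano compares, within one drug's reports, female
versus male reporting of each PT: the fold change is the odds ratio of the
(sex × PT-vs-other-events) table, the p-value comes from the same Yates
chi-square used in the scan (the convention names only "P < 0.05"), and a
PT is flagged when FC > 1.2 or FC < 1/1.2 (strictly) and p < 0.05. PTs with
any zero cell are skipped and tallied rather than corrected.

Aggregate helpers mirror published summary conventions: `sex_ratio()` is
the x of "1:x" (female/male), `drug_share()` is each drug's percentage of
the pooled report total, and `age_band_share()` is each drug's share of the
pooled band count across drugs — the only reading of a cross-drug age
comparison consistent with per-drug band counts.

## Label novelty

`assess_novelty()` flags a PT as novel (`"Y"`) iff it is absent from every
supplied label PT list *and* at least two algorithms flagged it for at least
one drug. Labels are user-supplied flattened PT lists (one CSV row per
drug–PT); terms mentioned on a label only as an indication still count as
"already occurred" and should be kept in the list, yielding `"N"`. The
verdict is monotone: adding a PT to any label can only turn Y into N.

## The synthetic generator

`simulate_faers_bundle()` emulates the data model, not any real cohort:

* Each case draws a Primary Suspect drug; the targets hold small shares
  (3.1/4.3/2.6% by default, echoing the three drugs' relative report
  volumes) and 25 background drugs share the rest.
* Events are independent per-PT Bernoulli draws. The default per-PT rates
  follow a geometric ladder from 0.15 down to 0.002 over 50 PTs
  (≈1.8 events per case), giving both common terms and rare ones. A planted
  signal multiplies the rate for cases whose PS is the given drug, so
  expected cells — and hence the expected ROR — are available in closed form
  (`expected_contingency()`); with planted PTs on the rare end the true ROR
  is within a few percent of λ.
* Target cases are 74% female (the reported skew for these drugs);
  onset delays are log-normal (meanlog log 180, sdlog 1.4 — median ≈ 6
  months with a heavy tail), and about half of the reports lack a usable
  date pair (missing or month-precise start, missing onset, or onset before
  start), matching the high Unknown fractions seen in practice.
* 10% of cases receive a follow-up demo row (same `caseid`, later receipt,
  altered weight), so deduplication has observable work to do; a
  configurable fraction of target drug names is corrupted to exercise the
  lexicon tally.

What the generator deliberately does **not** emulate: correlated events
(real syndromes co-report), drug–drug interactions, reporting-rate drift
over calendar time, country/reporter structure beyond categorical draws,
and free-text name noise beyond simple corruption. Passing tests on
synthetic data therefore demonstrate *computational* correctness (counting,
formulas, rules, determinism) and statistical calibration under
independence — not robustness to the biases of real spontaneous data.

## Numerical and design choices

* All statistics are computed in double precision on vectorized columns;
  cells are coerced to double before products to avoid integer overflow at
  database scale.
* Scan ordering is deterministic: report count descending, then term
  lexicographic; reruns of the pipeline produce byte-identical TSVs, and
  the manifest hashes every output.
* Problem sizes in the test-suite scenarios: 1,000 random tables for the
  dual-implementation check, 50,000 synthetic cases for signal recovery
  (λ ∈ {2, 4, 8}), 10,000 draws for TTO median recovery, 1,000 cases with
  20% follow-ups for deduplication. These sizes give the Monte-Carlo checks
  comfortable margins (3 standard errors) while keeping a full run fast.
* The generator restores the caller's RNG state (`with_rng`), so seeded
  simulation never perturbs a user's session stream.

## Known limitations

Disproportionality is hypothesis-generating only: no causality, no
incidence, and sensitivity to masking and notoriety effects. The closed-form
EBGM lacks the shrinkage of the gamma-mixture fit, so for very small counts
its point estimate tracks the raw observed/expected ratio (the IC posterior
provides the shrunk view). The comparator is fixed to "full database minus
targets"; restricted comparators (same indication, same class) are out of
scope. MedDRA hierarchy levels other than PT/SOC are not modelled.
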