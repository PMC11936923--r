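---
title: "Methods: disproportionality screening and onset modelling in faerspv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening and onset modelling in faerspv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faerspv)
```

## The screening model

Spontaneous-report databases have no denominator: we never observe how
many patients took a drug, only how many adverse events were *reported*
for it. Disproportionality analysis therefore compares the share of a
given event among a drug's reports with its share among all other
drugs' reports. `faerspv` follows the four-algorithm design that has
become standard for single-drug FAERS screens.

The counting unit is the **(deduplicated report, distinct PT) record**,
not the case. A report listing three distinct preferred terms
contributes three records, all attributed to the report's
primary-suspect drug; duplicated PT rows within one report collapse to
one record. This choice makes a drug's record total exceed its case
total (roughly by the mean number of distinct reactions per report) and
keeps the PT-level and SOC-level denominators consistent: at SOC level,
two same-SOC PTs on one report still count as two records, with no
extra per-report collapse.

For each term the 2×2 table `a, b, c, d` (target drug × target event)
is screened by:

* **ROR** `= ad/(bc)` with lognormal CI
  `exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`;
* **PRR** `= a(c+d)/(c(a+b))` with the Pearson
  `χ² = (ad − bc)²·N / ((a+b)(c+d)(a+c)(b+d))`, no Yates continuity
  correction (the screening convention, and what the printed formula
  states);
* **BCPNN information component** `IC = log₂(aN/((a+c)(a+b)))`;
* **"EBGM"** `= aN/((a+c)(a+b))` with a lognormal lower limit.

Note that `IC = log₂(EBGM)` holds *exactly* under these definitions —
both are the observed-to-expected reporting ratio — and the test suite
asserts the identity on 10⁴ random tables. The quantity called EBGM here
is the raw relative reporting ratio, not the posterior geometric mean of
the gamma-Poisson shrinker that the MGPS acronym historically denotes;
we keep the field's column name for comparability with published signal
tables but flag the nomenclature mismatch. True empirical-Bayes
shrinkage (openEBGM-style hyperparameter estimation) is deliberately out
of scope.

An event is called an adverse reaction only when **all four** positivity
thresholds hold (lower ROR CI > 1 with n ≥ 3; PRR ≥ 2 with χ² ≥ 4 and
n ≥ 3; IC025 > 0; EBGM05 > 2). The conjunction is monotone: loosening
any threshold can only add terms, a property the tests check. No
multiple-comparison correction is applied — the four-way conjunction is
itself the (heuristic) specificity device of this design.

### The IC lower limit

The BCPNN literature offers several variance approximations for IC, and
published four-algorithm tables built with the common tooling show a
count-independent gap of almost exactly 1.67 between IC and its printed
lower limit across rows spanning three orders of magnitude in `a`. The
default mode therefore uses the fixed offset `IC025 = IC − 1.67`, which
reproduces that convention. A principled `"delta"` mode is offered as
the alternative:
`V(IC) = (1/ln 2)² · (1/a − 1/(a+b) + 1/(a+c) − 1/N)`,
`IC025 = IC − 2√V(IC)`. The delta-method limit is tighter for large
cells; users comparing against published tables should keep the default,
users screening de novo should prefer `"delta"`.

### Zero cells and degenerate tables

When `a ≥ 1` but any of `b, c, d` is zero, all four cells receive the
Haldane–Anscombe +0.5 before statistics and limits are computed, and the
result carries a `corrected` flag. `a = 0` yields NA statistics with all
flags false — a term never reported for the drug is not a signal, and
dividing around it is meaningless. The n ≥ 3 rules make both situations
rare in practice.

## Ingestion and deduplication

FAERS quarterly ASCII files are `$`-delimited with a header line and no
quoting dialect. A row whose field count disagrees with the header
cannot be repaired unambiguously, so it is counted, reported, and
dropped; unparseable dates become absent fields with the row retained.
Partial dates keep a precision tag (`day`/`month`/`year`) because the
onset analysis needs day resolution while descriptives only need years.

Deduplication follows the FDA-recommended rule: per CASEID keep the
version with the maximum FDA receipt date, ties broken by the highest
PRIMARYID (numeric comparison when the ids are digit strings,
lexicographic otherwise — real FAERS ids are numeric; the fallback keeps
synthetic ids safe). The operation is idempotent and returns exactly one
row per case, asserted as properties.

Primary-suspect selection matches `drugname` *or* `prod_ai` against the
user's patterns after upper-casing, trimming and collapsing internal
whitespace; matching is exact-after-normalization by default with an
optional substring mode. Reports whose drugname matches but whose
active-ingredient text differs are kept (match on either field), since
free-text FAERS drug names are the noisier of the two fields.

## Demographic descriptives

Age bins partition at 18, 65 and 85 years: `<18`, `[18, 65)`,
`[65, 85]`, `>85`. Published tables of this design print overlapping bin
labels ("18–65", "65–85"); a partition requires a choice, and we place
the half-open boundaries at 18 and 65 with 85 closed. Occupation codes
map MD → Physician, CN → Consumer, PH → Pharmacist, and both HP and OT
pool into "Health professionals" (the four-named-categories convention).
Percentages are count/total × 100 rounded **half-up** to one decimal;
base R's banker's rounding would turn e.g. 39.55 into 39.5.

## Time to onset and the Weibull model

TTO is the day difference from the *earliest day-precision therapy
start* of the target drug to the event onset date. Reports with absent
or partial dates on either side are excluded with a reason code
(`missing`/`partial` × `event`/`start` date, `negative`); a same-day
onset is remapped to 0.5 days because the Weibull support is strictly
positive (the remap count is logged). When several therapy rows exist
the minimum start is used — onset is measured from treatment initiation.

The two-parameter Weibull density is fitted by maximum likelihood via
the profile score in the shape β: for fixed β the scale MLE is
`α = (mean(tᵝ))^(1/β)` in closed form, and the profile score
`1/β + mean(log t) − Σtᵝ log t / Σtᵝ` is monotone in β, so a bracketed
root search (tolerance 10⁻¹²; the fit errors if the final score norm
exceeds 10⁻⁸) finds the global optimum without multivariate
optimization. Confidence intervals come from the observed information on
the `(log α, log β)` scale, exponentiated back — standard for positive
parameters and guaranteeing positive bounds. `t^β` is computed on values
scaled by the sample maximum to avoid overflow. Degenerate samples (all
values equal) and n < 10 are rejected. The test suite cross-checks the
fit against an independent general-purpose fitter and asserts scale
equivariance (`t → kt` multiplies α̂ by k and leaves β̂ unchanged, to
10⁻⁶).

The failure mode is a total function of the shape CI: `early` when the
upper bound is below 1 (decreasing hazard — most onsets soon after
initiation), `wear-out` when the lower bound exceeds 1, `random`
otherwise (including CIs touching 1). Quantiles use R's default
inclusive linear interpolation (type 7); no competing-risk or censoring
adjustment is attempted — the model describes observed onsets only.

## Reconstruction of published tables

`reconstruct_counts()` inverts the statistic definitions: given a row's
`a`, the drug's record total `a + b`, and the printed ROR and EBGM, the
ratio `c/d = a/(ROR·b)` and the absolute scale
`d = aT(EBGM − 1) / (a(1+r) − EBGM·r·T)` recover the two unobserved
cells, from which *all* four statistics can be re-evaluated. This turns
published signal tables into worked examples: the package's acceptance
script recomputes a row's PRR and ROR confidence bound from nothing but
that row's printed summary statistics. At EBGM = 1 the scale is
indeterminate (any balanced table matches); the function then requires
marginal consistency and returns the representative with equal drug and
comparator margins.

## The synthetic generator

`simulate_faers()` is the package's stand-in for the raw database. It
emulates the features the pipeline must survive: the seven-table
quarterly file layout (DEMO/DRUG/REAC/THER are emitted; the others are
optional inputs), duplicate case versions (2–3 PRIMARYIDs per case with
receipt dates shifted 1–90 days), role codes with concomitant co-drugs,
free-text name casing, missing demographics, partial dates, and
Weibull-distributed onset intervals. Its defaults encode the study
conditions of the motivating cohort: sex missingness 24.9%, age
missingness 42.3%, occupation shares 61.4/29.7/4.7/2.4/1.8%, report
years weighted 5.2/27.1/67.7% over 2022–2024, onset times
Weibull(β = 0.80, α = 133.72 days) with 16% of reports carrying complete
onset and start dates, and about 2.1 distinct PTs per case
(1 + Poisson(1.1), capped at 6).

The generative model is deliberately *conditional*: record totals per
drug are fixed by the case count times the mean PT count, and each
case's distinct PTs are drawn from the weight vector in which signal
pairs carry their relative risk `RR` and all other PTs weight 1. This
makes the expected cells closed-form (`expected_tables()`), at the price
of a first-order approximation: within-case distinctness deflates the
expected count of strongly elevated PTs by up to ~2%, which the oracle
tests absorb explicitly.

Default problem sizes are 400 target cases and three comparators of
2,000 cases each — chosen so that one generated dataset and its full
analysis run in about a second, letting the recovery suites use dozens
of replicates. The default injected relative risk is 12 across five
eye-disorder PTs, fixed by an a-priori power calculation: with these
sizes the expected signal cell is ≈88 records and the expected relative
reporting ratio ≈4.7, which clears the binding constraint — the
fixed-offset IC025 > 0 needs EBGM > 2^1.67 ≈ 3.18 — by about three
standard errors of `log EBGM`, so a four-way positive call is the
overwhelmingly likely outcome per replicate without being trivially
saturated.

What passing these tests does **not** show: real FAERS data have
correlated co-reported PTs, secular reporting trends, drug-specific
demographic profiles, indication channeling and duplicate reports that
differ in content across versions. The generator models none of these,
so end-to-end recovery demonstrates that the pipeline's plumbing and
statistics are correct, not that four-way positivity has any particular
sensitivity or specificity on real reports. Published full-database
headline figures (case and record totals, positive-PT counts, onset
medians) require the actual FAERS download and are reachable through
`scripts/integration_faers.R`, not through the desk-scale suite.

## Known limitations

* The four thresholds are conventions, not calibrated error rates; the
  conjunction's false-positive behaviour depends on the background.
  Published signal tables occasionally mark terms whose own printed
  statistics fail these thresholds; this implementation applies the
  stated rules exactly and makes no such exceptions.
* "EBGM" without shrinkage overstates disproportionality for small `a`
  relative to the true MGPS; the n ≥ 3 and EBGM05 > 2 rules mitigate but
  do not remove this.
* The fixed-offset IC025 is a reproduction device; its coverage is not
  2.5% in any formal sense.
* Report-level deduplication cannot detect the same patient reported
  under different CASEIDs.
* The Weibull model ignores right-censoring: patients without an event
  never enter, so the fitted distribution describes reported onsets, not
  time-to-event risk.
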