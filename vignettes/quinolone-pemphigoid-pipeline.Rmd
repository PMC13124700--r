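---
title: "Disproportionality analysis of quinolone-associated pemphigoid: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis of quinolone-associated pemphigoid: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvdispro)
```

## The problem

Spontaneous reporting systems such as FAERS collect unsolicited reports of
suspected adverse drug reactions. They have no denominator of drug use, so
absolute risks cannot be estimated; what can be measured is
*disproportionality* — whether a drug–event pair is reported more often than
the rest of the database would predict under independence. This package
implements that analysis end to end for the pair studied here: systemic
quinolone antibiotics as primary-suspect drugs and pemphigoid, an autoimmune
subepidermal blistering disease of predominantly elderly patients, as the
target preferred term (PT).

Every stage is a tested, reusable function: generating FAERS-like data with
a *known* ground-truth association (so the whole chain can be validated),
reading and deduplicating quarterly files, standardizing drug names and
building approval-window cohorts, computing three disproportionality
statistics with their published signal criteria, profiling demographics,
binning time-to-onset, and checking concordance with a published case
series.

## The statistics

For each drug the deduplicated, approval-window-restricted database is
partitioned into the fourfold table

|                  | target event | other events |
|------------------|--------------|--------------|
| target drug (PS) | a            | b            |
| all other drugs  | c            | d            |

with `N = a+b+c+d`. The package computes, via `signal_stats()`:

* **ROR** (reporting odds ratio), the primary metric:
  `ROR = (a/b)/(c/d)` with
  `95% CI = exp(ln ROR ± 1.96 √(1/a + 1/b + 1/c + 1/d))`.
* **PRR** (proportional reporting ratio):
  `PRR = (a/(a+b))/(c/(c+d))`, companion interval
  `exp(ln PRR ± 1.96 √(1/a + 1/(a+b) + 1/c + 1/(c+d)))`, plus the 2×2
  chi-squared statistic.
* **BCPNN information component**:
  `IC = log2(aN / ((a+b)(a+c)))`, with the closed-form Bayesian posterior
  moments and `IC025 = E(IC) − 2√(V(IC))`.

Signal criteria, evaluated independently per metric
(`evaluate_signals()`): ROR — at least 3 cases and 95% lower bound above 1;
PRR — at least 3 cases, PRR ≥ 2 and chi-squared ≥ 4; BCPNN — IC025 strictly
above 0. A pair is flagged when *any* criterion is met. No multiplicity
adjustment is applied (none is conventional for this screening use); the
per-metric flags are reported side by side instead.

### Numerical conventions worth stating

* **The literal 1.96** is used in the interval formulas (not
  `qnorm(0.975)` ≈ 1.959964); the printed convention is the contract the
  hand-checked examples pin down.
* **PRR interval variance.** The default follows the companion formula
  above, whose middle terms enter with *plus* signs. Much of the
  disproportionality literature instead uses
  `1/a − 1/(a+b) + 1/c − 1/(c+d)` (the delta-method variance of ln PRR);
  that variant is available as `prr(ci = "conventional")`. The two differ
  noticeably only when `a` is a large share of `a+b`. The default was
  chosen to reproduce the printed formula exactly; the choice is surfaced
  as an explicit argument rather than hidden.
* **Chi-squared.** Yates-continuity-corrected Pearson statistic by default —
  the convention attached to the PRR ≥ 2 / χ² ≥ 4 rule — via the closed
  form `N(|ad−bc| − N/2)² / ((a+b)(c+d)(a+c)(b+d))`, with plain Pearson as
  an option. Note `stats::chisq.test(correct = TRUE)` caps the correction
  at zero deviation, so the two coincide only when `|ad−bc| ≥ N/2`; the
  test suite compares them exactly on that domain and compares the Pearson
  variant everywhere.
* **BCPNN priors.** The closed-form posterior uses the classical priors
  `α1 = β1 = 1`, `α = β = 2`, `γ11 = 1` with
  `γ = γ11 (N+α)(N+β) / ((a+b+α1)(a+c+β1))`, which make E(IC) shrink the
  point IC toward 0 for small `a` — visible in the worked example where
  `a = 3` gives IC = 1.56 but IC025 = −0.53. A Monte-Carlo posterior is
  deliberately not implemented; the closed form is the published standard
  matching the IC025 expression used.
* **Zero cells.** Default `correction = "none"`: a zero cell makes the
  affected statistic undefined and flagged, never an exception and never
  silently corrected. The Haldane–Anscombe +0.5 on all cells is opt-in,
  because it changes estimates and the analysed pair has `a ≥ 3`
  everywhere it matters.
* **Ties and boundaries are strict** where the criteria say so: IC025
  exactly 0 is not a signal; 2 cases with an enormous ROR is not a signal.

## Deduplication and cohort construction

FAERS cases accumulate follow-up versions under one CASEID.
`deduplicate_reports()` keeps, per case, the version with the largest
numeric PRIMARYID — the FDA-recommended retention rule — and is idempotent
and order-invariant (both property-tested). Deduplication runs on the whole
database before any event restriction, matching the order in which the
steps are usually described.

Drug names are standardized by case- and whitespace-insensitive exact
synonym lookup (`standardize_drug()`); the bundled dictionary carries the
five analysed quinolones (ciprofloxacin, levofloxacin, moxifloxacin,
norfloxacin, ofloxacin) with brand/salt synonyms and US approval dates,
plus three quinolones present but excluded (`include = FALSE`) the way an
analysis would exclude drugs with unreliable naming or no target-event
reports. Fuzzy matching is out of scope: unmapped names are returned as
`NA` and counted, not guessed.

A report enters drug D's cohort iff it lists D with role code PS (primary
suspect) and its receipt date falls within D's reporting window (on/after
approval). The window restricts the *whole* 2×2 universe for that drug,
comparator included, so each drug's analysis is a complete database
snapshot of its own era. The comparator is all other in-window reports not
listing D as PS — including reports whose PS is another quinolone. A report
listing several PS quinolones contributes to each drug's cohort but only
once within any one table. Reports with unparseable receipt dates cannot be
windowed and are excluded from the universe (they are counted in the parse
log; real quarterly files essentially always carry FDA_DT).

Event matching is exact, case-insensitive comparison against a configurable
PT list, default the single term "Pemphigoid". A licensed MedDRA hierarchy
is deliberately not consulted; the term list is a config file precisely
because the exact PT set behind any given analysis is an editorial choice.

Partial dates (4- or 6-digit) are treated as missing for day-level
arithmetic but still populate the report year — fabricating day precision
would silently bias latency. Ages are normalized to years (decades ×10,
months ÷12, days ÷365.25), weights to kg (lbs × 0.45359237).

## Descriptive profile and rounding

`profile_cohort()` tabulates drug, sex, age band (<18, 18–44, 45–64, ≥65),
weight band (<80, ≥80 kg), reporter occupation, region and outcome, with NS
(not specified) a first-class level everywhere — dropping missingness would
change every denominator. Percentages are `100·count/total` rounded
**half-up** to one decimal: the published tables this style of analysis
produces are half-up rounded (e.g. 42/183 = 22.95 → 23.0, where banker's
rounding would give 22.9). The ≥65 band is inclusive at 65. Time-to-onset
percentages use the same rule at two decimals.

## Time to onset

Latency is the day difference between event onset and the *earliest*
therapy-start date of the suspect drug in that report (first exposure
defines induction time; re-challenge episodes do not shorten it). Records
with missing or partial dates or negative differences are excluded and
counted, and the percentage denominator is the records with computable
latency — which is why a drug with 48 reports can have a 29-record onset
table. Bins are closed on integer days: [0,30], [31,60], [61,90], [91,359],
[360,∞). The explicit 91–359 bin makes the partition total so percentages
can sum to 100; "within one month" means ≤30 days and "after one year"
≥360 days. The cumulative curve is reported alongside and ends at 100.00.

## The synthetic spontaneous reporting system

`simulate_faers()` draws a database in which every downstream stage is
testable against known truth. Per case: independent exposure to each drug
with its background probability; one primary suspect (an exposed quinolone
with probability 0.85, else a background drug); the target event occurs
with probability `base_rate × rr_effective`, where `rr_effective` is the
configured relative risk when a configured drug is PS and 1 otherwise (an
optional sex modifier scales the *excess* risk, enabling sex-specific
simulated effects). At low base rates the ROR consistently estimates the
odds-ratio analogue of this rate ratio, which is what the calibration
suites verify.

Defaults were fixed once as the package's study conditions: 50,000 raw
report versions per replicate (a desk-scale database big enough for stable
cells yet fast enough for hundreds of replicates), base event reporting
rate 0.01, duplicate fraction 0.1 (extra versions share a CASEID, receive
strictly later receipt dates and larger PRIMARYIDs, and may carry stale
demographic fields — the last version is truth, matching the retention
rule), exposure probabilities 0.003–0.03 across the five quinolones,
log-normal latency with median 15 days and σ = 1 (≈76% of onsets within 30
days, reproducing the short-latency pattern of immune-mediated blistering
reactions), missingness mirroring what pemphigoid cohorts actually show
(weight ≈70% missing, event dates ≈40%, sex ≈13%, age ≈17%), and uniform
receipt years 2004–2024. The region field is an opaque categorical
dominated by an "Others" level, as the corresponding reporting field is in
practice. Each output table draws from its own RNG stream derived from the
master seed, so adding one table never perturbs another's draws; equal
seeds give byte-identical files.

What the generator does *not* emulate — and therefore what passing
calibration says nothing about: reporting trends over time, country-level
dynamics, correlated missingness, notoriety biases, duplicated cases that
*change* CASEID, and real MedDRA coding noise beyond letter-case variation
of the PT. Calibration against this generator validates the statistical
machinery, not the epidemiology of any real database.

Calibration results (computed by the acceptance suite, not quoted from
anywhere): under the null (relative risk 1) the ROR-signal rate over 200
replicates stays within the ≤5% band implied by the one-sided 2.5% criterion
plus Monte-Carlo slack; at relative risk 5 (expected `a` ≥ 50) the median
ROR over 100 replicates falls in [4, 6]; a female-only effect (excess risk
confined to female cases) is recovered by the sex-stratified analysis,
whose strata partition the universe and use stratum-restricted comparators.

## Literature concordance

`summarize_literature()` reduces a case-series table (drug, age, sex,
latency, hospitalization, outcome) to the dimensions on which spontaneous
data can be compared with published cases: combined share of the three
dominant quinolones, % aged ≥65, % under 45, % female, % hospitalized, and
median latency with range. `concordance()` pairs those against the same
summaries of the FAERS cohort and reports absolute differences,
flagging dimensions that differ by more than 25 percentage points —
a descriptive screen, not a test; no inferential procedure is attached
because none is standard for this comparison. Median for even-sized series
is the mean of the central pair (the bundled series has n = 9, so the
choice is documented rather than exercised). The packaged nine-case table
is a *synthetic* stand-in constructed to carry the marginal summaries of
the curated series (7/9 elderly, 5/9 female, 5/9 hospitalized, median
latency 18 days, range 4–30, cipro+levo+oflox 7/9); it is labelled
synthetic in its filename because it is not the underlying publications'
case-level data.

## Problem sizes and scope choices

The test and calibration suites run at 50,000 raw versions per replicate
with 200 null and 100 recovery replicates, and the property suites use
1,000 random 2×2 tables — sizes chosen so cells are stable (null `a` ≈ 10,
recovery `a` ≈ 55) while a full run stays comfortably on one CPU.
Headline estimates from the full multi-million-report FAERS corpus are
*not* reproducible at these sizes and are not targeted: the b/c/d cells of
the real analysis are unpublished, so the package instead reproduces
exactly every proportion computable from published counts and validates
the estimators by simulation.

Out of scope by design: literature retrieval itself, licensed MedDRA/WHO
Drug dictionaries (replaced by editable term/synonym tables), figure
aesthetics (plot-ready tables are emitted instead), EBGM/MGPS shrinkage
methods, and sequential signal detection.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config(n_reports = 20000,
                  relative_risk = c(CIPROFLOXACIN = 1, LEVOFLOXACIN = 1,
                                    MOXIFLOXACIN = 1, NORFLOXACIN = 1,
                                    OFLOXACIN = 5),
                  seed = 42)
dedup <- deduplicate_tables(normalize_tables(simulate_faers(cfg)))
sig <- signal_stats(contingency_tables(dedup, read_drug_dictionary()))
sig[, c("drug", "a", "ror", "ror_lo", "ror_hi", "ic025", "any_signal")]
```

Only the drug simulated with a five-fold reporting-rate ratio is flagged;
drugs with zero target-event reports come back undefined (`NA`) rather
than corrected, and small-count drugs show the wide intervals that motivate
the ≥3-case rule. `run_pipeline()` wires the same stages into one call with
a JSON manifest; `inst/scripts/pvdispro.R` exposes them as shell
subcommands.
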