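---
title: "Methods: disproportionality and time-to-onset analysis of spontaneous reports"
author: "pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality and time-to-onset analysis of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The data and the unit of analysis

Spontaneous reporting systems (SRS) such as Japan's JADER or the US
FAERS collect voluntary reports of suspected adverse drug reactions.
The JADER distribution is four linked CSV tables sharing a case
identification number: DEMO (demographics), DRUG (one row per drug
administration, with an involvement code distinguishing the *suspect*
drug from concomitant and interacting drugs, plus start/end dates),
REAC (one row per adverse event, coded as a MedDRA preferred term, with
onset date and outcome), and HIST (primary disease). `pvsignal` treats
preferred terms as opaque strings — no dictionary traversal — and
reads the tables through a *dialect* object that maps column headers,
involvement codes, outcome labels and the file encoding, because the
header vocabulary and label language vary between distributions.

All statistics are computed on the **pair table**: one row per distinct
(case, drug, preferred term) combination, by default restricted to
suspect-drug records. Two choices deserve justification:

* **Report unit, not patient unit.** The 2×2 cells count case–PT
  pairs, so the denominator for a drug is its total number of
  adverse-event *reports*. In published JADER analyses of this kind the
  "cases + non-cases" column is constant for a drug and equals the
  drug's reported-AE total, and the database-wide total is quoted as a
  count of reported AEs — both identify the report, not the patient,
  as the counting unit.
* **Deduplication.** A case that repeats the same term (or the same
  drug) several times still contributes at most one pair to a
  (drug, PT) cell, so a single chatty report cannot inflate a signal.
  When duplicates disagree, the pair keeps the earliest onset date and
  the worst outcome (death > with sequelae > not recovered > remission
  > recovered; "unclear" ranks lowest).

Rows in DRUG/REAC/HIST whose case id is absent from DEMO are collected
into an orphan report rather than dropped, so record counts always
reconcile.

### Partial dates

SRS dates come at day, month, year or no precision. The reader never
rejects a date: malformed components degrade the precision (an
impossible day keeps year-month; an impossible month keeps the year).
Usability is decided downstream — only the time-to-onset stage
requires day precision, mirroring the practice of excluding records
with missing administration or onset dates from onset analysis while
keeping them for disproportionality.

## Reporting odds ratio and the signal rule

For a target drug and term, the pair table partitions into the classic
2×2 table: `a` (drug, term), `b` (drug, other terms), `c` (other
drugs, term), `d` (the rest). The reporting odds ratio is

$$ROR = \frac{a\,d}{b\,c},\qquad
95\%\ CI = \exp\!\left(\ln ROR \pm z_{0.975}
\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\right)$$

the Woolf (log-normal) interval with $z_{0.975} = 1.959964$. A
**signal** is declared when the lower CI bound exceeds 1 *and* the term
has at least `minCases` (default 10) reports with the drug; rarer terms
are listed but marked `screened_out`. The published analysis this
package is validated against names no CI method; Woolf is the standard
choice for the ROR and reproduces the published magnitude pattern, which
is why it is the package's method and is documented as an assumption.

**Zero cells.** With the default Haldane–Anscombe policy, 0.5 is added
to *all four* cells before both the estimate and the interval whenever
any cell is zero. The ≥10-case screen makes `a = 0` impossible for
reportable rows; the policy matters mainly for sparse synthetic data.
An all-zero table is an error, not a number.

Display rounding is half-away-from-zero (`roundHalfUp()`), to two
decimals for rates and ROR/CI and one decimal for outcome percentages,
matching the conventions of published tables; internal values keep full
precision.

## Time to onset

For each pair with day-precision dates,

$$\text{days} = (\text{onset date} - \text{start date}) + 0.5$$

so a same-day onset counts half a day and the value is never zero.
When a case has several start dates for the drug, the start
substituted is the **earliest** day-precision start on or before the
onset; the phrase "first start date prior to onset" is genuinely
ambiguous between earliest-overall and most-recent-before-onset, so
the alternative is available via `startRule = "latest"` and the
default is documented rather than silent. Delays above `capDays`
(default 730, two years) are excluded, as are pairs with no usable
start or onset date; every exclusion carries a machine-readable reason
and observations + exclusions always equal the pairs examined.

### Weibull model

Onset days are fitted to the two-parameter Weibull distribution
$F(t) = 1 - \exp(-(t/\alpha)^\beta)$ by maximum likelihood on the
uncensored sample (only reports with an observed onset enter; there is
no censoring mechanism in an SRS onset analysis). The implementation
profiles the scale — for fixed $\beta$ the MLE of $\alpha$ is
$(\tfrac1n\sum t_i^\beta)^{1/\beta}$ in closed form — leaving a 1-D
search in $\log\beta$ over [log 0.05, log 50], solved with Brent's
method to tolerance $10^{-10}$. The bounds only bind for degenerate
samples (e.g. all values equal), where $\beta$ is reported at the
bound with no confidence interval. Confidence intervals elsewhere are
Wald intervals on $(\log\alpha, \log\beta)$ from the numerically
observed information, exponentiated, guaranteeing positive bounds.

The **failure type** summarises the hazard trend through the shape CI:

* `early_failure` — CI entirely below 1: hazard decreases; events
  cluster shortly after treatment start (e.g. acute gastrointestinal
  reactions);
* `wear_out` — CI entirely above 1: hazard increases with time on
  drug (e.g. cumulative haematological toxicity);
* `random` — CI straddles 1: no demonstrated trend.

Raw-day summaries (median, IQR) use type-7 quantiles (linear
interpolation between order statistics, R's default); the reference
analysis does not state a quantile rule, so the package uses R's.

Small-sample caveat: the Weibull MLE of $\beta$ is biased upward by
roughly 5–10% below about 30 observations and Wald coverage dips
accordingly; the package reports `n` with every fit so readers can
weigh this.

## Outcomes

Outcomes are tabulated per (drug, term) over the six substantive
categories; reports with no recorded outcome are excluded from the
denominator, which is why a term's outcome `n` can be smaller than its
signal case count. Percentages are `100·count/n`, half-up to one
decimal. When validating against the published outcome tables we found
12 of 156 printed cells inconsistent with their own printed count and
denominator (truncation rather than rounding, and a few slips — one
remission cell prints 3.5% where count/n gives 5.3%, and one row's
counts sum to n+1); the regression test freezes exactly that whitelist
and requires every other cell to reproduce bit-for-bit.

## The synthetic database generator

Real SRS downloads are large, encumbered and unversioned, so every
stage is validated against `generateSrs()`, which emulates the
schema's statistical structure with known ground truth:

* one suspect drug per case (multinomial), optional concomitant drugs
  (default rate 0.3) to exercise the involvement filter;
* per-term Bernoulli events; a *planted association* tilts the event
  probability for one (drug, term) pair. Because the off-event cells
  of the report-unit 2×2 table count other events, whose rates the
  tilt leaves untouched, the expected ROR equals the ratio of tilted to
  background probability, so the tilt is simply
  `targetRor × background` — exact in expectation, rejected as
  infeasible when it reaches 1;
* onset dates = start date + Weibull($\alpha$, $\beta$) delay rounded
  to whole days (real dates resolve to days), with per-association
  parameters for planted pairs and a scale-60/shape-1 background;
* multinomial outcomes (defaults roughly matching the mix seen in
  oncology SRS tables, including 10% missing), overridable per
  association;
* dates degraded at `missingDateRate` (default 5%): half to
  year-month precision, half removed, independently for start and
  onset — exercising the partial-date path;
* 10% of cases get a second, later start date (re-administration).

The generator is seeded and byte-deterministic, restores the caller's
RNG state, and emits a **ledger** with the realized 2×2 cells and
sample ROR of every planted association, against which the pair table
is checked cell-for-cell.

The default world — a target drug holding ~5% of reports, one 2%
background event and a tail of 0.1–1% events in 5,000–20,000 cases —
is chosen as a realistic small-world miniature of an SRS slice. What it
deliberately does **not** emulate: real JADER marginal frequencies,
MedDRA coding structure, report-revision/duplicate semantics, Japanese
text fields, or correlated co-reporting of related terms. Passing the
synthetic suite therefore demonstrates correctness of the statistical
machinery under the stated model, not robustness to every real-data
pathology.

## Validation summary and problem sizes

The test suite validates, among other properties: the Woolf formulas
against an independent log-space evaluation on 1,000 random tables to
12 significant digits; the Weibull MLE against a coarse grid-search
oracle (20 small samples) and against an independent MLE
implementation; shape-CI coverage over 500 simulations at n = 200
(observed within the nominal band); planted-ROR recovery and
single-signal detection over 200 seeds of 20,000-case databases; and
reproduction of the published signal counts (15 and 11), rate
arithmetic, outcome percentages and failure-type labels from the
transcribed reference tables. These problem sizes were chosen to give
stable statistical verdicts at interactive runtimes and are stated
here as the package's own simulation design.

## Known limitations

* No stratified or adjusted disproportionality (age/sex adjustment),
  and no alternative measures (PRR, IC, EBGM) — ROR only.
* No censoring or competing-risks machinery in the onset model.
* Case-level deduplication beyond unique case ids (report revisions)
  is out of scope.
* Wald intervals are asymptotic; for terms with very few onsets the
  reported CIs are approximate and the failure type defaults to
  `random` when no interval is available.
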