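---
title: "Methods: an EHR-wide association scan around new-onset atrial fibrillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an EHR-wide association scan around new-onset atrial fibrillation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrwas)
```

## The question and the design

Atrial fibrillation (AF) is the most common sustained cardiac arrhythmia.
Rather than testing a prespecified list of risk factors or complications,
an *EHR-wide* association scan asks, hypothesis-free, which coded clinical
conditions bring patients into contact with the health system more often
than their peers — separately **before** and **after** the first AF
diagnosis, and separately in **primary care** (GP consultations, Read-coded)
and **secondary care** (hospital admissions, ICD-10-coded primary
diagnoses). The output is four ranked lists of conditions, one per stratum,
plus a four-panel polar summary figure (the "iris plot").

The design implemented here is a matched case–control comparison embedded
in a registry cohort:

1. **Cohort.** Adults (≥ 18 at study entry) registered for at least one
   year, observed during the study period (defaults 1998-01-01 to
   2016-05-31), with no AF code before study entry. Study entry is the
   later of `reg_start + 1 year` and the study start.
2. **Cases.** The index date is the first AF-phenotype code inside the
   observation window. The shipped phenotype is ICD-10 `I48` (prefix match,
   so `I48.0`… qualify) plus seven terminal Read codes matched verbatim.
   One of the Read codes circulates both as `3272.00` and with a spurious
   thousands separator as `3,272.00`; the shipped list carries both
   spellings.
3. **Controls.** Incidence-density (risk-set) matching: for each case, in
   ascending index-date order, one control (configurable ratio) is sampled
   uniformly from eligible patients of the same sex and birth year
   (tolerance configurable, default 0) who are under observation and
   AF-free **at the case's index date**. A control may become a case later
   — excluding future cases would condition on the future — but no person
   serves as a control twice. Cases with an empty risk set are dropped and
   logged.
4. **Counting.** For each stratum (setting × pre/post) and condition code,
   the statistic is the *patient-level* occurrence: the share of case
   patients with ≥ 1 qualifying in-window event versus the same share in
   controls. Windows are half-open five-year spans that exclude the index
   day itself: pre keeps `index − W ≤ t < index`, post keeps
   `index < t ≤ index + W`. The AF phenotype codes are excluded from the
   scanned stream (they define the index; counting them would be
   circular).
5. **Ranking.** The frequency ratio per condition is
   $\mathrm{FR} = \frac{\%\,\text{cases with the condition}}{\%\,\text{controls with the condition}},$
   and each stratum reports the leading `top_n` (default 100) conditions by
   descending ratio.
6. **Uncertainty.** Percentile confidence intervals from a *balanced*
   bootstrap over matched pairs (default B = 2,000).
7. **Grouping and display.** Every reported condition is assigned to one of
   fourteen disease groups, and the four ranked lists are drawn as polar
   bar panels with group-coloured sectors arranged clockwise.

## Interpretation choices that were genuinely open

**Patient-level versus visit-level frequency.** "Most frequent reasons for
visits" can be read as counting patients or counting visits. The default
counts each patient at most once per condition and stratum: it is robust to
a single heavy utiliser and matches the usual epidemiological estimand (a
risk ratio of condition occurrence). A visit-count mode is available via
`study_config(count_mode = "visits")` for sensitivity analyses.

**Risk-set matching.** Published matched designs on incident disease
overwhelmingly evaluate control eligibility at the case's index date; with
only "age and sex matched" to go on, that convention is adopted, with exact
birth-year matching by default (the near-identical case/control mean ages
reported for such designs imply tight matching). Matching is without
replacement, processed in index-date order from a single seeded stream, so
results are reproducible and invariant to input storage order.

**Index-day exclusion.** Events on the index day are in neither window:
diagnostic work-up on the day of the first AF code would otherwise
contaminate both directions.

**Zero-control cells.** With `n_control = 0` the ratio is undefined; a
continuity correction `c` (default 0.5) is added to both counts, giving
`(n_case + c)/c`, and the row is flagged (`zero_control_flag`) so readers
can discount those entries. `n_case = 0` rows never reach the ratio: codes
below `min_case_patients` (default 5, the usual small-cell disclosure
convention for UK EHR outputs) are dropped first.

**No multiple-testing adjustment.** The scan ranks by effect magnitude and
reports bootstrap uncertainty; it is a hypothesis-generating screen, not a
testing procedure.

## The balanced bootstrap

The resampling unit is the matched pair, which preserves the matched
design. A *balanced* plan is built by concatenating $B$ copies of the pair
indices $\{1,\dots,n\}$, applying one seeded uniform permutation, and
cutting the result into $B$ consecutive blocks of size $n$; every pair
therefore appears exactly $B$ times across the plan, removing first-order
Monte-Carlo imbalance. Each replicate recomputes `n_case`, `n_control` and
the ratio on its multiset of pairs (a pair drawn $k$ times contributes $k$
times), with the same continuity rule for empty cells. The interval is the
percentile interval at $(1-\gamma)/2$ and $1-(1-\gamma)/2$; endpoints are
order statistics of the replicate set (`quantile(type = 1)`), so widening
the confidence level can only widen the interval. Percentile rather than
BCa intervals: the simplest method consistent with reporting "bootstrap
distributions", and the machinery accepts a pre-built plan should another
flavour be wanted.

```{r}
plan <- balanced_plan(n_pairs = 3, B = 4, seed = 1)
table(plan)   # every pair index appears exactly B = 4 times
```

## The fourteen disease groups

Classification is total and deterministic: per-code overrides are checked
first, then ICD-10 chapter/block ranges on the 3-character category
(`C00–D48` cancer, `I63–I69` cerebrovascular, `I05–I52` cardiac except the
overridden codes, `I60–I62` haemorrhages, and so on), and anything left
maps to *other* with a summarising warning. The overrides pin down the
manual judgements visible in the curated reference lists shipped with the
package — e.g. `I89.0` lymphoedema under peripheral/other vascular,
`I85.9` oesophageal varices under gastrointestinal, infective endocarditis
(`I33.0`, `I38`) under infection, `K85.9` acute pancreatitis under
infection — which the fixtures preserve verbatim rather than "correcting".
One genuine conflict exists in the source tables: `I31.9` (pericardial
disease, unspecified) appears under peripheral/other vascular in the
pre-index hospital list but under cardiac in the post-index list. The
scheme follows the pre-index placement; the other entry is enumerated in
`fixture_exceptions()`, and the scheme reproduces 199 of the 200 coded
entries (99.5%). Primary-care entries circulate as free-text Read terms
without codes; they classify through an explicit term table derived from
the same lists. Cardiac codes additionally carry a subcategory
(arrhythmia, heart failure, valve, cardiomyopathy, ischaemic, other) via
`cardiac_subcategory()`.

## The iris plot

Clock positions drive the sector **order** (12 h = 0°, clockwise:
bleeding, cancer, cardiac, cerebrovascular, endocrine & frailty,
gastrointestinal, haematological & infection, osteoarticular & other,
peripheral vascular, renal, respiratory), and sector **widths** are
proportional to each group's bar count so that all reported conditions fit
without overlap; groups sharing a clock hour follow the legend order. Bars
within a sector are sorted by descending ratio, and each panel is scaled to
its own maximum ratio (annotated on the figure) because the four strata
span very different ranges. The radial axis is linear. The SVG is written
directly by the package as plain markup — legend labels and scale
annotations are real `<text>` nodes, and repeated renders of the same
input are byte-identical — while the PNG is drawn with base graphics.

## The synthetic EHR generator

Real UK primary/secondary-care linkages cannot be redistributed, so every
stage is tested against a generator with known ground truth:

* registrants with Bernoulli sex, uniform birth years, and registration
  intervals that always overlap the study period (an interval ending
  earlier is shifted forward);
* AF onset as the first event of a constant-hazard process over each
  patient's registered, in-study, adult time — an onset beyond that
  interval means the patient never becomes a case;
* for each (patient, code), an independent homogeneous Poisson stream at
  the code's base rate; for cases, the rate is multiplied by a planted
  `pre_ratio` on `[onset − W, onset)` and `post_ratio` on
  `(onset, onset + W]`; one `I48` secondary event marks the onset itself.

Because planted effects are *rate* multipliers while the scan counts
*patients*, the generator exposes the analytically implied patient-level
target: with base rate $\lambda$, window $W$ and multiplier $r$,
$$\mathrm{FR}_{\text{implied}} = \frac{1 - e^{-r\lambda W}}{1 - e^{-\lambda W}}.$$

What the generator deliberately does **not** emulate: correlated
multimorbidity (streams are independent across codes), calibration to real
incidence or code prevalences, and differential mortality between cases
and controls (competing risk is out of scope for the scan itself, so the
generator applies at most a shared mortality hazard). Passing tests
therefore demonstrate the correctness of the pipeline's counting,
matching, ranking and uncertainty machinery under a known model — not that
real EHR data meet that model.

## Simulation studies and their sizes

The packaged tests run four study-scale simulations, sized to finish in
seconds to a couple of minutes on one CPU while leaving comfortable
statistical margins:

* **Ranking contract** — 4,000 patients, 160 primary + 160 secondary
  codes at base rate 0.06/patient-year, AF hazard 0.02/year: every
  stratum has well over the 100-condition reporting cap, and each ranked
  table must contain exactly 100 rows in descending ratio order.
* **Null calibration** — 3,400 patients, 110 secondary codes at base rate
  0.2, no planted effects, 500 matched pairs, B = 2,000: the sign test on
  log ratios must not reject a zero centre (p > 0.01) and the share of
  95% CIs excluding 1 must lie in [0.01, 0.12].
* **Parameter recovery** — one code at base rate 0.05 with a planted
  fourfold pre-window ratio, 6,500 patients at AF hazard 0.005/year,
  500 pairs, 50 replicate cohorts: the implied patient-level ratio
  (≈ 2.86) must fall inside the 95% CI in at least 90% of runs.
* **Oracle equivalence** — ≤ 20-pair fixtures where counting, windowing,
  matching and bootstrap intervals must equal independent brute-force
  recomputations exactly.

The recovery study's hazard is deliberately low. Under risk-set matching a
control can become a case shortly after its index date, and its own
elevated pre-onset stream then overlaps the scanned control window; the
analytic target above assumes base-rate control streams. At a 1.4%/year
hazard about 7% of controls are affected and the control percentage is
inflated by roughly 6% — a real feature of incidence-density sampling, not
an estimator defect — which is material against a CI half-width of ~0.18
on the log scale. At 0.5%/year the contamination (~2.5% of controls)
is negligible and the oracle is valid.

## Numerical conventions

* Dates are whole calendar days (`Date`); files use ISO-8601. A span of
  $y$ years is `round(365.25 * y)` days, so the five-year window is 1,826
  days.
* ICD-10 codes are normalized to the dotted dialect (`I635` → `I63.5`);
  Read codes are kept verbatim, dots included, and AF Read matching is
  exact-string (the phenotype lists terminal 7-character codes), while AF
  ICD-10 matching is prefix-based.
* Ranking uses the deterministic total order: descending ratio, then
  descending case percentage, then ascending code string.
* All randomness (generator, matching, bootstrap) derives from one
  configured seed through fixed per-stage offsets; reruns are
  bit-identical, and inputs are canonically sorted so storage order never
  matters.

## Known limitations

* No competing-risk handling: differential mortality after AF can
  suppress post-window counts in cases.
* Read-coded conditions classify into disease groups only through the
  term table; novel Read codes fall into *other*.
* The continuity-corrected ratio for zero-control cells is a convention;
  such rows are flagged and should be read qualitatively.
* Percentile intervals can undercover for very rare conditions near the
  `min_case_patients` threshold.
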