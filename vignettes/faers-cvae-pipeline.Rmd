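---
title: "Methods: disproportionality analysis of FAERS-style spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality analysis of FAERS-style spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

This vignette is the package's account of its statistics: what each stage
assumes, which knobs matter, what the synthetic generator does and does not
emulate, and where the design was genuinely open.

## The case/non-case model

Spontaneous-report databases have no denominators: we never observe how many
patients took a drug, only how many adverse-event reports mention it.
Disproportionality analysis sidesteps this by comparing *reporting* odds. For
one preferred term (PT) the reports are cross-classified as

|              | PT reported | PT not reported |
|--------------|------------:|----------------:|
| target drug  | a           | b               |
| other drugs  | c           | d               |

and the reporting odds ratio is $ROR = ad/bc$ with Wald interval
$\exp(\ln ROR \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$. The package flags a PT as a
signal when $a \ge 3$ and the lower 95% limit exceeds 1. The estimate is
meaningful only as *relative reporting*, not incidence; with small cells the
log-normal approximation is rough, which is exactly why the count threshold
exists. Event presence is binary per report: a report listing the same PT
twice counts once.

Assumptions worth stating explicitly:

* reports are independent across CASEIDs once deduplicated (versioned
  duplicates would otherwise inflate cells);
* the comparator — all reports not naming the target drug — is an acceptable
  proxy for background reporting of the PT. A target-drug report that falls
  outside the analysis cohort (e.g. an adult patient) is still *not* a
  non-case: leaving such reports in the comparator contaminates the
  background with drug-associated reporting and biases the ROR toward the
  null, which is measurable in simulation. `comparator_reports()` therefore
  excludes all target reports, with `scope = "pediatric"` available to
  age-restrict the background as a sensitivity analysis (the default is the
  unrestricted background);
* the cells are large enough for the Wald interval; with any zero cell the
  estimate is reported as undefined unless the Haldane–Anscombe +0.5
  correction is explicitly enabled (`zero_correction = TRUE`, flagged in the
  output). The correction is off by default because the signal rule already
  requires $a \ge 3$, so correction could only manufacture estimates for
  terms that cannot be signals anyway.

## Deduplication and deletion

One case accumulates report versions; the retained version per CASEID is the
one with the highest FDA_DT (receipt date), ties broken by the highest
PRIMARYID. Deletion lists are applied *after* deduplication, in that order,
because a deletion targets the case as a whole. Rows with unparseable CASEID
or PRIMARYID are excluded and counted; a row with an unparseable FDA_DT is
kept but treated as FDA_DT 0 so it loses every tie — preferring to retain
*some* version of a case over dropping it. The operation is idempotent,
order-independent, and verified in the test suite against a brute-force
group/sort/take-last reference on randomized inputs.

## Cohort and covariates

* **Ages** arrive as value plus unit code and are converted to years
  (decades ×10, months ÷12, weeks ÷52.1775, days ÷365.25, hours ÷8766).
  A missing or unknown unit yields a missing age — no guessing.
* **Pediatric** means strictly `age_years < 18`; missing ages are excluded
  from the cohort. This is conservative and reproducible; imputing ages from
  other fields would silently move reports across the boundary.
* **Target identification** is case-insensitive substring matching of a
  synonym list (default: the tisagenlecleucel product under its generic,
  brand and development names) against DRUGNAME and PROD_AI, over *all* drug
  role codes by default. The FAERS role code does not reliably distinguish
  suspect from concomitant for cell-therapy products; a `roles =` switch
  restricts to PS/SS when wanted.
* **CVAE** means any PT whose system organ class is *Cardiac disorders* or
  *Vascular disorders* under the supplied PT→SOC table (a MedDRA surrogate;
  the licensed dictionary itself is deliberately not bundled). PTs missing
  from the table are counted and treated as non-cardiovascular.
* **CRS** is detected by exact, case-insensitive PT match on
  *Cytokine release syndrome* — a single PT, not an organ-class rollup.
* **Fatality** is outcome code `DE` at report level.
* **Co-medication classes** are ATC level-1 letters of non-target drug rows,
  via a drugname→class table; unmapped non-target drugs pool into an
  `other` class. The target drug itself never contributes a flag — its own
  antineoplastic class would be constant 1 in the cohort and unidentifiable.

Summary tables use counts with percentages against the column total
(missing categories included) and median (Q1, Q3) ages.

## Time to onset

Onset is the event date (DEMO.EVENT_DT) minus the earliest therapy start of
the target drug (THER.START_DT joined through DSG_DRUG_SEQ). Both dates must
be full `YYYYMMDD`; partial dates are excluded and tallied rather than
imputed to mid-month, because the quantities of interest are day-scale
medians and mid-month imputation would fabricate them. Negative differences
(event before therapy) are excluded the same way. Summaries are
linear-interpolation (type 7) quantiles — R's default, documented here
because SAS's default quantile rule differs and can shift a quartile by a
day on small groups. Group contrasts use the Wilcoxon rank-sum test: exact
when $n_x+n_y \le 20$ with no ties, otherwise a normal approximation with
tie-corrected variance and 0.5 continuity correction. The test suite sweeps
every tie-free configuration at $n = 8\ldots10$: the corrected approximation
stays within 0.05 of exact enumeration (its worst deviation is ≈0.04 in the
mid-range, so the approximation is adequate for screening, not for
borderline inference at tiny n — there the exact branch applies anyway).

## Categorical tests

`assoc_test()` implements the reporting convention literally: if any
expected cell count is below 5 the table goes to Fisher's exact test
(two-sided, sum of hypergeometric probabilities at most that of the observed
table), otherwise to Pearson's chi-square without continuity correction
(a `yates` flag exists, off by default because the uncorrected statistic is
what the convention names).

## Two-stage risk-factor analysis

Candidate variables — age (continuous), sex (male = 1) and the ATC class
indicators — are screened one at a time in univariate logistic regressions;
variables with Wald $p < 0.05$ enter one multivariate logistic model. Fits
are maximum likelihood via IRLS (`stats::glm`, coefficient tolerance
$10^{-8}$, at most 100 iterations; verified in tests against an
independently written IRLS to $10^{-6}$). Each row reports Wald $\chi^2 =
(\beta/SE)^2$, $OR = e^\beta$ and $e^{\beta \pm 1.96\,SE}$. For the
fatal-within-CVAE outcome the design is restricted to CVAE reports, the
cardiovascular co-medication class is excluded (death among cardiovascular
events would otherwise be conditioned on its own treatment), and the age
screen additionally reports the two-sample *t* statistic, since routine
pharmacovigilance reports mix the two conventions for continuous covariates;
the multivariate stage always uses the logistic slope. Missing age or sex is
handled listwise. No multiplicity correction is applied across the screened
variables — deliberately, matching field practice — and the simulation suite
quantifies the induced false-selection rate (≈5% per null variable) instead
of pretending it away. Complete or quasi-separation is flagged
(boundary fitted probabilities, non-convergence, or runaway coefficients)
and coefficients are reported at the last iterate rather than suppressed.

## The synthetic generator

`generate_reports()` draws independent reports and emits them in the exact
quarterly ASCII dialect the ingest layer reads, so tests exercise the true
file path. Per report: target drug with probability `target_share`;
pediatric age with probability `pediatric_share`; each catalog PT as a
Bernoulli draw whose odds are multiplied by the injected ROR on target
reports; a guaranteed anchor reaction (no report is reaction-free); CRS
co-reported at configurable conditional rates; onset days log-normal by
cardiovascular status, with therapy-start, event and receipt dates derived
consistently; death from a logistic model over age, cardiovascular status
and co-medication flags; a fraction of reports re-emitted as later versions
(same CASEID, later FDA_DT, higher PRIMARYID); and a deletion list. The
ground-truth object records the injected parameters, the superseded
PRIMARYIDs a correct dedup must remove, and the deleted CASEIDs.

Defaults (the package's own choices, stated once): 20,000 reports,
`target_share` 0.03, `pediatric_share` 0.5, background PT rates 0.1–6%
(cardiovascular terms at the low end), injected ROR 30 on hypotension,
`crs_given_cvae` 0.9, onset medians 3 days (CVAE) vs 7 days (non-CVAE) with
log-scale SDs 1.0/1.2, fatality intercept −0.4 with age log-OR −0.094 per
year (OR 0.91) and a respiratory-class log-OR of log 1.82, duplicate rate
10%, deletion rate 2%, partial-date rate 10%. These give a pediatric
target cohort a few hundred strong in which roughly a third of reports are
cardiovascular and about 30% of those are fatal — the regime the analysis
is designed for.

What the generator does **not** emulate: reporting dynamics over time
(stimulated reporting, the Weber effect), correlated PT co-occurrence beyond
the CRS linkage, drug–drug interaction structure, free-text drug-name noise
beyond case differences, or duplicated patients under *different* CASEIDs
(probabilistic record linkage is out of scope). Passing tests therefore
demonstrate correctness of the estimators and plumbing under a clean
data-generating process, not robustness to every pathology of real FAERS
data.

`fixture_quarter()` is different in kind: a fully deterministic bundle whose
pediatric target cohort has fixed marginals (568 reports; 187 CVAE of which
57 fatal; 434 US; 310 physician-reported; per-PT blocks for hypotension,
tachycardia, shock and cardiac arrest with fixed CRS-overlap and mortality
counts; onset patterns with medians 3 vs 7 days). It exists so worked
examples and percentage checks are exact, not stochastic; a generator-drawn
background of non-target reports (fixed internal seed) supplies the
non-cases.

## Numerical conventions and degenerate inputs

* All table values stay strings through ingest; typing happens where the
  analysis needs it, so dirty fields degrade to counted exclusions instead
  of parse failures.
* `read_faers_table()` skips and counts malformed lines; it never throws on
  data rows. Orphan child rows (PRIMARYID absent from DEMO) are dropped with
  a logged count.
* z is fixed at 1.96 throughout: every interval the pipeline reports is a
  95% interval, so the quantile is not a parameter.
* Empty cohorts, constant outcomes, constant covariates, zero-margin tables
  and empty onset vectors all produce explicit warnings/errors or flagged
  rows, never silent NaNs.
* Pipeline CSVs round floats to 4 decimals; JSON keeps full precision.
  Reruns on identical inputs are byte-identical (no timestamps).

## Problem sizes in the test suite

The simulation-backed checks run at: 1,000 null datasets of 2,000 reports
(signal-rule calibration), 100 datasets of 50,000 reports (injected-ROR
recovery), 1,000 randomized dedup inputs of up to 200 rows, the complete
enumeration sweeps for Fisher (margins ≤ 12) and the rank-sum test
(n ≤ 10), and 200 logistic fits at n = 5,000. These sizes make the Monte
Carlo error small relative to every asserted bound while keeping the suite
comfortably runnable on one CPU.

## Limitations

Disproportionality cannot estimate incidence or establish causality;
signals are hypotheses. The report is the counting unit — a patient proxy,
not a patient. Comorbidity enters only through co-medication classes, so
confounding by indication is unaddressed and unaddressable with these
fields. The PT→SOC and drugname→ATC tables are user-supplied surrogates;
the bundled defaults cover the terms and drugs used in examples and tests,
not the full dictionaries.
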