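---
title: "Methodology: indicators, formulas and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methodology: indicators, formulas and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dqscreen)
```

This vignette documents the statistical and structural methods behind each
check in `dqscreen`, and records the design decisions the package makes
where several defensible choices exist.

## 1. The indicator model

Data quality is assessed along four dimensions, in a fixed order, because
later checks are only meaningful once earlier ones pass:

* **Integrity** — structural and technical compliance of the data set.
* **Completeness** — presence of expected data values.
* **Consistency** — admissibility of observed values.
* **Accuracy** — distributional and associational plausibility.

`dq_registry()` enumerates 34 indicators, identified as `DQI-<dddd>` where
the first digit encodes the dimension (1 integrity, 2 completeness,
3 consistency, 4 accuracy). 27 are computed by checks in this package; the
remaining 7 (`DQI-3004`, `DQI-3005`, `DQI-4007`–`DQI-4009`, `DQI-4011`,
`DQI-4012`) are registered with `implemented = FALSE` so that result files
from complementary tools can be merged under one vocabulary.

Every check returns a `dq_result`: a tibble with one row per
(indicator, variable) pair, carrying `n_flagged`, `denominator`, `percent`,
a binary `grading` (`ok`/`issue`), and a list-column of flagged cell
coordinates (`record_id`, `variable`). Descriptive procedures that do not
flag cells (distribution summaries, LOESS trends) are returned as
*descriptors* and kept separate from indicator results in exports.

### Applicability gating

`dq_report()` first computes an applicability matrix from the metadata:
each (check, variable) pair is `applicable`, `no-metadata` (the needed
metadata attribute is absent), `no-data` (the variable is not in the study
table), or `type-mismatch` (the observed column type contradicts
`DATA_TYPE`). Downstream checks only run on `applicable` cells; a numeric
range check is never attempted on a column that failed the type check.
This gating is itself reported, so silence is always distinguishable from
"checked and clean".

## 2. Metadata vocabulary and interval grammar

Checks are configured by one flat table with one row per variable
(`read_dq_metadata()` validates it):

* `VAR_NAMES`, `LABEL`, `DATA_TYPE` ∈ {`integer`, `float`, `string`,
  `datetime`}.
* `HARD_LIMITS`, `SOFT_LIMITS`, `DETECTION_LIMITS`: interval literals.
* `VALUE_LABELS`: admissible categories as `"code = label | …"`.
* `MISSING_LIST`, `JUMP_LIST`: qualified missing / jump codes (≥ 99900 by
  convention) as `"code = reason | …"`.
* `STUDY_SEGMENT`: the examination block a variable belongs to.
* `KEY_OBSERVER`, `KEY_DATETIME`: names of the process variables (examiner
  id, examination date-time) attached to a measurement.
* Optional `ROLE` (otherwise inferred: identifier / process-examiner /
  process-time / measurement) and `SOURCE_TABLE` for multi-table studies.

Interval literals follow the grammar

```
interval := ("[" | "(") lower ";" upper ("]" | ")")
```

where `[`/`]` are closed and `(`/`)` open endpoints, `lower`/`upper` are
numbers (including `-Inf`/`Inf`) or strict ISO-8601 date-times. Date-time
parsing is round-trip validated, so an impossible calendar date such as
`2001-02-30` is rejected rather than silently rolled over.

Qualified codes are semantically prior to limits: a value equal to a
declared missing or jump code is *never* a limit violation, an
inadmissible category, or an outlier — it is a coded absence.

## 3. Completeness: staged missingness

Missingness is decomposed into stages that mirror how field work loses
data, and each stage's denominator excludes units already lost at an
earlier stage:

1. **Unit missingness** (`DQI-2001`, unit level): units on the expected
   roster with no usable study record (all measurement variables
   system-missing, or the whole unit refused). Denominator: all expected
   units.
2. **Segment missingness**: units that entered the study but have an
   entire examination segment system-missing. Denominator: units not
   unit-missing.
3. **Item missingness**: individual absent values among units that entered
   the segment. Denominator: units not lost at stages 1–2.

For each variable, item missingness is split into system missingness
(`NA`, `DQI-2005` / crude `DQI-2001`) and per-code qualified missingness
(`DQI-1008` reports usage of undeclared vs declared codes). The
conservation identity

```
n_observed + n_system_missing + Σ_codes n_code + Σ_jumps n_jump = n_expected
```

holds for every variable and is enforced in the test suite.

Qualified rates combine stages with code semantics:

* `DQI-2002` (nonresponse): roster units that never produced data plus
  unit-level system missingness.
* `DQI-2003` (refusal): unit-level refusal codes.
* `DQI-2004` (drop-out): units whose missing segments form a *suffix* of
  the declared `segment_order` — intermittent segment missingness is not
  drop-out.

**Decision:** staged (conditional) denominators are used for qualified
rates, rather than dividing everything by the roster size, because the
stages answer different operational questions (recruitment vs retention vs
instrument performance). Crude per-variable rates over all expected units
are still reported under `DQI-2001`.

## 4. Consistency

### Limit deviations

For numeric and date-time variables, observed (non-coded) values are
tested against `HARD_LIMITS` (`DQI-3001`, values outside the technically
possible range), `SOFT_LIMITS` (`DQI-3006`, values outside the plausible
range but inside the hard range), and `DETECTION_LIMITS` (`DQI-3007`,
values at or beyond instrument censoring bounds). Date-time limits use the
same interval grammar (`DQI-3002`). `DQI-3003` flags inadmissible
categorical values, i.e. observed levels absent from both `VALUE_LABELS`
and the declared code lists.

### The contradiction predicate catalog

Two-variable contradiction rules are built from a 16-member predicate
catalog: the outer product of four *side types* on each side,

* `set` — membership in an enumerated value set (`"1|2"`),
* `range` — membership in an interval (`"[2;16)"`),
* `trange` — membership in a date-time interval,
* `miss` — the cell is empty (system-missing or qualified-coded),

giving predicates `set_set`, `set_range`, …, `miss_miss`. A rule fires for
a record when both sides hold. Cells carrying qualified missing or jump
codes never satisfy a value-comparison side (`set`, `range`, `trange`);
they only satisfy `miss`. Each rule carries a class: `logical`
(impossible by definition, `DQI-3008`) or `empirical` (implausible,
`DQI-3009`). The test suite validates all 16 predicates against a
brute-force truth-table oracle over enumerated domains.

## 5. Accuracy

### Univariate outlier fences

Four fence rules are implemented; values are screened after removing
qualified codes and hard-limit violations (a measurement error is not an
"outlier"):

* **tukey**: `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` with type-7 quantiles.
* **sixsigma**: `mean ± 3·sd`.
* **mad**: `median ± 3·MAD`, with the 1.4826 consistency constant.
* **hubert**: medcouple-tilted fences for skewed data,
  `[Q1 − 1.5·e^{−4·MC}·IQR, Q3 + 1.5·e^{3·MC}·IQR]` for medcouple
  `MC ≥ 0`, and with exponents `(−3, 4)` for `MC < 0`.

The medcouple is computed exactly in O(n²): with `z_i = x_i − median(x)`,

```
MC = median over pairs (i, j), z_i ≥ 0 ≥ z_j, of h(z_i, z_j)
h(z_i, z_j) = (z_i + z_j) / (z_i − z_j)
```

with the special tie kernel for `z_i = z_j = 0`: ordering the tied zeros,
`h = −1` below the anti-diagonal, `0` on it, `+1` above. For an exactly
mirror-symmetric sample the kernel values pair into exact negations and
`MC = 0`, so hubert fences coincide with Tukey fences — a property the
test suite exercises. `DQI-4001` counts per-rule flags; `DQI-4002` adds a
multivariate screen via Mahalanobis distance against a
`qchisq(0.999, p)` cutoff.

**Decision:** the MAD rule is included as a fourth fence alongside the
classical three because it is the most robust simple rule for heavy-tailed
but symmetric data; results report each rule separately rather than a
vote, so the analyst sees where the rules disagree.

### Distributional checks

`DQI-4004` (shape or scale): a parametric family is fitted by method of
moments, the support is cut into 10 equal-probability bins under the
fitted model, and a χ² statistic with `df = 10 − 1 − #estimated
parameters` is computed; a hanging rootogram descriptor accompanies the
test. `DQI-4005` (end-digit preference): the terminal digit at a declared
decimal position is extracted exactly via
`floor(|x|·10^dec + 0.5) %% 10` and tested against uniformity (χ²,
`df = 9`).

### Examiner effects and variance components

`DQI-4003` (continuous) / `DQI-4006` (binary): the measurement is modelled
by `lm()` or `glm()` (family chosen from the response type) on the
examiner class plus user-supplied covariates; `emmeans::emmeans()`
produces covariate-adjusted marginal means per class, and a class is
flagged when its 95 % confidence interval excludes the `n`-weighted
overall adjusted mean. Classes below a minimum size are dropped from the
comparison, not silently pooled.

Covariates are cleaned with the same code semantics as responses: a
qualified missing code in a covariate enters the model as `NA`, never as
its numeric code value.

`DQI-4010` (variance components): a random-intercept model
(`lme4::lmer(y ~ 1 + (1 | class))`) yields the intra-class correlation
`ICC = σ²_b / (σ²_b + σ²_w)`; the check flags when `ICC > 0.05`, i.e.
when more than 5 % of measurement variance is attributable to who (or
what) performed the measurement.

**Decision:** marginal-means flagging uses per-class decisions against the
weighted grand mean rather than an omnibus F-test, because the output must
name *which* examiner drifts, and the per-class decision rate under the
null is what the simulation suite controls.

### Time trends

LOESS (span 0.75, degree 2) of the measurement against the examination
date-time, evaluated on a 100-point grid per examiner class, is reported
as a descriptor with the observed drift range — a visualization aid, not a
hypothesis test.

## 6. The synthetic-study generator

`dq_simulate_study()` draws a synthetic examination survey (default
`n = 2154` units, 13 variables in segments `INTERVIEW`, `SOMATOMETRY`,
`BLOOD_PRESSURE`) and then injects defects, recording every altered cell
in a ground-truth ledger with columns `record_id`, `var_name`,
`defect_type`, `true_value` (the pre-injection value).

Design properties that make the ledger a usable oracle:

* **Sub-seeded streams.** Every defect family draws from its own seed
  derived as `(seed·1009 + offset·9973) mod (2³¹ − 1)`, so changing one
  injection rate does not reshuffle any other stream.
* **No leakage.** Cells not named in the ledger are byte-identical to the
  clean draw; contradiction injection overwrites two cells and logs both.
* **Eligibility tracking.** A `touched` matrix prevents two defect types
  from landing on the same cell, so each ledger row maps to exactly one
  observable symptom.
* **Stage guards.** Item-level injection never deletes the last remaining
  value of a segment, so unit, segment and item missingness remain
  distinguishable in the output exactly as planted.

The roster includes a small rate of expected-but-absent units, and one
variable (`contraceptives`) is routed by a jump code for male
participants — a realistic questionnaire skip that shows up in crude
missingness even on defect-free data.

`dq_write_simulation()` / `read_dq_metadata()` round-trip the bundle
(study, metadata, rules, roster, ledger) through CSV.

## 7. Reporting and reproducibility

`dq_report()` runs the full battery with gating and returns an object with
`tidy()` (one row per indicator result) and `glance()` (totals) methods
and `autoplot()` visualizations. Exports:

* `dq_export_json()` — schema-versioned (`"1.0"`) JSON with indicator
  results, descriptors, flagged cells and the configuration; given a fixed
  timestamp in the config, the export is byte-deterministic.
* `dq_render_report()` — a static HTML page plus per-dimension CSVs,
  byte-stable across runs.
* `annotate_flags()` — writes `<var>_dq` columns containing the firing
  indicator ids next to each flagged cell.

A configuration hash (rolling polynomial hash over the canonicalized
configuration, timestamp excluded) is embedded in every export so that two
result files can be checked for comparable provenance.
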