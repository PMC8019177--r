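# dqscreen

Metadata-driven data quality assessment for observational health studies.

`dqscreen` computes data quality indicators on tabular study data (one row
per observational unit), driven entirely by an item-level metadata table.
It distinguishes four dimensions of data quality, assessed in order:

1. **Integrity** — does the data set comply with structural and technical
   requirements? Unexpected data elements and records, duplicates,
   record/element mismatches across tables, data type mismatches,
   inhomogeneous value formats, uncertain missingness status.
2. **Completeness** — are expected data values present? Missingness is
   staged the way data collection loses it: unit nonentry, segment
   (examination-block) nonparticipation, then item missingness; crude
   counts are complemented by qualified rates (nonresponse, refusal,
   drop-out, missing due to specified reasons) that use declared missing
   and jump codes.
3. **Consistency** — are observed values admissible? Hard/soft/detection
   limit checks for numeric and date-time variables, inadmissible
   categorical values, and two-variable contradiction rules drawn from a
   16-member predicate catalog.
4. **Accuracy** — are distributions and associations plausible? Univariate
   outliers (Tukey, six sigma, medcouple-adjusted Hubert, MAD fences),
   multivariate outliers via Mahalanobis distance, distributional
   shape/scale tests, end-digit preference, examiner effects via
   covariate-adjusted marginal means, variance components (intra-class
   correlation), and LOESS-smoothed time trends.

A registry (`dq_registry()`) enumerates 34 indicators across these four
dimensions; 27 are computed by checks in this package, the remainder are
registered for interoperability. Every check returns a `dq_result` tibble
with machine-readable counts, percentages, a binary grading and the exact
flagged cell coordinates, so findings feed directly into data management.
Checks run only where an applicability matrix — computed from the metadata
during the integrity step — says they are valid; a column whose observed
type contradicts its declaration is never range-checked.

The package is tidyverse-native: functions accept and return tibbles,
result objects have `generics::tidy()` / `generics::glance()` methods, and
plotting goes through `ggplot2::autoplot()`.

## The metadata vocabulary

Checks are configured by a flat table with one row per variable:

| column | meaning |
|---|---|
| `VAR_NAMES`, `LABEL`, `DATA_TYPE` | name, label, one of `integer`/`float`/`string`/`datetime` |
| `HARD_LIMITS`, `SOFT_LIMITS`, `DETECTION_LIMITS` | interval literals, e.g. `"[60;300]"`, `"(0;Inf)"`, `"[1997-01-01;2001-12-31]"` |
| `VALUE_LABELS` | admissible categories, `"0 = never | 1 = former | 2 = current"` |
| `MISSING_LIST`, `JUMP_LIST` | qualified missing / jump codes with reasons, `"99901 = refusal"` |
| `STUDY_SEGMENT` | examination block the variable belongs to |
| `KEY_OBSERVER`, `KEY_DATETIME` | process variables (examiner, exam date) attached to a measurement |

Brackets encode interval closedness (`[`/`]` closed, `(`/`)` open); a
missing code is never a limit violation, a jump code is a legitimate skip.

## Worked example

The built-in generator draws a synthetic examination survey and injects
defects recorded in a ground-truth ledger:

```r
library(dqscreen)

sim <- dq_simulate_study(n = 500, seed = 42)
dplyr::count(sim$ledger, defect_type)
#>    defect_type             n
#>  1 category-violation      5
#>  2 coded-missing:99900    37
#>  3 coded-missing:99901   115
#>  4 contradiction:R1       14
#>  5 contradiction:R2       10
#>  6 hard-violation         19
#>  7 outlier                 5
#>  8 soft-violation         11
#>  9 system-missing        254
#> 10 type-mismatch           2

rep <- dq_report(sim$study, sim$metadata, sim$rules,
                 config = list(roster = sim$roster,
                               segment_order = sim$segment_order,
                               covariates = "age"))
glance(rep)
#>   n_units n_results n_issues n_not_applicable n_flagged_cells
#> 1     500        77       52                1            1063
```

The machine-readable results recover the planted defects exactly — the 19
hard violations split over height/sbp/dbp, the 11 soft violations over
weight/sbp, and the 7 + 5 contradictory units (each contradiction writes
two cells, hence 14 + 10 ledger rows):

```r
dplyr::filter(tidy(rep), indicator_id %in% c("DQI-3001", "DQI-3006",
                                             "DQI-3008", "DQI-3009"))
#>   indicator_id variable n_flagged denominator percent grading
#> 1 DQI-3001     height           7         448   1.56  issue
#> 2 DQI-3001     sbp              5         469   1.07  issue
#> 3 DQI-3001     dbp              7         457   1.53  issue
#> 4 DQI-3006     weight           5         454   1.10  issue
#> 5 DQI-3006     sbp              6         469   1.28  issue
#> 6 DQI-3008     R1               7         500   1.4   issue
#> 7 DQI-3009     R2               5         500   1     issue
```

Reports export to schema-versioned JSON and render to a static HTML + CSV
bundle; `annotate_flags()` writes the firing indicator IDs next to each
flagged cell of the study table:

```r
dq_export_json(rep, "report.json")
dq_render_report(rep, "report_dir")
annotated <- annotate_flags(sim$study, rep)
```

Single checks run standalone for a step-by-step workflow:

```r
limit_deviations(sim$study, sim$metadata, "sbp")
#>   indicator_id variable n_flagged denominator percent grading
#> 1 DQI-3001     sbp              5         469    1.07 issue
#> 2 DQI-3006     sbp              6         469    1.28 issue
```

A thin command line interface wraps the same operations:

```sh
dqscreen simulate --n 500 --seed 42 --out sim_dir
dqscreen report --study sim_dir/study.csv --metadata sim_dir/metadata.csv \
         --rules sim_dir/rules.csv --out report_dir
dqscreen check limit_deviations --study sim_dir/study.csv \
         --metadata sim_dir/metadata.csv --var sbp
```

Exit code 0 means the assessment ran (finding issues is not an error),
1 signals an input error, 2 an internal error.

## Further reading

The methods vignette (`vignettes/methodology.Rmd`) documents the
missingness staging, the predicate catalog, the fence formulas (including
the exact O(n²) medcouple), the marginal-means flagging rule and the
design of the synthetic-study generator.
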