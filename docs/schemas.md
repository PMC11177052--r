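# Input table schemas

One cohort is a bundle of flat CSV tables. Dialect: comma-separated,
UTF-8, header row, RFC-4180 quoting. Timestamps are timezone-naive
ISO-8601 (`YYYY-MM-DDTHH:MM:SS`), local clock time, second resolution.
The missing-value sentinel in every column is the literal `NA` (never an
empty string). `read_tables()` validates files against these schemas and
reports rejected rows with their line numbers; `validate_bundle()` does
the same for in-memory data frames.

## stays — one row per ICU stay

| column | type | constraints |
|---|---|---|
| stay_id | id | |
| patient_id | id | |
| admit_time | timestamp | |
| discharge_time | timestamp | strictly after `admit_time` |
| is_readmission | boolean (`true`/`false`) | |
| age_years | number | ≥ 0 |
| sex | enum | `male`, `female` |
| diabetes | boolean | |
| race | label | free text |
| admission_type | enum | `elective`, `emergency` |
| sofa_admission | integer | ≥ 0, may be `NA` |
| oasis | integer | ≥ 0, may be `NA` |
| in_hospital_mortality | boolean | |

## glucose_events — one row per measurement

| column | type | constraints |
|---|---|---|
| stay_id | id | |
| chart_time | timestamp | time of data entry |
| store_time | timestamp | may be `NA`; used when earlier than `chart_time` |
| value_mmol_l | number | > 0 (mg/dL inputs: multiply by 0.0555 before loading) |
| sample_type | enum | `whole_blood`, `serum`, `capillary` |

## nutrition_events — rate-based enteral-nutrition intervals

| column | type | constraints |
|---|---|---|
| stay_id | id | |
| product_id | id | joined to `products` |
| start_time | timestamp | |
| end_time | timestamp | ≥ `start_time` |
| rate | number | mL/h, ≥ 0 |

## medication_events — insulin / dextrose / glucocorticoid

| column | type | constraints |
|---|---|---|
| stay_id | id | |
| kind | enum | `insulin`, `dextrose`, `glucocorticoid` |
| subtype | enum | insulin: `rapid`, `short`, `intermediate`, `long`; dextrose: `infusion`, `push`; glucocorticoid: `NA` |
| start_time | timestamp | |
| end_time | timestamp | ≥ `start_time` (equal for pushes) |
| rate | number | units/h (insulin) or g/h (dextrose); exactly one of rate/amount for insulin and dextrose |
| amount | number | units or g for discrete pushes |

## ventilation_events — charted ventilation state

| column | type | constraints |
|---|---|---|
| stay_id | id | |
| time | timestamp | state carried forward until the next record |
| state | enum | `invasive`, `non_invasive`, `none` |

## rass_events — charted sedation scores

| column | type | constraints |
|---|---|---|
| stay_id | id | |
| time | timestamp | |
| rass | integer | −5 … +4 |

## products — carbohydrate-content lookup

| column | type | constraints |
|---|---|---|
| product_id | id | |
| carb_g_ml | number | g carbohydrate per mL; `NA` = unknown content (measurements covered only by such products are removed) |

## analysis rows (output of `build_analysis_table()` / `write_analysis_table()`)

Fixed column order: `stay_id`, `patient_id`, `glucose_mmol_l`,
`hour_bin`, `age_cat`, `sex`, `diabetes`, `carb_cat`, `insulin_cat`,
`dextrose_cat`, `glucocorticoid`, `carb_rate_g_h`, `insulin_rate_u_h`,
`dextrose_rate_g_h`, `age_years`, `days_since_admission`,
`time_to_next_sample_h`, `ventilation`, `rass`, `sample_type`.
`time_to_next_sample_h` is `NA` for a stay's last measurement and `rass`
before the first charted score; all model covariates are non-missing by
construction.
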