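# steppath file formats

All tabular files are headered CSV, UTF-8, with ISO-8601 dates.

## Inputs (written by `write_cohort()`, read by `read_cohort()`)

### steps.csv — daily device records
| column | type | meaning |
|---|---|---|
| person_id | string | participant identifier |
| date | date | calendar day |
| steps | integer >= 0 | daily step count |
| wear_minutes | integer in [0, 1440] | device wear time |

### bmi.csv — EHR BMI records
`person_id`, `date`, `bmi` (kg/m^2, in (10, 100)).

### genetics.csv
`person_id`, `score` (raw polygenic score), `pc1` ... `pc10` (ancestry
principal components). Alternatively a dosage matrix (persons x SNPs,
values in [0, 2]) plus a weights CSV with columns `snp_id`, `weight` can
be scored with `score_genotypes()`.

### covariates.csv
`person_id`, `baseline_age` (years), `sex` (1 = male), `cancer`, `cad`,
`sbp` (mm Hg), `alcohol`, `education`
(`no_college` / `some_college` / `college`), `smoking`. Missing values
are empty cells; only baseline BMI, alcohol, education, SBP and smoking
may be missing (they are the imputed variables).

### truth.json (simulated cohorts only)
`config` (the generating parameters) and `participants` with per-person
`prs_true`, `latent_onset_time` (years from monitoring start, null when
censored) and `step_intercept`.

## Outputs (written by `run_pipeline()`)

- `manifest.json` — package version, seed, configuration hash, cohort and
  event counts.
- `attrition.json` — ordered per-rule exclusion counts; the counts sum to
  the input person count.
- `analytic_cohort.csv` — one row per analysed person (curate verb).
- `fit.json` — model name, coefficients, covariance, term map,
  nonlinearity p-values, chunk tests, 75th-vs-25th percentile hazard-ratio
  contrasts.
- `targets.csv` — `prs_percentile`, `baseline_bmi` (stratum or empty),
  `steps_at_unit_hr`, `ci_low`, `ci_high`, `flag`
  (`ok`, `one_sided`, `multiple_crossings`, `unattainable`).
- `incidence.csv` — `prs_percentile`, `steps`, `year`, `risk`, `ci_low`,
  `ci_high`.
- `summary.txt` — plain-text analysis summary.
- `table1.csv` — descriptive characteristics across PRS quartiles with
  small-cell suppression.
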