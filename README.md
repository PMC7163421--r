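# eship2

Validation analysis for automated blood-pressure monitors under the
European Society of Hypertension International Protocol, 2010 revision
(ESH-IP2), with a synthetic paired-device cohort simulator.

## The problem

Before a home blood-pressure monitor can be trusted — clinically or for
self-measurement in a specific population such as hemodialysis patients —
it must be validated against a reference device under a standardized
protocol. The ESH-IP2 design takes 33 subjects and makes nine consecutive
readings per subject, alternating reference and test devices:

```
BPA (reference)  BPB (test)            <- entry readings
BP1 (ref) BP2 (test) BP3 (ref) BP4 (test) BP5 (ref) BP6 (test) BP7 (ref)
```

Each test reading (BP2, BP4, BP6) is compared to **both** flanking
reference readings and the *most favorable* comparison — the flanking
reading with the smaller absolute difference — is kept, giving 3
comparisons per subject and 99 in total per quantity (systolic pressure,
diastolic pressure, heart rate).

Absolute differences d = test − reference are classified into three nested
bands (|d| ≤ 5, 10, 15 mmHg for SBP/DBP; ≤ 3, 5, 8 bpm for HR), and the
device is graded in three parts:

* **Part 1** — pooled band counts over the 99 comparisons must exceed
  per-band thresholds (> 72 / 86 / 95 of 99 for SBP and HR,
  > 64 / 80 / 92 for DBP in the default *paper* mode; a *canonical* mode
  implements the protocol's published two-of-three ≥ 73/87/96 plus
  all-three ≥ 65/81/93 rule).
* **Part 2** — per subject: more than 23 of the 33 subjects must have at
  least two of their three comparisons within the first band, and at most
  3 subjects may have none.
* **Part 3** — overall validation: part 1 ∧ part 2 (blood pressure passes
  only if SBP and DBP both pass; heart rate is graded separately).

Agreement is additionally summarised in Bland-Altman form: the signed
difference of each graded pair against its mean, with 95% limits of
agreement at mean ± 1.96·SD.

The package also ships a seeded cohort simulator (subject baselines drawn
from recruitment-style pressure strata; linear within-session drift plus
reading-to-reading noise; per-device additive bias, proportional bias and
observation noise, integer rounding and display-range clamping) and a
Monte-Carlo estimator of the probability that a device with a given error
model passes the protocol — the 33-subject design is small, and that
operating characteristic is worth seeing before running a study.

## Worked example

Simulate a validation study of a slightly biased but precise test device,
then grade it:

```r
library(eship2)

sessions <- simulate_cohort(
  cohort_spec(),   # 33 subjects, >=10 of each sex, strata-based baselines
  reference_model = device_error_model(noise_sd = c(sbp = 1.5, dbp = 1.5, hr = 1)),
  test_model = device_error_model(bias = c(sbp = 1, dbp = 1, hr = 0.5),
                                  noise_sd = c(sbp = 1.5, dbp = 1.5, hr = 1)),
  seed = 1
)
report <- grade_device(sessions)
report
#> ESH-IP2 device validation (paper mode, 33 subjects)
#>
#> Part 1 (pooled band counts of 99 comparisons):
#> # A tibble: 3 x 9
#>   quantity n_total n_band1 n_band2 n_band3 band1_pass band2_pass band3_pass
#>   <chr>      <int>   <int>   <int>   <int> <lgl>      <lgl>      <lgl>
#> 1 dbp           99      91      99      99 TRUE       TRUE       TRUE
#> 2 hr            99      83      94      99 TRUE       TRUE       TRUE
#> 3 sbp           99      82      97      99 TRUE       TRUE       TRUE
#>
#> Part 2 (per-subject band-1 tallies):
#> # A tibble: 3 x 5
#>   quantity n_subjects n_ge2 n_zero pass
#> 1 dbp              33    33      0 TRUE
#> 2 hr               33    30      1 TRUE
#> 3 sbp              33    29      0 TRUE
#>
#> Overall:
#> # A tibble: 2 x 4
#>   group part1_pass part2_pass part3_pass
#> 1 bp    TRUE       TRUE       TRUE
#> 2 hr    TRUE       TRUE       TRUE
```

Reading this: of the 99 systolic comparisons, 82 were within 5 mmHg
(> 72 required), 97 within 10 (> 86) and 99 within 15 (> 95), so SBP
passes part 1; 29 of 33 subjects had at least two of three systolic
comparisons within 5 mmHg (> 23 required) and none had zero (≤ 3
allowed), so SBP passes part 2. The same holds for DBP and HR, so the
simulated device passes part 3 — overall validation — for both blood
pressure and heart rate.

Everything is a tibble underneath: `tidy(report)` gives one row per
quantity (band counts, pass flags, agreement statistics), `glance(report)`
a one-row summary, and

```r
autoplot(bland_altman(report$comparisons))
```

draws the three Bland-Altman panels with mean difference and limits of
agreement. `estimate_pass_probability()` wraps the whole pipeline in a
Monte-Carlo loop:

```r
estimate_pass_probability(
  cohort_spec(),
  test_model = device_error_model(noise_sd = 4),
  n_replicates = 100, seed = 1
)
#> # A tibble: 1 x 5  (n_replicates, n_passes, estimate, conf_low, conf_high)
```

A command-line wrapper is installed at `exec/eship2` inside the package
(`eship2 validate --sessions FILE --out DIR`, `eship2 simulate`,
`eship2 power`); a device *failing* validation is a result (exit 0), not
an execution error.

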