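test_that("cohort specs validate their constraints", {
  expect_s3_class(cohort_spec(), "cohort_spec")
  expect_error(cohort_spec(n_subjects = 15, min_males = 10, min_females = 10),
               class = "eship2_config_error")
  expect_error(cohort_spec(sbp_strata = tibble::tibble(
    lower = 90, upper = 180, count = 10
  )), class = "eship2_config_error")  # counts must sum to n_subjects
  expect_error(cohort_spec(within_sd = c(sbp = -1)),
               class = "eship2_config_error")
  expect_error(device_error_model(noise_sd = -2),
               class = "eship2_config_error")
  expect_error(device_error_model(bias = c(pulse = 3)),
               class = "eship2_config_error")
})

test_that("subject truth honours cohort constraints and is seed-deterministic", {
  spec <- cohort_spec()
  truth <- simulate_subject_truth(spec, seed = 7)
  expect_equal(nrow(truth), 33L)
  expect_gte(sum(truth$sex == "male"), 10)
  expect_gte(sum(truth$sex == "female"), 10)
  expect_true(all(truth$age >= 47 & truth$age <= 88))
  expect_true(all(truth$arm_circumference_mm >= 220 &
                    truth$arm_circumference_mm <= 350))
  # 11 baselines in each default stratum
  in_range <- function(x, lo, hi) sum(x >= lo & x <= hi)
  expect_equal(in_range(truth$sbp_baseline, 90, 129), 11L)
  expect_equal(in_range(truth$sbp_baseline, 130, 160), 11L)
  expect_equal(in_range(truth$sbp_baseline, 161, 180), 11L)
  expect_true(all(truth$dbp_baseline < truth$sbp_baseline))

  expect_equal(simulate_subject_truth(spec, seed = 7), truth)
  expect_false(isTRUE(all.equal(simulate_subject_truth(spec, seed = 8),
                                truth)))
})

test_that("enlarging the cohort leaves earlier subjects unchanged", {
  small <- simulate_subject_truth(cohort_spec(n_subjects = 21), seed = 3)
  large <- simulate_subject_truth(cohort_spec(n_subjects = 33), seed = 3)
  expect_equal(large[1:21, ], small)

  s_small <- suppressMessages(simulate_cohort(cohort_spec(n_subjects = 21),
                                              seed = 3))
  s_large <- suppressMessages(simulate_cohort(cohort_spec(), seed = 3))
  attrs <- function(x) {
    attr(x, "truth") <- NULL
    attr(x, "clamp_events") <- NULL
    x
  }
  expect_equal(attrs(s_large)[1:21, ], attrs(s_small)[1:21, ])
})

test_that("simulated cohorts are deterministic down to the CSV bytes", {
  a <- suppressMessages(simulate_cohort(cohort_spec(), seed = 42))
  b <- suppressMessages(simulate_cohort(cohort_spec(), seed = 42))
  pa <- withr::local_tempfile(fileext = ".csv")
  pb <- withr::local_tempfile(fileext = ".csv")
  write_sessions(a, pa)
  write_sessions(b, pb)
  expect_identical(readLines(pa), readLines(pb))
})

test_that("simulated sessions respect the data model", {
  sessions <- suppressMessages(simulate_cohort(cohort_spec(), seed = 13))
  expect_equal(nrow(sessions), 33L)
  issues <- validate_sessions(sessions)
  expect_equal(nrow(issues[issues$severity == "error", ]), 0L)
  # integer readings within device display ranges
  expect_true(all(vapply(
    sessions[grep("_(sbp|dbp|hr)$", names(sessions))], is.integer,
    logical(1)
  )))
  cmp <- build_comparisons(sessions)
  expect_equal(unname(table(cmp$quantity)), rep(99L, 3),
               ignore_attr = TRUE)
})

test_that("zero-noise simulation reproduces device parameters exactly", {
  quiet_spec <- cohort_spec(drift = c(sbp = 0, dbp = 0, hr = 0),
                            within_sd = c(sbp = 0, dbp = 0, hr = 0))
  # identical ideal devices: every reading equals the rounded baseline
  sessions <- simulate_cohort(quiet_spec, seed = 2)
  cmp <- build_comparisons(sessions)
  expect_true(all(cmp$difference == 0))
  expect_true(all(grade_device(sessions)$summary$part3_pass))

  # +4 test bias, no noise anywhere: every systolic difference is exactly +4
  biased <- simulate_cohort(
    quiet_spec,
    test_model = device_error_model(bias = c(sbp = 4)),
    seed = 2
  )
  cmp <- build_comparisons(biased, "sbp")
  expect_true(all(cmp$difference == 4))
})

test_that("within-session drift shows up in the readings", {
  drifting <- cohort_spec(drift = c(sbp = -2, dbp = 0, hr = 0),
                          within_sd = c(sbp = 0, dbp = 0, hr = 0))
  sessions <- simulate_cohort(drifting, seed = 9)
  # reference readings BPA (index 0) and BP7 (index 8): 8 steps of -2
  expect_true(all(sessions$BP7_sbp - sessions$BPA_sbp == -16L))
})

test_that("configured bias is recovered within three clustered standard errors", {
  spec <- cohort_spec(n_subjects = 500)
  sessions <- suppressMessages(simulate_cohort(
    spec,
    test_model = device_error_model(bias = 3, noise_sd = 2),
    seed = 31
  ))
  rec <- recover_device_bias(sessions)
  expect_equal(nrow(rec), 3L)
  for (q in rec$quantity) {
    row <- rec[rec$quantity == q, ]
    expect_lt(abs(row$bias_estimate - 3), 3 * row$se)
  }

  neg <- suppressMessages(simulate_cohort(
    spec,
    test_model = device_error_model(bias = -3, noise_sd = 2),
    seed = 31
  ))
  expect_true(all(recover_device_bias(neg)$bias_estimate < 0))

  expect_true(all(recover_device_bias(perfect_cohort(33))$bias_estimate == 0))
})

test_that("pass probability is 1 for a perfect device and 0 beyond band 3", {
  quiet_spec <- cohort_spec(drift = c(sbp = 0, dbp = 0, hr = 0),
                            within_sd = c(sbp = 0, dbp = 0, hr = 0))
  perfect <- estimate_pass_probability(quiet_spec, n_replicates = 50,
                                       seed = 21)
  expect_equal(perfect$estimate, 1)
  expect_equal(perfect$n_passes, 50L)
  expect_true(perfect$conf_low <= 1 & perfect$conf_high >= perfect$estimate)

  hopeless <- estimate_pass_probability(
    cohort_spec(),
    test_model = device_error_model(bias = 20, noise_sd = 1),
    n_replicates = 200, seed = 22
  )
  expect_equal(hopeless$estimate, 0)
  expect_true(hopeless$conf_low <= hopeless$estimate)
  expect_true(hopeless$conf_high >= hopeless$estimate)
})

test_that("pass probability is nonincreasing in test-device noise", {
  grid <- c(0, 2, 4, 6, 8)
  est <- vapply(seq_along(grid), function(i) {
    estimate_pass_probability(
      cohort_spec(),
      test_model = device_error_model(noise_sd = grid[i]),
      n_replicates = 40, seed = 500
    )$estimate
  }, numeric(1))
  # allow Monte-Carlo error: each step may rise by at most ~3 binomial SEs
  mc_slack <- 3 * sqrt(0.25 / 40)
  expect_true(all(diff(est) <= mc_slack))
  expect_lt(est[length(est)], est[1])
})
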