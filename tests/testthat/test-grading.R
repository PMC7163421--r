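paper_band_counts <- function() {
  tibble::tibble(
    quantity = c("sbp", "dbp", "hr"),
    n_total = 99L,
    n_band1 = c(90L, 89L, 81L),
    n_band2 = c(95L, 94L, 91L),
    n_band3 = c(98L, 94L, 96L)
  )
}

test_that("part 1 passes on the published worked-example counts", {
  res <- evaluate_part1(paper_band_counts(), grading_config())
  expect_true(all(res$band1_pass))
  expect_true(all(res$band2_pass))
  expect_true(all(res$band3_pass))
  expect_true(all(res$pass))
})

test_that("part 1 thresholds are strict inequalities in paper mode", {
  counts <- paper_band_counts()
  counts$n_band1[counts$quantity == "sbp"] <- 72L  # not strictly above 72
  res <- evaluate_part1(counts, grading_config())
  expect_false(res$band1_pass[res$quantity == "sbp"])
  expect_false(res$pass[res$quantity == "sbp"])
  expect_true(res$pass[res$quantity == "dbp"])

  counts$n_band1[counts$quantity == "sbp"] <- 73L  # minimal pass
  res <- evaluate_part1(counts, grading_config())
  expect_true(res$pass[res$quantity == "sbp"])
})

test_that("canonical mode allows one band below the upper criterion row", {
  # band-1 count 72 fails paper mode but meets the canonical two-of-three
  # rule (95 >= 87, 98 >= 96) with all three above the lower row
  counts <- tibble::tibble(
    quantity = "sbp", n_total = 99L,
    n_band1 = 72L, n_band2 = 95L, n_band3 = 98L
  )
  expect_false(evaluate_part1(counts, grading_config())$pass)
  expect_true(evaluate_part1(counts, grading_config("canonical"))$pass)

  # but a count below the all-three row fails regardless
  counts$n_band1 <- 64L
  expect_false(evaluate_part1(counts, grading_config("canonical"))$pass)
})

test_that("part 1 rejects mismatched totals and decreasing bands", {
  counts <- paper_band_counts()
  counts$n_total <- 66L
  expect_error(evaluate_part1(counts, grading_config()),
               class = "eship2_config_error")
  counts <- paper_band_counts()
  counts$n_band2[1] <- 80L
  expect_error(evaluate_part1(counts, grading_config()),
               "nondecreasing", class = "eship2_input_error")
})

test_that("part 2 applies both subject-level criteria", {
  # published BP outcome: 31 subjects with >=2 of 3 in band 1, 1 with none
  bp <- evaluate_part2(tallies_fixture(31, 1, 1), grading_config())
  expect_equal(bp$n_ge2, 31L)
  expect_equal(bp$n_zero, 1L)
  expect_true(bp$pass)

  # published HR outcome: 28 with >=2, 2 with none
  hr <- evaluate_part2(tallies_fixture(28, 3, 2, quantity = "hr"),
                       grading_config())
  expect_true(hr$pass)

  # enough subjects with >=2 but too many with zero
  fail <- evaluate_part2(tallies_fixture(24, 5, 4), grading_config())
  expect_equal(fail$n_ge2, 24L)
  expect_equal(fail$n_zero, 4L)
  expect_false(fail$pass)

  # boundary: exactly 23 subjects with >=2 is not enough (strict >)
  expect_false(evaluate_part2(tallies_fixture(23, 10, 0),
                              grading_config())$pass)
  expect_true(evaluate_part2(tallies_fixture(24, 9, 0),
                             grading_config())$pass)
})

test_that("part 2 rejects invalid tallies and wrong cohort sizes", {
  bad <- tallies_fixture(31, 1, 1)
  bad$band1_tally[1] <- 4L
  expect_error(evaluate_part2(bad, grading_config()),
               class = "eship2_input_error")
  expect_error(evaluate_part2(tallies_fixture(20, 5, 0), grading_config()),
               class = "eship2_config_error")
})

test_that("grading refuses non-33-subject cohorts without custom thresholds", {
  expect_error(grading_config(n_subjects = 20),
               class = "eship2_config_error")
  cfg <- grading_config(
    n_subjects = 20,
    part1_thresholds = tibble::tibble(
      quantity = c("sbp", "dbp", "hr"),
      band1 = c(43, 38, 43), band2 = c(52, 48, 52), band3 = c(57, 55, 57)
    )
  )
  expect_equal(cfg$n_comparisons, 60L)
  sessions <- perfect_cohort(32)
  expect_error(grade_device(sessions), "32",
               class = "eship2_config_error")
})

test_that("a perfect-agreement cohort passes everything", {
  report <- grade_device(perfect_cohort(33))
  expect_true(all(report$band_counts$n_band1 == 99L))
  expect_true(all(report$part1$pass))
  expect_true(all(report$part2$pass))
  expect_true(all(report$summary$part3_pass))
  g <- glance(report)
  expect_true(g$bp_part3_pass)
  expect_true(g$hr_part3_pass)
  td <- tidy(report)
  expect_equal(nrow(td), 3L)
  expect_true(all(td$mean_signed_difference == 0))
})

test_that("a +20 mmHg systolic bias zeroes the SBP bands and fails part 1", {
  spec <- cohort_spec(drift = c(sbp = 0, dbp = 0, hr = 0),
                      within_sd = c(sbp = 0, dbp = 0, hr = 0))
  sessions <- suppressMessages(simulate_cohort(
    spec,
    test_model = device_error_model(bias = c(sbp = 20), noise_sd = 1),
    seed = 5
  ))
  report <- grade_device(sessions)
  sbp <- report$part1[report$part1$quantity == "sbp", ]
  expect_equal(sbp$n_band3, 0L)
  expect_false(sbp$pass)
  expect_false(report$summary$part3_pass[report$summary$group == "bp"])
})

test_that("part 3 is the conjunction of parts 1 and 2 across noise regimes", {
  for (noise in c(0, 3, 6, 10)) {
    sessions <- suppressMessages(simulate_cohort(
      cohort_spec(),
      test_model = device_error_model(noise_sd = noise),
      seed = 100 + noise
    ))
    report <- grade_device(sessions)
    s <- report$summary
    p1 <- report$part1$pass
    names(p1) <- report$part1$quantity
    p2 <- report$part2$pass
    names(p2) <- report$part2$quantity
    expect_equal(s$part1_pass[s$group == "bp"],
                 unname(p1["sbp"] && p1["dbp"]))
    expect_equal(s$part2_pass[s$group == "bp"],
                 unname(p2["sbp"] && p2["dbp"]))
    expect_equal(s$part1_pass[s$group == "hr"], unname(p1["hr"]))
    expect_equal(s$part3_pass, s$part1_pass & s$part2_pass)
  }
})

test_that("shrinking any difference never turns a pass into a fail", {
  withr::local_seed(303)
  decide <- function(diffs) {
    cmp <- cohort_comparisons(diffs, "sbp")
    cfg <- grading_config()
    p1 <- evaluate_part1(classify_differences(cmp), cfg)$pass
    p2 <- evaluate_part2(subject_band1_tally(cmp), cfg)$pass
    p1 && p2
  }
  for (rep in 1:40) {
    diffs <- matrix(round(rnorm(99, 0, 5)), nrow = 33)
    before <- decide(diffs)
    shrunk <- diffs
    idx <- cbind(sample(33, 1), sample(3, 1))
    shrunk[idx] <- trunc(shrunk[idx] / 2)  # strictly smaller magnitude
    after <- decide(shrunk)
    expect_false(before && !after)
  }
})

test_that("validation reports round-trip through JSON", {
  report <- grade_device(perfect_cohort(33))
  path <- withr::local_tempfile(fileext = ".json")
  write_validation_report(report, path)
  back <- read_validation_report(path)
  expect_equal(back$n_subjects, report$n_subjects)
  expect_equal(back$mode, "paper")
  expect_equal(back$part1, report$part1)
  expect_equal(back$part2[c("quantity", "n_ge2", "n_zero", "pass")],
               report$part2[c("quantity", "n_ge2", "n_zero", "pass")])
  expect_equal(back$summary, report$summary)
  expect_equal(back$agreement, report$agreement)
})
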