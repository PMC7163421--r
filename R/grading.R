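# Part 1 / part 2 / part 3 grading.
#
# Two threshold modes are provided:
#
# * "paper": per-band exceed-thresholds applied with a strict ">" — (72, 86,
#   95) of 99 for SBP, (64, 80, 92) for DBP, and SBP-style thresholds for
#   heart rate; a quantity passes part 1 iff all three band counts strictly
#   exceed their thresholds.
# * "canonical": the protocol's published two-row criterion, applied per
#   quantity — at least two of the three band counts must reach (73, 87, 96)
#   AND all three must reach (65, 81, 93).
#
# Note >72 on an integer count is equivalent to >=73, so the two modes
# differ only in the two-of-three allowance.  Part 2 is identical in both
# modes: more than 23 subjects with at least two of their three band-1
# comparisons, and at most 3 subjects with none.

#' Grading configuration
#'
#' Encodes the pass thresholds used by [evaluate_part1()],
#' [evaluate_part2()] and [grade_device()].  The bundled thresholds are
#' stated for a 33-subject cohort (99 comparisons per quantity); grading a
#' different cohort size requires explicit `part1_thresholds`.
#'
#' @param mode `"paper"` (strict per-band exceed-thresholds, the default) or
#'   `"canonical"` (the protocol's two-of-three / all-three criterion).
#' @param n_subjects Number of graded subjects the thresholds refer to
#'   (default 33).
#' @param part1_thresholds Optional replacement threshold table, same shape
#'   as the bundled one (paper mode: columns `quantity`, `band1`, `band2`,
#'   `band3`; canonical mode: `two_of_three` and `all_three` rows).
#' @param part2_min_ge2 Part 2 passes only if the number of subjects with at
#'   least two band-1 comparisons strictly exceeds this (default 23).
#' @param part2_max_zero Part 2 passes only if the number of subjects with
#'   zero band-1 comparisons is at most this (default 3).
#' @return An object of class `grading_config`.
#' @examples
#' grading_config()
#' grading_config("canonical")
#' @export
grading_config <- function(mode = c("paper", "canonical"), n_subjects = 33,
                           part1_thresholds = NULL,
                           part2_min_ge2 = 23, part2_max_zero = 3) {
  mode <- match.arg(mode)
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1) {
    abort_config("`n_subjects` must be a positive integer")
  }
  if (is.null(part1_thresholds)) {
    if (n_subjects != 33L) {
      abort_config(paste0(
        "bundled part 1 thresholds are stated for 33 subjects (99 ",
        "comparisons); supply `part1_thresholds` to grade a ",
        n_subjects, "-subject cohort"
      ))
    }
    part1_thresholds <- if (mode == "paper") {
      tibble(
        quantity = c("sbp", "dbp", "hr"),
        band1 = c(72, 64, 72),
        band2 = c(86, 80, 86),
        band3 = c(95, 92, 95)
      )
    } else {
      tibble(
        rule = c("two_of_three", "all_three"),
        band1 = c(73, 65),
        band2 = c(87, 81),
        band3 = c(96, 93)
      )
    }
  }
  if (any(unlist(part1_thresholds[sapply(part1_thresholds, is.numeric)]) < 0)) {
    abort_config("part 1 thresholds must be nonnegative")
  }
  structure(
    list(
      mode = mode,
      n_subjects = n_subjects,
      n_comparisons = 3L * n_subjects,
      part1_thresholds = part1_thresholds,
      part2_min_ge2 = part2_min_ge2,
      part2_max_zero = part2_max_zero
    ),
    class = "grading_config"
  )
}

#' @export
print.grading_config <- function(x, ...) {
  cat("Device-validation grading configuration\n")
  cat("  mode:", x$mode, "\n")
  cat("  subjects:", x$n_subjects,
      sprintf("(%d comparisons per quantity)\n", x$n_comparisons))
  cat("  part 1 thresholds:\n")
  print(x$part1_thresholds)
  cat(sprintf("  part 2: > %d subjects with >=2 band-1 comparisons, <= %d with 0\n",
              x$part2_min_ge2, x$part2_max_zero))
  invisible(x)
}

#' Evaluate the part 1 criterion
#'
#' Part 1 grades the pooled band counts over all comparisons (99 in a
#' 33-subject cohort) for each quantity.  In paper mode a band passes iff
#' its count strictly exceeds the configured threshold and a quantity passes
#' iff all three bands pass; in canonical mode a quantity passes iff at
#' least two band counts reach the upper threshold row and all three reach
#' the lower row.
#'
#' @param band_counts A tibble as returned by [classify_differences()]
#'   (`quantity`, `n_total`, `n_band1`, `n_band2`, `n_band3`).
#' @param config A [grading_config()].
#' @return A tibble with one row per quantity: the band counts, per-band
#'   pass flags and the overall `pass` flag.
#' @export
evaluate_part1 <- function(band_counts, config = grading_config()) {
  stopifnot(inherits(config, "grading_config"))
  required <- c("quantity", "n_total", "n_band1", "n_band2", "n_band3")
  missing_cols <- setdiff(required, names(band_counts))
  if (length(missing_cols) > 0) {
    abort_input(paste0("band_counts missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (any(band_counts$n_total != config$n_comparisons)) {
    abort_config(paste0(
      "band counts cover ", band_counts$n_total[1], " comparisons but the ",
      "configuration expects ", config$n_comparisons
    ))
  }
  counts <- as.matrix(band_counts[c("n_band1", "n_band2", "n_band3")])
  if (any(counts[, 1] > counts[, 2]) || any(counts[, 2] > counts[, 3])) {
    abort_input("band counts must be nondecreasing across bands")
  }

  if (config$mode == "paper") {
    thr <- dplyr::left_join(band_counts["quantity"], config$part1_thresholds,
                            by = "quantity")
    if (anyNA(thr$band1)) {
      abort_config(paste0("no part 1 thresholds configured for quantity ",
                          thr$quantity[is.na(thr$band1)][1]))
    }
    pass_mat <- counts > as.matrix(thr[c("band1", "band2", "band3")])
  } else {
    hi <- as.numeric(config$part1_thresholds[
      config$part1_thresholds$rule == "two_of_three",
      c("band1", "band2", "band3")])
    lo <- as.numeric(config$part1_thresholds[
      config$part1_thresholds$rule == "all_three",
      c("band1", "band2", "band3")])
    ge_hi <- sweep(counts, 2, hi, `>=`)
    ge_lo <- sweep(counts, 2, lo, `>=`)
    pass_mat <- ge_hi
    attr(pass_mat, "all_three_ok") <- rowSums(ge_lo) == 3
  }

  out <- band_counts
  out$band1_pass <- pass_mat[, 1]
  out$band2_pass <- pass_mat[, 2]
  out$band3_pass <- pass_mat[, 3]
  out$pass <- if (config$mode == "paper") {
    rowSums(pass_mat) == 3
  } else {
    rowSums(pass_mat) >= 2 & attr(pass_mat, "all_three_ok")
  }
  out
}

#' Evaluate the part 2 criterion
#'
#' Part 2 grades per-subject behaviour: the device passes for a quantity iff
#' strictly more than 23 subjects have at least two of their three
#' comparisons within band 1, and at most 3 subjects have none.
#'
#' @param tallies A tibble as returned by [subject_band1_tally()]
#'   (`subject_id`, `quantity`, `band1_tally` in 0-3), one row per subject
#'   and quantity.
#' @param config A [grading_config()].
#' @return A tibble with one row per quantity: `n_subjects`, `n_ge2`
#'   (subjects with tally >= 2), `n_zero` (subjects with tally 0) and
#'   `pass`.
#' @export
evaluate_part2 <- function(tallies, config = grading_config()) {
  stopifnot(inherits(config, "grading_config"))
  missing_cols <- setdiff(c("subject_id", "quantity", "band1_tally"),
                          names(tallies))
  if (length(missing_cols) > 0) {
    abort_input(paste0("tallies missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(tallies$band1_tally)) ||
      any(!tallies$band1_tally %in% 0:3)) {
    abort_input("band-1 tallies must be integers in 0-3")
  }
  out <- tallies |>
    dplyr::group_by(.data$quantity) |>
    dplyr::summarise(
      n_subjects = dplyr::n_distinct(.data$subject_id),
      n_ge2 = sum(.data$band1_tally >= 2),
      n_zero = sum(.data$band1_tally == 0),
      .groups = "drop"
    )
  if (any(out$n_subjects != config$n_subjects)) {
    abort_config(paste0(
      "tallies cover ", out$n_subjects[1], " subjects but the ",
      "configuration expects ", config$n_subjects
    ))
  }
  out$pass <- out$n_ge2 > config$part2_min_ge2 &
    out$n_zero <= config$part2_max_zero
  out
}

#' Grade a device-validation cohort
#'
#' Runs the full grading pipeline on a cohort of measurement sessions:
#' validation and exclusion of ungradable sessions, most-favorable paired
#' comparisons ([build_comparisons()]), band classification
#' ([classify_differences()]), the part 1 and part 2 criteria, the part 3
#' conjunction, and Bland-Altman agreement summaries
#' ([difference_summary()]).  Blood pressure is graded as a group (SBP and
#' DBP must both pass each part); heart rate is graded separately.
#'
#' @param sessions A session tibble; sessions with error-severity issues are
#'   excluded before grading.  The number of gradable sessions must equal
#'   `config$n_subjects` (the bundled thresholds are stated for 33).
#' @param config A [grading_config()].
#' @param tie_rule Tie rule for most-favorable selection; see
#'   [build_comparisons()].
#' @return An object of class `device_validation`; see [tidy()] and
#'   [glance()] methods, and [write_validation_report()].
#' @examples
#' sessions <- simulate_cohort(cohort_spec(), seed = 42)
#' report <- grade_device(sessions)
#' glance(report)
#' @export
grade_device <- function(sessions, config = grading_config(),
                         tie_rule = c("preceding", "following")) {
  stopifnot(inherits(config, "grading_config"))
  tie_rule <- match.arg(tie_rule)
  graded <- gradable_sessions(sessions)
  issues <- attr(graded, "issues")
  n_valid <- nrow(graded)
  if (n_valid == 0) {
    abort_input("no valid sessions to grade")
  }
  if (n_valid != config$n_subjects) {
    abort_config(paste0(
      n_valid, " gradable session(s) but the ", config$mode,
      "-mode thresholds are stated for ", config$n_subjects,
      " subjects; grade a matching cohort or supply a grading_config with ",
      "custom `n_subjects` and `part1_thresholds`"
    ))
  }
  attr(graded, "issues") <- NULL

  comparisons <- build_comparisons(graded, tie_rule = tie_rule)
  band_counts <- classify_differences(comparisons)
  part1 <- evaluate_part1(band_counts, config)
  tallies <- subject_band1_tally(comparisons)
  part2 <- evaluate_part2(tallies, config)
  agreement <- difference_summary(comparisons)

  p1 <- function(q) part1$pass[part1$quantity == q]
  p2 <- function(q) part2$pass[part2$quantity == q]
  summary <- tibble(
    group = c("bp", "hr"),
    part1_pass = c(p1("sbp") && p1("dbp"), p1("hr")),
    part2_pass = c(p2("sbp") && p2("dbp"), p2("hr"))
  )
  summary$part3_pass <- summary$part1_pass & summary$part2_pass

  structure(
    list(
      n_subjects = n_valid,
      config = config,
      issues = issues,
      comparisons = comparisons,
      band_counts = band_counts,
      part1 = part1,
      tallies = tallies,
      part2 = part2,
      agreement = agreement,
      summary = summary
    ),
    class = "device_validation"
  )
}

#' @export
print.device_validation <- function(x, ...) {
  cat("ESH-IP2 device validation (", x$config$mode, " mode, ",
      x$n_subjects, " subjects)\n\n", sep = "")
  cat("Part 1 (pooled band counts of ", x$config$n_comparisons,
      " comparisons):\n", sep = "")
  print(x$part1, n = Inf)
  cat("\nPart 2 (per-subject band-1 tallies):\n")
  print(x$part2, n = Inf)
  cat("\nOverall:\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' Tidy a device-validation report
#'
#' @param x A `device_validation` object from [grade_device()].
#' @param ... Unused.
#' @return One row per quantity combining band counts, part 1 / part 2 pass
#'   flags and agreement statistics.
#' @method tidy device_validation
#' @export
tidy.device_validation <- function(x, ...) {
  x$part1 |>
    dplyr::rename(part1_pass = "pass") |>
    dplyr::left_join(
      dplyr::rename(x$part2, part2_pass = "pass"),
      by = "quantity"
    ) |>
    dplyr::left_join(x$agreement, by = "quantity")
}

#' Summarise a device-validation report in one row
#'
#' @param x A `device_validation` object.
#' @param ... Unused.
#' @return A one-row tibble with cohort size, grading mode and the part 1-3
#'   pass flags for the blood-pressure group and heart rate.
#' @method glance device_validation
#' @export
glance.device_validation <- function(x, ...) {
  s <- x$summary
  g <- function(grp, col) s[[col]][s$group == grp]
  tibble(
    n_subjects = x$n_subjects,
    mode = x$config$mode,
    bp_part1_pass = g("bp", "part1_pass"),
    bp_part2_pass = g("bp", "part2_pass"),
    bp_part3_pass = g("bp", "part3_pass"),
    hr_part1_pass = g("hr", "part1_pass"),
    hr_part2_pass = g("hr", "part2_pass"),
    hr_part3_pass = g("hr", "part3_pass")
  )
}
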