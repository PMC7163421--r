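# Fixture builders and an independent brute-force pairing oracle.

all_labels <- c("BPA", "BPB", paste0("BP", 1:7))

# One wide session row from per-label reading vectors (protocol order).
session_row <- function(subject_id = "S01", sex = "male", age = 60L,
                        arm = 265, arm_side = "right",
                        sbp = rep(120L, 9), dbp = rep(80L, 9),
                        hr = rep(70L, 9)) {
  row <- tibble::tibble(
    subject_id = subject_id, sex = sex, age = as.integer(age),
    arm_circumference_mm = as.numeric(arm), measurement_arm = arm_side
  )
  for (i in seq_along(all_labels)) {
    row[[paste0(all_labels[i], "_sbp")]] <- as.integer(sbp[i])
    row[[paste0(all_labels[i], "_dbp")]] <- as.integer(dbp[i])
    row[[paste0(all_labels[i], "_hr")]] <- as.integer(hr[i])
  }
  row
}

# n subjects whose nine readings are identical within subject: every graded
# difference is exactly zero.
perfect_cohort <- function(n = 33) {
  purrr::map_dfr(seq_len(n), function(i) {
    session_row(
      subject_id = sprintf("S%02d", i),
      sex = if (i %% 2 == 0) "female" else "male",
      age = 47L + (i %% 40),
      sbp = rep(110L + i, 9),
      dbp = rep(55L + i, 9),
      hr = rep(58L + i, 9)
    )
  })
}

# Random integer sessions spanning the device ranges (dbp kept below sbp).
random_sessions <- function(n) {
  purrr::map_dfr(seq_len(n), function(i) {
    sbp <- sample(90:200, 9, replace = TRUE)
    session_row(
      subject_id = sprintf("R%04d", i),
      sbp = sbp,
      dbp = pmin(sample(40:120, 9, replace = TRUE), sbp - 1L),
      hr = sample(40:180, 9, replace = TRUE)
    )
  })
}

# Brute-force oracle: for one session row and quantity, enumerate both
# flanking candidates per slot and keep the minimum absolute difference
# (tie -> preceding).  Deliberately loop-based and independent of the
# vectorised implementation.
oracle_comparisons <- function(row, quantity, tie_rule = "preceding") {
  slots <- list(
    list(slot = 1L, test = "BP2", before = "BP1", after = "BP3"),
    list(slot = 2L, test = "BP4", before = "BP3", after = "BP5"),
    list(slot = 3L, test = "BP6", before = "BP5", after = "BP7")
  )
  out <- NULL
  for (s in slots) {
    test_v <- row[[paste0(s$test, "_", quantity)]]
    cand <- c(before = row[[paste0(s$before, "_", quantity)]],
              after = row[[paste0(s$after, "_", quantity)]])
    diffs <- test_v - cand
    pick <- if (abs(diffs["before"]) < abs(diffs["after"])) {
      "before"
    } else if (abs(diffs["after"]) < abs(diffs["before"])) {
      "after"
    } else if (tie_rule == "preceding") "before" else "after"
    out <- rbind(out, data.frame(
      slot = s$slot,
      chosen_reference = unname(cand[pick]),
      difference = unname(diffs[pick])
    ))
  }
  out
}

# Minimal comparisons tibble from raw differences (one subject, 3 slots per
# quantity) for exercising classification and tallies directly.
comparisons_from_differences <- function(differences, quantity,
                                         subject_id = "S01") {
  n <- length(differences)
  tibble::tibble(
    subject_id = rep(subject_id, n),
    quantity = quantity,
    slot = rep_len(1:3, n),
    difference = as.numeric(differences)
  )
}

# Full-cohort comparisons tibble from a 33 x 3 matrix of differences.
cohort_comparisons <- function(diff_matrix, quantity) {
  purrr::map_dfr(seq_len(nrow(diff_matrix)), function(i) {
    comparisons_from_differences(diff_matrix[i, ], quantity,
                                 subject_id = sprintf("S%02d", i))
  })
}

# Part-2 tally fixture: a tallies tibble with given numbers of subjects
# having >=2, exactly 1, and 0 band-1 comparisons.
tallies_fixture <- function(n_ge2, n_one, n_zero, quantity = "sbp") {
  values <- c(rep(2L, n_ge2), rep(1L, n_one), rep(0L, n_zero))
  tibble::tibble(
    subject_id = sprintf("S%02d", seq_along(values)),
    quantity = quantity,
    band1_tally = values
  )
}
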