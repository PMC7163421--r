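# Most-favorable paired comparisons.  Each test reading (BP2, BP4, BP6) is
# compared against both flanking reference readings (BP1/BP3, BP3/BP5,
# BP5/BP7); the flanking reading giving the smaller absolute difference is
# retained, so each subject contributes exactly three comparisons per
# quantity (99 in a 33-subject cohort).

comparison_slots <- function() {
  tibble(
    slot = 1:3,
    test_label = c("BP2", "BP4", "BP6"),
    before_label = c("BP1", "BP3", "BP5"),
    after_label = c("BP3", "BP5", "BP7")
  )
}

#' Build most-favorable paired comparisons
#'
#' For each subject, quantity and test slot, computes the signed difference
#' `test - reference` against both flanking reference readings and keeps the
#' flanking reading with the smaller absolute difference.  When the two
#' candidates tie in absolute value, `tie_rule` decides: `"preceding"` (the
#' default) keeps the reference reading taken before the test reading.
#'
#' @param sessions A complete, valid session tibble (see
#'   [validate_sessions()]); an incomplete session is an error naming the
#'   missing reading.
#' @param quantities Quantities to compare; default all of
#'   `"sbp"`, `"dbp"`, `"hr"`.
#' @param tie_rule `"preceding"` or `"following"`.
#' @return A tibble with one row per subject x quantity x slot:
#'   `subject_id`, `quantity`, `slot`, `test_label`, `test_value`,
#'   `chosen_label`, `chosen_reference`, `alternate_reference`,
#'   `difference` (test minus chosen reference) and `alternate_difference`.
#' @examples
#' sessions <- simulate_cohort(cohort_spec(), seed = 1)
#' build_comparisons(sessions, "sbp")
#' @export
build_comparisons <- function(sessions, quantities = quantity_names(),
                              tie_rule = c("preceding", "following")) {
  tie_rule <- match.arg(tie_rule)
  quantities <- vapply(quantities, check_quantity, character(1))
  slots <- comparison_slots()

  needed_labels <- unique(c(slots$test_label, slots$before_label,
                            slots$after_label))
  for (lab in needed_labels) {
    for (q in quantities) {
      col <- paste0(lab, "_", q)
      if (!col %in% names(sessions)) {
        abort_input(paste0("sessions are missing reading column ", col))
      }
      if (anyNA(sessions[[col]])) {
        bad <- sessions$subject_id[is.na(sessions[[col]])]
        abort_input(paste0(
          "incomplete session: missing reading ", col, " for subject(s) ",
          paste(bad, collapse = ", ")
        ))
      }
    }
  }

  purrr::map_dfr(quantities, function(q) {
    purrr::map_dfr(seq_len(nrow(slots)), function(i) {
      s <- slots[i, ]
      test_v <- sessions[[paste0(s$test_label, "_", q)]]
      before_v <- sessions[[paste0(s$before_label, "_", q)]]
      after_v <- sessions[[paste0(s$after_label, "_", q)]]
      d_before <- test_v - before_v
      d_after <- test_v - after_v
      take_before <- abs(d_before) < abs(d_after) |
        (abs(d_before) == abs(d_after) & tie_rule == "preceding")
      tibble(
        subject_id = as.character(sessions$subject_id),
        quantity = q,
        slot = s$slot,
        test_label = s$test_label,
        test_value = as.numeric(test_v),
        chosen_label = ifelse(take_before, s$before_label, s$after_label),
        chosen_reference = as.numeric(ifelse(take_before, before_v, after_v)),
        alternate_reference = as.numeric(ifelse(take_before, after_v, before_v)),
        difference = as.numeric(ifelse(take_before, d_before, d_after)),
        alternate_difference = as.numeric(ifelse(take_before, d_after, d_before))
      )
    })
  }) |>
    dplyr::arrange(.data$quantity,
                   match(.data$subject_id, as.character(sessions$subject_id)),
                   .data$slot)
}

#' Count paired differences within the tolerance bands
#'
#' Classifies absolute signed differences into the three nested bands for
#' each quantity (bounds inclusive: a 5 mmHg difference is within the
#' 5 mmHg band).
#'
#' @param comparisons A comparison tibble with at least `quantity` and
#'   `difference` columns, as from [build_comparisons()].
#' @return A tibble with one row per quantity: `quantity`, `n_total`,
#'   `n_band1`, `n_band2`, `n_band3`.
#' @export
classify_differences <- function(comparisons) {
  if (nrow(comparisons) == 0) {
    abort_input("no comparisons to classify")
  }
  vapply(unique(comparisons$quantity), check_quantity, character(1))
  comparisons |>
    dplyr::group_by(.data$quantity) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_band1 = sum(abs(.data$difference) <= band_tolerances(.data$quantity[1])[1]),
      n_band2 = sum(abs(.data$difference) <= band_tolerances(.data$quantity[1])[2]),
      n_band3 = sum(abs(.data$difference) <= band_tolerances(.data$quantity[1])[3]),
      .groups = "drop"
    )
}

#' Per-subject band-1 tallies
#'
#' Counts, for each subject and quantity, how many of the subject's three
#' comparisons fall within the first band (<= 5 mmHg for pressures,
#' <= 3 bpm for heart rate).  These tallies feed the part 2 criteria.
#'
#' @param comparisons A comparison tibble (`subject_id`, `quantity`, `slot`,
#'   `difference`); every subject must contribute exactly three comparisons
#'   per quantity.
#' @return A tibble `subject_id`, `quantity`, `band1_tally` (0-3).
#' @export
subject_band1_tally <- function(comparisons) {
  vapply(unique(comparisons$quantity), check_quantity, character(1))
  tallies <- comparisons |>
    dplyr::group_by(.data$quantity, .data$subject_id) |>
    dplyr::summarise(
      n_comparisons = dplyr::n(),
      band1_tally = sum(abs(.data$difference) <=
                          band_tolerances(.data$quantity[1])[1]),
      .groups = "drop"
    )
  if (any(tallies$n_comparisons != 3)) {
    bad <- tallies[tallies$n_comparisons != 3, ]
    abort_input(paste0(
      "each subject must have exactly 3 comparisons per quantity; got ",
      bad$n_comparisons[1], " for subject ", bad$subject_id[1],
      " (", bad$quantity[1], ")"
    ))
  }
  tallies |>
    dplyr::select("subject_id", "quantity", "band1_tally")
}
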