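# Bland-Altman agreement between test and reference devices, computed on
# the same most-favorable comparisons that feed grading.

#' Summarise paired differences
#'
#' Computes, per quantity, the mean and SD (n-1 denominator) of the signed
#' differences (test minus chosen reference), the mean and SD of the
#' absolute differences, and the 95% limits of agreement
#' `mean +/- 1.96 * SD` of the signed differences.
#'
#' Both signed and absolute summaries are reported: they answer different
#' questions (systematic bias versus typical disagreement) and validation
#' reports in this field quote either.
#'
#' @param comparisons A comparison tibble with `quantity` and `difference`
#'   columns; at least two comparisons per quantity (the SD is undefined
#'   below that).
#' @return A tibble with one row per quantity: `n`,
#'   `mean_signed_difference`, `sd_signed_difference`,
#'   `mean_absolute_difference`, `sd_absolute_difference`, `loa_low`,
#'   `loa_high`.
#' @export
difference_summary <- function(comparisons) {
  if (nrow(comparisons) == 0) {
    abort_input("no comparisons to summarise")
  }
  vapply(unique(comparisons$quantity), check_quantity, character(1))
  counts <- table(comparisons$quantity)
  if (any(counts < 2)) {
    abort_input(paste0(
      "at least 2 comparisons per quantity are required (",
      names(counts)[counts < 2][1], " has ", min(counts), ")"
    ))
  }
  comparisons |>
    dplyr::group_by(.data$quantity) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_signed_difference = mean(.data$difference),
      sd_signed_difference = sd(.data$difference),
      mean_absolute_difference = mean(abs(.data$difference)),
      sd_absolute_difference = sd(abs(.data$difference)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      loa_low = .data$mean_signed_difference -
        1.96 * .data$sd_signed_difference,
      loa_high = .data$mean_signed_difference +
        1.96 * .data$sd_signed_difference
    )
}

#' Bland-Altman points and agreement statistics
#'
#' One point per comparison: the pair mean `(test + chosen reference) / 2`
#' on the x-axis against the signed difference `test - chosen reference` on
#' the y-axis, with the mean difference and 95% limits of agreement as
#' reference lines.  Uses the chosen (most-favorable) reference so the plot
#' displays exactly the differences that were graded.
#'
#' @param comparisons A comparison tibble from [build_comparisons()].
#' @return An object of class `bland_altman`: a list with `points` (tibble
#'   `subject_id`, `quantity`, `slot`, `pair_mean`, `difference`) and
#'   `stats` (the [difference_summary()] tibble).  Has [autoplot()] and
#'   [tidy()] methods.
#' @examples
#' sessions <- simulate_cohort(cohort_spec(), seed = 7)
#' ba <- bland_altman(build_comparisons(sessions))
#' head(tidy(ba))
#' @export
bland_altman <- function(comparisons) {
  required <- c("subject_id", "quantity", "slot", "test_value",
                "chosen_reference", "difference")
  missing_cols <- setdiff(required, names(comparisons))
  if (length(missing_cols) > 0) {
    abort_input(paste0("comparisons missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  stats <- difference_summary(comparisons)
  points <- comparisons |>
    dplyr::transmute(
      subject_id = .data$subject_id,
      quantity = .data$quantity,
      slot = .data$slot,
      pair_mean = (.data$test_value + .data$chosen_reference) / 2,
      difference = .data$difference
    )
  structure(list(points = points, stats = stats), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman agreement (", nrow(x$points), " points)\n", sep = "")
  print(x$stats)
  invisible(x)
}

#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) x$points

#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) x$stats

#' Bland-Altman plot
#'
#' Difference against pair mean, faceted by quantity, with the mean
#' difference (solid) and 95% limits of agreement (dashed) drawn per facet.
#'
#' @param object A `bland_altman` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  lines <- object$stats |>
    tidyr::pivot_longer(
      c("mean_signed_difference", "loa_low", "loa_high"),
      names_to = "line", values_to = "y"
    ) |>
    dplyr::mutate(style = ifelse(.data$line == "mean_signed_difference",
                                 "mean", "loa"))
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$pair_mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(
      data = lines,
      ggplot2::aes(yintercept = .data$y, linetype = .data$style)
    ) +
    ggplot2::scale_linetype_manual(
      values = c(mean = "solid", loa = "dashed"), guide = "none"
    ) +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::labs(
      x = "Pair mean (test + reference) / 2",
      y = "Difference (test - reference)",
      title = "Bland-Altman agreement",
      subtitle = "Solid: mean difference; dashed: 95% limits of agreement"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.bland_altman
#' @param comparisons A comparison tibble from [build_comparisons()].
#' @export
plot_bland_altman <- function(comparisons) {
  autoplot(bland_altman(comparisons))
}
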