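# JSON serialization of validation reports.
#
# Layout: {"n_subjects", "mode", "quantities": {sbp: {band_counts, part1,
# part2, agreement}, ...}, "groups": {bp: {part1_pass, part2_pass,
# part3_pass}, hr: {...}}}.

report_to_list <- function(report) {
  stopifnot(inherits(report, "device_validation"))
  q_entry <- function(q) {
    p1 <- report$part1[report$part1$quantity == q, ]
    p2 <- report$part2[report$part2$quantity == q, ]
    agr <- report$agreement[report$agreement$quantity == q, ]
    list(
      band_counts = list(
        n_total = p1$n_total, n_band1 = p1$n_band1,
        n_band2 = p1$n_band2, n_band3 = p1$n_band3
      ),
      part1 = list(
        band1_pass = p1$band1_pass, band2_pass = p1$band2_pass,
        band3_pass = p1$band3_pass, pass = p1$pass
      ),
      part2 = list(n_ge2 = p2$n_ge2, n_zero = p2$n_zero, pass = p2$pass),
      agreement = as.list(agr[setdiff(names(agr), "quantity")])
    )
  }
  g_entry <- function(g) {
    s <- report$summary[report$summary$group == g, ]
    list(part1_pass = s$part1_pass, part2_pass = s$part2_pass,
         part3_pass = s$part3_pass)
  }
  quantities <- report$part1$quantity
  list(
    n_subjects = report$n_subjects,
    mode = report$config$mode,
    quantities = stats::setNames(lapply(quantities, q_entry), quantities),
    groups = list(bp = g_entry("bp"), hr = g_entry("hr"))
  )
}

#' Write a validation report as JSON
#'
#' @param report A `device_validation` object from [grade_device()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_validation_report()]
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a validation report written by [write_validation_report()]
#'
#' Reconstructs the tabular components of the report (band counts, part 1,
#' part 2, group summary and agreement statistics).  The per-comparison
#' detail is not serialized; export it with [readr::write_csv()] on the
#' `comparisons` element instead.
#'
#' @param path Path to a report JSON file.
#' @return An object of class `device_validation_summary` with elements
#'   `n_subjects`, `mode`, `part1`, `part2`, `agreement` and `summary`,
#'   shaped like the corresponding `device_validation` elements.
#' @export
read_validation_report <- function(path) {
  if (!file.exists(path)) {
    abort_input(paste0("report file not found: ", path))
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  quantities <- names(x$quantities)
  row_for <- function(q, section) {
    as_tibble(c(list(quantity = q), x$quantities[[q]][[section]]))
  }
  part1 <- purrr::map_dfr(quantities, function(q) {
    dplyr::bind_cols(row_for(q, "band_counts")["quantity"],
                     row_for(q, "band_counts")[-1],
                     row_for(q, "part1")[-1])
  })
  part2 <- purrr::map_dfr(quantities, function(q) row_for(q, "part2"))
  agreement <- purrr::map_dfr(quantities, function(q) row_for(q, "agreement"))
  summary <- purrr::map_dfr(names(x$groups), function(g) {
    as_tibble(c(list(group = g), x$groups[[g]]))
  })
  structure(
    list(
      n_subjects = x$n_subjects,
      mode = x$mode,
      part1 = part1,
      part2 = part2,
      agreement = agreement,
      summary = summary
    ),
    class = "device_validation_summary"
  )
}
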