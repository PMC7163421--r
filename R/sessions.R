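# Session data model: one row per subject, five metadata columns and a
# 27-column block of labelled readings (L_sbp, L_dbp, L_hr for each of the
# nine labels BPA, BPB, BP1..BP7).

new_issues <- function(subject_id = character(), field = character(),
                       severity = character(), message = character()) {
  tibble(
    subject_id = as.character(subject_id),
    field = as.character(field),
    severity = as.character(severity),
    message = as.character(message)
  )
}

issue <- function(subject_id, field, severity, message) {
  new_issues(subject_id, field, severity, message)
}

#' Read measurement sessions from CSV
#'
#' Reads a session table written in the package's CSV schema: columns
#' `subject_id`, `sex`, `age`, `arm_circumference_mm`, `measurement_arm`,
#' then `L_sbp`, `L_dbp`, `L_hr` for each reading label `L` in
#' BPA, BPB, BP1..BP7, one row per subject.
#'
#' Malformed cells never crash the read: a non-integer reading value becomes
#' `NA` and is recorded as an error-severity parse issue retrievable with
#' [session_parse_issues()].  [validate_sessions()] folds parse issues into
#' its result, so sessions affected by them are excluded from grading.
#'
#' @param path Path to a CSV file.
#' @return A tibble of sessions (readings as integers) with a
#'   `"parse_issues"` attribute.
#' @seealso [write_sessions()], [validate_sessions()]
#' @export
read_sessions <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort_input(paste0("session file not found: ", path))
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing_cols <- setdiff(session_columns(), names(raw))
  if (length(missing_cols) > 0) {
    abort_input(paste0(
      "session file is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  raw <- raw[session_columns()]

  issues <- new_issues()
  subject_ids <- raw$subject_id
  parse_int_col <- function(values, field) {
    trimmed <- trimws(values)
    ok <- is.na(trimmed) | grepl("^-?[0-9]+$", trimmed)
    bad <- which(!ok)
    if (length(bad) > 0) {
      issues <<- dplyr::bind_rows(issues, issue(
        subject_ids[bad], field, "error",
        paste0("non-integer value '", trimmed[bad], "' in ", field)
      ))
    }
    out <- rep(NA_integer_, length(values))
    out[ok] <- suppressWarnings(as.integer(trimmed[ok]))
    out
  }

  sessions <- tibble(
    subject_id = as.character(raw$subject_id),
    sex = as.character(raw$sex),
    age = parse_int_col(raw$age, "age"),
    arm_circumference_mm = {
      num <- suppressWarnings(as.numeric(raw$arm_circumference_mm))
      bad <- which(is.na(num) & !is.na(raw$arm_circumference_mm))
      if (length(bad) > 0) {
        issues <- dplyr::bind_rows(issues, issue(
          subject_ids[bad], "arm_circumference_mm", "error",
          "non-numeric arm circumference"
        ))
      }
      num
    },
    measurement_arm = as.character(raw$measurement_arm)
  )
  for (col in reading_columns()) {
    sessions[[col]] <- parse_int_col(raw[[col]], col)
  }
  attr(sessions, "parse_issues") <- issues
  sessions
}

#' Parse issues recorded while reading a session file
#'
#' @param sessions A tibble returned by [read_sessions()].
#' @return A tibble of issues (`subject_id`, `field`, `severity`, `message`);
#'   empty if the file parsed cleanly or the sessions were built in code.
#' @export
session_parse_issues <- function(sessions) {
  attr(sessions, "parse_issues") %||% new_issues()
}

#' Write measurement sessions to CSV
#'
#' Writes the package's session CSV schema (see [read_sessions()]).
#' `read_sessions(write_sessions(x, path))` reproduces `x` field for field.
#'
#' @param sessions A session tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  missing_cols <- setdiff(session_columns(), names(sessions))
  if (length(missing_cols) > 0) {
    abort_input(paste0(
      "sessions are missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  out <- sessions[session_columns()]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate measurement sessions
#'
#' Checks every session against the data-model invariants: all nine labelled
#' readings present; systolic and diastolic pressure within the 0-300 mmHg
#' device range; heart rate within 40-180 bpm; diastolic strictly below
#' systolic in every reading; sex one of male/female; age at least 25 years
#' (the protocol's inclusion rule); positive arm circumference; measurement
#' arm left or right.  Parse issues attached by [read_sessions()] are
#' included in the result.
#'
#' Issues are data, not exceptions: a session with any error-severity issue
#' is ungradable and is dropped by [grade_device()], mirroring whole-subject
#' exclusion for device failure rather than partial grading.
#'
#' @param sessions A session tibble.
#' @return A tibble of issues; zero rows iff every session is gradable.
#' @export
validate_sessions <- function(sessions) {
  issues <- list(session_parse_issues(sessions))
  n <- nrow(sessions)
  if (n == 0) {
    return(new_issues())
  }
  id <- as.character(sessions$subject_id)

  add <- function(idx, field, severity, message) {
    if (length(idx) > 0) {
      issues[[length(issues) + 1]] <<- issue(id[idx], field, severity, message)
    }
  }

  bad_sex <- which(is.na(sessions$sex) | !sessions$sex %in% c("male", "female"))
  add(bad_sex, "sex", "error", "sex must be 'male' or 'female'")
  add(which(is.na(sessions$age)), "age", "error", "missing age")
  add(which(!is.na(sessions$age) & sessions$age < 25), "age", "error",
      "age below the 25-year inclusion threshold")
  add(which(is.na(sessions$arm_circumference_mm)),
      "arm_circumference_mm", "error", "missing arm circumference")
  add(which(!is.na(sessions$arm_circumference_mm) &
              sessions$arm_circumference_mm <= 0),
      "arm_circumference_mm", "error", "arm circumference must be positive")
  bad_arm <- which(is.na(sessions$measurement_arm) |
                     !sessions$measurement_arm %in% c("left", "right"))
  add(bad_arm, "measurement_arm", "error",
      "measurement arm must be 'left' or 'right'")

  for (lab in session_labels()) {
    for (q in quantity_names()) {
      col <- paste0(lab, "_", q)
      v <- sessions[[col]]
      add(which(is.na(v)), col, "error", paste0("missing reading ", col))
      lim <- reading_limits(q)
      add(which(!is.na(v) & (v < lim[1] | v > lim[2])), col, "error",
          paste0(col, " outside device range ", lim[1], "-", lim[2],
                 " ", quantity_units(q)))
    }
    s <- sessions[[paste0(lab, "_sbp")]]
    d <- sessions[[paste0(lab, "_dbp")]]
    add(which(!is.na(s) & !is.na(d) & d >= s), paste0(lab, "_dbp"), "error",
        paste0("diastolic not below systolic in reading ", lab))
  }
  dplyr::bind_rows(issues)
}

#' Identify sessions eligible for grading
#'
#' @param sessions A session tibble.
#' @return The subset of `sessions` whose subjects have no error-severity
#'   validation issue, with the issues attached as attribute `"issues"`.
#' @export
gradable_sessions <- function(sessions) {
  issues <- validate_sessions(sessions)
  bad <- unique(issues$subject_id[issues$severity == "error"])
  out <- sessions[!sessions$subject_id %in% bad, , drop = FALSE]
  attr(out, "parse_issues") <- NULL
  attr(out, "issues") <- issues
  out
}

#' Write session issues as JSON lines
#'
#' One JSON object per line: `{subject_id, field, severity, message}`.
#'
#' @param issues An issues tibble, as from [validate_sessions()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_issues <- function(issues, path) {
  lines <- vapply(seq_len(nrow(issues)), function(i) {
    jsonlite::toJSON(as.list(issues[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Select the cuff for an arm circumference
#'
#' The reference device offers a standard cuff (22-32 cm) and a large cuff
#' (32-42 cm); the boundary 320 mm is assigned to the standard cuff.  The
#' test device has a single universal cuff covering 22-42 cm.
#'
#' @param arm_circumference_mm Arm circumference(s) in millimetres.
#' @param device `"reference"` or `"test"`.
#' @return Character vector of cuff labels: `"standard"`, `"large"` or
#'   `"universal"`.  Errors if any circumference falls outside the device's
#'   supported range.
#' @examples
#' select_cuff(265, "reference")
#' select_cuff(350, "reference")
#' select_cuff(350, "test")
#' @export
select_cuff <- function(arm_circumference_mm, device = c("reference", "test")) {
  device <- match.arg(device)
  x <- arm_circumference_mm
  if (any(is.na(x)) || any(x <= 0)) {
    abort_input("arm circumference must be positive and non-missing")
  }
  out_of_range <- x < 220 | x > 420
  if (any(out_of_range)) {
    abort_input(paste0(
      "arm circumference ", paste(x[out_of_range], collapse = ", "),
      " mm outside the ", device, " device cuff range 220-420 mm"
    ))
  }
  if (device == "test") {
    rep("universal", length(x))
  } else {
    ifelse(x <= 320, "standard", "large")
  }
}
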