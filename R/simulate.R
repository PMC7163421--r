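# Synthetic paired-device cohorts.
#
# Latent model: subject s has baseline true values (SBP, DBP, HR) drawn
# uniformly within paired recruitment strata; the true value at reading
# index k (0-based, protocol order BPA..BP7) is
#   baseline + drift * k + within-subject noise,
# i.e. a linear within-session trend (seated BP drifts slightly downwards
# over the rest sequence) plus independent reading-to-reading variation.
# Each reading is observed through its device's error model:
#   observed = round((1 + proportional_bias) * true + bias + noise),
# then clamped to the device display range; a diastolic reading that meets
# or exceeds its systolic companion after rounding is pulled to systolic - 1
# (counted as a clamp event).
#
# Randomness: one L'Ecuyer-CMRG stream per seed, split into two substreams
# per subject (truth, session noise) with parallel::nextRNGStream, so
# enlarging the cohort never reshuffles earlier subjects.

#' Cohort specification for the synthetic-session simulator
#'
#' Defaults emulate the hemodialysis validation cohort the grading
#' thresholds are stated for: 33 subjects, at least 10 of each sex, ages
#' 47-88 years, arm circumferences 220-350 mm, and recruitment-style
#' pressure strata (low / medium / high thirds).  The truth strata are
#' simulator defaults — uniform within plausible ranges — not estimates of
#' any particular study population.
#'
#' SBP and DBP strata are paired by position (a subject in the k-th SBP
#' stratum is in the k-th DBP stratum), which keeps pulse pressure positive
#' by construction when each DBP upper bound sits below its SBP lower
#' bound.
#'
#' @param n_subjects Cohort size (default 33).
#' @param min_males,min_females Minimum count of each sex (defaults 10).
#' @param age_range Integer age range in years (default 47-88).
#' @param arm_circumference_range Arm circumference range in mm
#'   (default 220-350).
#' @param sbp_strata,dbp_strata Tibbles with columns `lower`, `upper`,
#'   `count` giving baseline truth strata; counts must sum to `n_subjects`
#'   and the two tables must align row for row.
#' @param hr_range Baseline heart-rate range in bpm (default 55-95).
#' @param drift Named numeric: per-reading-index drift of the true value,
#'   in mmHg (or bpm) per reading (defaults `sbp = -0.5`, `dbp = -0.3`,
#'   `hr = -0.2`).
#' @param within_sd Named numeric: within-subject reading-to-reading SD
#'   (defaults `sbp = 4`, `dbp = 3`, `hr = 2`).
#' @param prob_left_arm Probability a subject is measured on the left arm
#'   (default 2/33, the typical fistula-driven exception rate in a dialysis
#'   cohort).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 33,
                        min_males = 10, min_females = 10,
                        age_range = c(47, 88),
                        arm_circumference_range = c(220, 350),
                        sbp_strata = tibble(
                          lower = c(90, 130, 161),
                          upper = c(129, 160, 180),
                          count = strata_counts(n_subjects)
                        ),
                        dbp_strata = tibble(
                          lower = c(40, 80, 101),
                          upper = c(79, 100, 130),
                          count = strata_counts(n_subjects)
                        ),
                        hr_range = c(55, 95),
                        drift = c(sbp = -0.5, dbp = -0.3, hr = -0.2),
                        within_sd = c(sbp = 4, dbp = 3, hr = 2),
                        prob_left_arm = 2 / 33) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1) {
    abort_config("`n_subjects` must be a positive integer")
  }
  if (min_males + min_females > n_subjects) {
    abort_config("`min_males` + `min_females` exceeds `n_subjects`")
  }
  check_range <- function(r, what) {
    if (length(r) != 2 || anyNA(r) || r[1] > r[2]) {
      abort_config(paste0("`", what, "` must be a nonempty (lo, hi) range"))
    }
  }
  check_range(age_range, "age_range")
  check_range(arm_circumference_range, "arm_circumference_range")
  check_range(hr_range, "hr_range")
  check_strata <- function(s, what) {
    if (!all(c("lower", "upper", "count") %in% names(s))) {
      abort_config(paste0("`", what,
                          "` needs columns lower, upper, count"))
    }
    if (any(s$lower > s$upper)) {
      abort_config(paste0("`", what, "` has an empty stratum range"))
    }
    if (sum(s$count) != n_subjects) {
      abort_config(paste0("`", what, "` counts must sum to n_subjects (",
                          n_subjects, "), got ", sum(s$count)))
    }
  }
  check_strata(sbp_strata, "sbp_strata")
  check_strata(dbp_strata, "dbp_strata")
  if (nrow(sbp_strata) != nrow(dbp_strata) ||
      any(sbp_strata$count != dbp_strata$count)) {
    abort_config("`sbp_strata` and `dbp_strata` must align row for row")
  }
  take <- function(x, default) {
    out <- default
    out[names(x)] <- x
    if (any(is.na(out))) abort_config("drift/within_sd must be named numeric")
    out
  }
  drift <- take(drift, c(sbp = 0, dbp = 0, hr = 0))
  within_sd <- take(within_sd, c(sbp = 0, dbp = 0, hr = 0))
  if (any(within_sd < 0)) abort_config("`within_sd` must be nonnegative")

  structure(
    list(
      n_subjects = n_subjects,
      min_males = min_males, min_females = min_females,
      age_range = age_range,
      arm_circumference_range = arm_circumference_range,
      sbp_strata = sbp_strata, dbp_strata = dbp_strata,
      hr_range = hr_range,
      drift = drift, within_sd = within_sd,
      prob_left_arm = prob_left_arm
    ),
    class = "cohort_spec"
  )
}

# Split n as evenly as possible over three strata (the recruitment pattern:
# a third of the cohort in each pressure category).
strata_counts <- function(n, k = 3) {
  base <- n %/% k
  extra <- n %% k
  base + c(rep(1, extra), rep(0, k - extra))
}

#' Device error model
#'
#' Observation model for one device: each reading is
#' `round((1 + proportional_bias) * true + bias + noise)` with
#' `noise ~ N(0, noise_sd)`, then clamped to the device display range.
#' Parameters may be scalars (applied to all quantities) or named vectors
#' with any of `sbp`, `dbp`, `hr`.
#'
#' @param bias Additive bias, mmHg or bpm (default 0).
#' @param proportional_bias Fractional bias relative to the true value
#'   (default 0).
#' @param noise_sd Observation noise SD, must be nonnegative (default 0).
#' @return An object of class `device_error_model` holding per-quantity
#'   parameter vectors.
#' @examples
#' device_error_model()                             # ideal device
#' device_error_model(bias = c(sbp = 3, dbp = 2), noise_sd = 2)
#' @export
device_error_model <- function(bias = 0, proportional_bias = 0,
                               noise_sd = 0) {
  expand <- function(x, what) {
    if (is.null(names(x))) {
      if (length(x) != 1) {
        abort_config(paste0("unnamed `", what, "` must be a scalar"))
      }
      x <- c(sbp = x[[1]], dbp = x[[1]], hr = x[[1]])
    } else {
      full <- c(sbp = 0, dbp = 0, hr = 0)
      extra <- setdiff(names(x), names(full))
      if (length(extra) > 0) {
        abort_config(paste0("unknown quantity in `", what, "`: ", extra[1]))
      }
      full[names(x)] <- x
      x <- full
    }
    x
  }
  noise_sd <- expand(noise_sd, "noise_sd")
  if (any(noise_sd < 0)) abort_config("`noise_sd` must be nonnegative")
  structure(
    list(
      bias = expand(bias, "bias"),
      proportional_bias = expand(proportional_bias, "proportional_bias"),
      noise_sd = noise_sd
    ),
    class = "device_error_model"
  )
}

# ---- seeded stream plumbing -------------------------------------------------

rng_streams <- function(seed, n) {
  seed <- as.integer(seed)
  if (is.na(seed)) abort_config("`seed` must be an integer")
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
  set.seed(seed)
  streams <- vector("list", n)
  s <- get(".Random.seed", globalenv())
  for (i in seq_len(n)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

with_stream <- function(stream, expr) {
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  assign(".Random.seed", stream, envir = globalenv())
  expr
}

# ---- truth ------------------------------------------------------------------

runif_int <- function(n, lo, hi) as.integer(floor(runif(n, lo, hi + 1)))

# Round-robin assignment over strata, honouring the per-stratum counts.
# Unlike a block assignment, subject i's stratum does not depend on how
# many subjects follow, so enlarging a cohort leaves earlier subjects'
# simulated records untouched.
stratum_assignment <- function(counts) {
  k <- length(counts)
  remaining <- counts
  out <- integer(sum(counts))
  j <- 0L
  for (i in seq_along(out)) {
    repeat {
      j <- j %% k + 1L
      if (remaining[j] > 0) break
    }
    out[i] <- j
    remaining[j] <- remaining[j] - 1L
  }
  out
}

simulate_truth_impl <- function(spec, streams) {
  n <- spec$n_subjects
  stratum_of <- stratum_assignment(spec$sbp_strata$count)
  purrr::map_dfr(seq_len(n), function(i) {
    with_stream(streams[[i]], {
      sex <- if (i <= spec$min_males) {
        "male"
      } else if (i <= spec$min_males + spec$min_females) {
        "female"
      } else {
        if (rbinom(1, 1, 0.5) == 1) "male" else "female"
      }
      k <- stratum_of[i]
      tibble(
        subject_id = sprintf("S%03d", i),
        sex = sex,
        age = runif_int(1, spec$age_range[1], spec$age_range[2]),
        arm_circumference_mm = runif_int(1, spec$arm_circumference_range[1],
                                         spec$arm_circumference_range[2]),
        measurement_arm = if (rbinom(1, 1, spec$prob_left_arm) == 1) {
          "left"
        } else "right",
        sbp_baseline = runif(1, spec$sbp_strata$lower[k],
                             spec$sbp_strata$upper[k]),
        dbp_baseline = runif(1, spec$dbp_strata$lower[k],
                             spec$dbp_strata$upper[k]),
        hr_baseline = runif(1, spec$hr_range[1], spec$hr_range[2]),
        sbp_drift = spec$drift[["sbp"]],
        dbp_drift = spec$drift[["dbp"]],
        hr_drift = spec$drift[["hr"]],
        sbp_within_sd = spec$within_sd[["sbp"]],
        dbp_within_sd = spec$within_sd[["dbp"]],
        hr_within_sd = spec$within_sd[["hr"]]
      )
    })
  })
}

#' Simulate subject truth and metadata
#'
#' Draws the latent per-subject state (baselines, drift, within-subject SD)
#' and metadata for a cohort.  Deterministic given `seed`, and subject `i`
#' is unchanged when `n_subjects` grows (per-subject RNG substreams).
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A tibble with one row per subject.
#' @export
simulate_subject_truth <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  streams <- rng_streams(seed, 2L * spec$n_subjects)
  simulate_truth_impl(spec, streams[seq(1, 2L * spec$n_subjects, by = 2)])
}

# ---- sessions ---------------------------------------------------------------

# One session from one truth row, drawing from the current RNG state.
# Returns a one-row wide tibble plus a clamp-event count attribute.
sim_session_impl <- function(truth, reference_model, test_model) {
  labels <- session_labels()
  k <- seq_along(labels) - 1    # 0-based reading index, protocol order
  is_test <- label_device_role(labels) == "test"
  clamps <- 0L

  obs <- list()
  for (q in quantity_names()) {
    true_q <- truth[[paste0(q, "_baseline")]] +
      truth[[paste0(q, "_drift")]] * k +
      rnorm(length(k), 0, truth[[paste0(q, "_within_sd")]])
    prop <- ifelse(is_test, test_model$proportional_bias[[q]],
                   reference_model$proportional_bias[[q]])
    bias <- ifelse(is_test, test_model$bias[[q]],
                   reference_model$bias[[q]])
    noise_sd <- ifelse(is_test, test_model$noise_sd[[q]],
                       reference_model$noise_sd[[q]])
    v <- round((1 + prop) * true_q + bias + rnorm(length(k), 0, noise_sd))
    lim <- reading_limits(q)
    clamped <- pmin(pmax(v, lim[1]), lim[2])
    clamps <- clamps + sum(clamped != v)
    obs[[q]] <- as.integer(clamped)
  }
  # physical constraint: diastolic below systolic in every reading
  bad <- obs$dbp >= obs$sbp
  if (any(bad)) {
    clamps <- clamps + sum(bad)
    obs$dbp[bad] <- obs$sbp[bad] - 1L
  }

  row <- tibble(
    subject_id = truth$subject_id,
    sex = truth$sex,
    age = as.integer(truth$age),
    arm_circumference_mm = as.numeric(truth$arm_circumference_mm),
    measurement_arm = truth$measurement_arm
  )
  for (j in seq_along(labels)) {
    for (q in quantity_names()) {
      row[[paste0(labels[j], "_", q)]] <- obs[[q]][j]
    }
  }
  attr(row, "clamp_events") <- clamps
  row
}

#' Simulate one measurement session
#'
#' Generates the nine protocol readings (BPA, BPB, BP1..BP7) for a single
#' subject, observing the latent trajectory through each device's error
#' model; see [cohort_spec()] for the latent model.
#'
#' @param truth A one-row truth tibble from [simulate_subject_truth()].
#' @param reference_model,test_model [device_error_model()] objects for the
#'   reference and test devices.
#' @param seed Integer seed.
#' @return A one-row session tibble.
#' @export
simulate_session <- function(truth,
                             reference_model = device_error_model(),
                             test_model = device_error_model(),
                             seed = 1L) {
  stopifnot(inherits(reference_model, "device_error_model"),
            inherits(test_model, "device_error_model"))
  if (nrow(truth) != 1) {
    abort_input("`truth` must be a single subject (one row)")
  }
  streams <- rng_streams(seed, 1L)
  with_stream(streams[[1]],
              sim_session_impl(truth, reference_model, test_model))
}

#' Simulate a full validation cohort
#'
#' One session per subject, composable with [grade_device()] and
#' [write_sessions()].  Deterministic given `seed`; per-subject substreams
#' mean subject `i`'s session does not depend on the cohort size.  Readings
#' clamped to device ranges are counted in the `"clamp_events"` attribute
#' and reported via a message when any occur.
#'
#' @param spec A [cohort_spec()].
#' @param reference_model,test_model [device_error_model()] objects.
#' @param seed Integer seed.
#' @return A session tibble with `spec$n_subjects` rows.
#' @examples
#' sessions <- simulate_cohort(cohort_spec(), seed = 1)
#' nrow(sessions)
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            reference_model = device_error_model(),
                            test_model = device_error_model(),
                            seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(reference_model, "device_error_model"),
            inherits(test_model, "device_error_model"))
  n <- spec$n_subjects
  streams <- rng_streams(seed, 2L * n)
  truth <- simulate_truth_impl(spec, streams[seq(1, 2L * n, by = 2)])
  clamps <- 0L
  sessions <- purrr::map_dfr(seq_len(n), function(i) {
    row <- with_stream(streams[[2L * i]],
                       sim_session_impl(truth[i, ], reference_model,
                                        test_model))
    clamps <<- clamps + attr(row, "clamp_events")
    row
  })
  if (clamps > 0) {
    inform(paste0(clamps, " simulated reading(s) clamped to device range"))
  }
  attr(sessions, "clamp_events") <- clamps
  attr(sessions, "truth") <- truth
  sessions
}

# ---- operating characteristics ---------------------------------------------

#' Estimate the protocol pass probability by Monte Carlo
#'
#' Repeatedly simulates a cohort under the given device error models,
#' grades each replicate with [grade_device()], and estimates the
#' probability that the device passes part 3 (overall validation) for the
#' chosen quantity group, with a Wilson 95% binomial confidence interval.
#'
#' The 33-subject design is small; this estimator makes its operating
#' characteristics explicit — a device with a borderline error model can
#' have a pass probability far from 0 or 1.
#'
#' @param spec A [cohort_spec()].
#' @param reference_model,test_model [device_error_model()] objects.
#' @param n_replicates Number of simulated validation studies (>= 1).
#' @param seed Integer seed; replicate seeds are derived from it.
#' @param config A [grading_config()].
#' @param group `"bp"` (default) or `"hr"`: which part 3 decision to count.
#' @return A one-row tibble: `n_replicates`, `n_passes`, `estimate`,
#'   `conf_low`, `conf_high`.
#' @export
estimate_pass_probability <- function(spec = cohort_spec(),
                                      reference_model = device_error_model(),
                                      test_model = device_error_model(),
                                      n_replicates = 100,
                                      seed = 1L,
                                      config = grading_config(),
                                      group = c("bp", "hr")) {
  group <- match.arg(group)
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1) {
    abort_config("`n_replicates` must be >= 1")
  }
  rep_seeds <- with_stream(
    rng_streams(seed, 1L)[[1]],
    sample.int(.Machine$integer.max - 1L, n_replicates)
  )
  passes <- vapply(seq_len(n_replicates), function(r) {
    sessions <- suppressMessages(
      simulate_cohort(spec, reference_model, test_model,
                      seed = rep_seeds[r])
    )
    report <- grade_device(sessions, config)
    report$summary$part3_pass[report$summary$group == group]
  }, logical(1))
  n_passes <- sum(passes)
  ci <- suppressWarnings(
    prop.test(n_passes, n_replicates, correct = FALSE)$conf.int
  )
  tibble(
    n_replicates = n_replicates,
    n_passes = n_passes,
    estimate = n_passes / n_replicates,
    conf_low = ci[1],
    conf_high = ci[2]
  )
}

#' Recover the configured device bias from simulated sessions
#'
#' Estimates the test-minus-reference additive bias per quantity as the
#' mean signed difference over *all* flanking comparisons — each test
#' reading against both its preceding and following reference reading, six
#' differences per subject.  Averaging both flanking differences keeps the
#' estimator unbiased: the most-favorable selection used for grading pulls
#' differences toward zero, and a linear within-session drift contributes
#' `+drift` to one flanking difference and `-drift` to the other, so both
#' effects cancel here.  The standard error is clustered by subject
#' (subjects are independent; differences within a subject are not).
#'
#' @param sessions A session tibble with at least one subject.
#' @return A tibble per quantity: `n_subjects`, `bias_estimate` and its
#'   clustered standard error `se`.
#' @export
recover_device_bias <- function(sessions) {
  if (nrow(sessions) == 0) abort_input("no sessions supplied")
  comparisons <- build_comparisons(sessions)
  subject_means <- comparisons |>
    tidyr::pivot_longer(c("difference", "alternate_difference"),
                        values_to = "flanking_difference") |>
    dplyr::group_by(.data$quantity, .data$subject_id) |>
    dplyr::summarise(subject_mean = mean(.data$flanking_difference),
                     .groups = "drop")
  subject_means |>
    dplyr::group_by(.data$quantity) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      bias_estimate = mean(.data$subject_mean),
      se = if (dplyr::n() > 1) {
        sd(.data$subject_mean) / sqrt(dplyr::n())
      } else NA_real_,
      .groups = "drop"
    )
}
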