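#' Read a cohort from the two-file CSV interchange format
#'
#' Reads the long weekly series CSV (`subject_id,week,nbd`, blank `nbd` =
#' missing reply) and, optionally, the per-subject covariates CSV, joining
#' them by `subject_id`. Weeks absent from the file are filled in as
#' missing so that every subject carries the full week grid. Raw input is
#' validated strictly: `nbd` must be an integer in 0-7 (or blank) and no
#' `(subject, week)` pair may appear twice.
#'
#' @param series_file Path to the long series CSV.
#' @param covariates_file Optional path to the covariates CSV
#'   (`subject_id,duration_gt30`, possibly `true_archetype`).
#' @return A long cohort tibble (`subject_id`, `week`, `nbd`, plus joined
#'   covariates).
#' @seealso [write_cohort()]
#' @export
#' @examples
#' cohort <- simulate_cohort(n_subjects = 5, seed = 1)
#' sf <- tempfile(fileext = ".csv"); cf <- tempfile(fileext = ".csv")
#' write_cohort(cohort, sf, cf)
#' back <- read_cohort(sf, cf)
read_cohort <- function(series_file, covariates_file = NULL) {
  series <- readr::read_csv(
    series_file,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      week = readr::col_integer(),
      nbd = readr::col_double()
    ),
    na = ""
  )
  assert_cohort(series)

  bad <- which(!is.na(series$nbd) &
    (series$nbd < 0 | series$nbd > 7 | series$nbd != round(series$nbd)))
  if (length(bad) > 0) {
    abort(paste0(
      "`nbd` must be an integer in 0-7 or blank; offending data row(s): ",
      paste(head(bad, 5), collapse = ", "), "."
    ))
  }
  dup <- duplicated(series[c("subject_id", "week")])
  if (any(dup)) {
    abort(paste0(
      "Duplicated (subject_id, week) pair(s) at data row(s): ",
      paste(head(which(dup), 5), collapse = ", "), "."
    ))
  }

  # subjects with absent week rows get explicit missing cells
  series <- tidyr::complete(series,
    subject_id = unique(series$subject_id),
    week = seq(min(series$week), max(series$week))
  )
  series <- arrange(series, .data$subject_id, .data$week)

  if (!is.null(covariates_file)) {
    covars <- readr::read_csv(
      covariates_file,
      col_types = readr::cols(subject_id = readr::col_character()),
      na = ""
    )
    unknown <- setdiff(covars$subject_id, series$subject_id)
    if (length(unknown) > 0) {
      warn(paste0(
        "Covariates contain subject_id(s) absent from the series file: ",
        paste(head(unknown, 5), collapse = ", "), "."
      ))
    }
    series <- left_join(series, covars, by = "subject_id")
  }
  series
}

#' Apply the eligibility filter
#'
#' Keeps subjects with at least `min_replies` observed weekly values (the
#' motivating study required 24 of 26) and a complete set of the required
#' baseline covariates. Excluded subjects are logged with a reason;
#' retrieve the log with [exclusions()].
#'
#' @param data A long cohort tibble.
#' @param min_replies Minimum number of observed weekly replies.
#' @param required_covariates Covariate columns that must be non-missing;
#'   columns not present in `data` are ignored.
#' @return The filtered cohort, with the exclusion log attached as an
#'   attribute.
#' @export
#' @examples
#' cohort <- simulate_cohort(n_subjects = 30, seed = 1)
#' kept <- filter_eligible(cohort)
#' exclusions(kept)
filter_eligible <- function(data, min_replies = 24,
                            required_covariates = "duration_gt30") {
  assert_cohort(data)
  n_weeks <- length(unique(data$week))
  if (min_replies > n_weeks) {
    abort("`min_replies` cannot exceed the number of weeks in the cohort.")
  }
  required_covariates <- intersect(required_covariates, names(data))

  per_subject <- data %>%
    group_by(.data$subject_id) %>%
    summarise(
      n_observed = sum(!is.na(.data$nbd)),
      covariates_complete = !any(dplyr::if_any(
        dplyr::all_of(required_covariates), is.na
      )),
      .groups = "drop"
    )

  log <- bind_rows(
    per_subject %>%
      filter(.data$n_observed < min_replies) %>%
      mutate(reason = sprintf(
        "only %d/%d weekly replies (minimum %d)",
        .data$n_observed, n_weeks, min_replies
      )),
    per_subject %>%
      filter(.data$n_observed >= min_replies, !.data$covariates_complete) %>%
      mutate(reason = "incomplete baseline covariates")
  ) %>%
    dplyr::select("subject_id", "reason")

  kept <- filter(data, !(.data$subject_id %in% log$subject_id))
  if (nrow(kept) == 0) {
    abort("No subject passes the eligibility filter.")
  }
  append_exclusions(kept, data, log)
}

#' Impute missing weekly values
#'
#' Implements the nearest-observations rule: an interior missing week gets
#' the mean of the nearest observed values before and after it, which for
#' gaps spanning several weeks generalises to linear interpolation between
#' the flanking observations (and coincides with the two-point mean for a
#' single-week gap). Missing values at the start or end of the series copy
#' the nearest observed value, since only one side exists there.
#' Fractional imputed values are retained.
#'
#' @param data A long cohort tibble.
#' @return The cohort with `nbd` complete and a logical `imputed` column
#'   flagging filled-in cells.
#' @export
#' @examples
#' x <- tibble::tibble(subject_id = "S1", week = 1:3, nbd = c(2, NA, 4))
#' impute_missing(x)$nbd
impute_missing <- function(data) {
  assert_cohort(data)
  all_missing <- data %>%
    group_by(.data$subject_id) %>%
    summarise(none = all(is.na(.data$nbd)), .groups = "drop") %>%
    filter(.data$none)
  if (nrow(all_missing) > 0) {
    abort(paste0(
      "Cannot impute subjects with no observed values: ",
      paste(head(all_missing$subject_id, 5), collapse = ", "), "."
    ))
  }

  out <- data %>%
    group_by(.data$subject_id) %>%
    arrange(.data$week, .by_group = TRUE) %>%
    mutate(
      imputed = is.na(.data$nbd),
      nbd = impute_series(.data$week, .data$nbd)
    ) %>%
    ungroup()
  append_exclusions(out, data)
}

#' @keywords internal
#' @noRd
impute_series <- function(week, nbd) {
  obs <- !is.na(nbd)
  if (all(obs)) {
    return(nbd)
  }
  if (sum(obs) == 1) {
    return(rep(nbd[obs], length(nbd)))
  }
  # rule = 2: boundary gaps copy the nearest observed value
  approx(week[obs], nbd[obs], xout = week, rule = 2)$y
}

#' Remove constant repliers
#'
#' Subjects whose complete series is one identical value carry no
#' trajectory information (the spline fit is degenerate), so they are
#' removed after imputation, mirroring the motivating study's removal of
#' constant repliers. Excluded subjects are logged; see [exclusions()].
#'
#' @param data A complete (imputed) cohort tibble.
#' @return The filtered cohort with the exclusion log attached.
#' @export
remove_constant <- function(data) {
  assert_cohort(data, complete = TRUE)
  constant <- data %>%
    group_by(.data$subject_id) %>%
    summarise(constant = max(.data$nbd) == min(.data$nbd), .groups = "drop") %>%
    filter(.data$constant)
  log <- tibble(
    subject_id = constant$subject_id,
    reason = "constant reply in all weeks"
  )
  kept <- filter(data, !(.data$subject_id %in% log$subject_id))
  append_exclusions(kept, data, log)
}
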