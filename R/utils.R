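#' @keywords internal
#' @noRd
assert_cohort <- function(data, complete = FALSE, call = rlang::caller_env()) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame (long cohort table).", call = call)
  }
  needed <- c("subject_id", "week", "nbd")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Cohort table must have columns subject_id, week, nbd; missing: ",
      paste(missing_cols, collapse = ", "), "."
    ), call = call)
  }
  if (complete && anyNA(data$nbd)) {
    abort("Cohort still has missing `nbd` values; run `impute_missing()` first.",
      call = call
    )
  }
  invisible(data)
}

# Exclusion logs are carried along the pipeline as an attribute so that
# `cohort |> filter_eligible() |> impute_missing() |> remove_constant()`
# accumulates one tidy log.
#' @keywords internal
#' @noRd
append_exclusions <- function(data, previous, new = NULL) {
  log <- attr(previous, "exclusions", exact = TRUE)
  if (is.null(log)) log <- empty_exclusions()
  if (!is.null(new) && nrow(new) > 0) log <- bind_rows(log, new)
  attr(data, "exclusions") <- log
  data
}

#' @keywords internal
#' @noRd
empty_exclusions <- function() {
  tibble(subject_id = character(), reason = character())
}

#' Retrieve the exclusion log attached to a cohort
#'
#' [filter_eligible()] and [remove_constant()] record every dropped subject
#' (id and reason) in an attribute of the returned cohort. This accessor
#' returns that log as a tibble, so pipelines never lose track of the
#' subjects they discard.
#'
#' @param data A cohort tibble returned by one of the filtering steps.
#' @return A tibble with columns `subject_id` and `reason` (zero rows when
#'   nothing was excluded).
#' @export
#' @examples
#' cohort <- simulate_cohort(n_subjects = 20, seed = 1)
#' kept <- filter_eligible(cohort)
#' exclusions(kept)
exclusions <- function(data) {
  log <- attr(data, "exclusions", exact = TRUE)
  if (is.null(log)) empty_exclusions() else log
}

# Round half away from zero (NBD values are non-negative, so this is
# floor(x + 0.5)); used when fractional imputed values enter the binomial
# risk model.
#' @keywords internal
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' @keywords internal
#' @noRd
with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
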