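#' Week sets of the six measurement-frequency designs
#'
#' The designs compare a full 26-week weekly follow-up (A, the reference)
#' with five reduced schedules:
#' \describe{
#'   \item{A}{all 26 weekly measures (reference)}
#'   \item{B}{the first 8 weekly measures}
#'   \item{C}{the first 13 weekly measures}
#'   \item{D}{the first 8 weekly measures, then every fourth week
#'     (12, 16, 20, 24) plus the final week 26 - 13 measures}
#'   \item{E}{every second week (1, 3, ..., 25) plus the final week 26 -
#'     14 measures}
#'   \item{F}{the first 18 weekly measures}
#' }
#'
#' @param name A single design letter, `"A"` to `"F"`.
#' @return Integer vector of measurement weeks, strictly increasing.
#' @seealso [design_options()], [subsample_design()]
#' @export
#' @examples
#' design_weeks("D")
#' lengths(lapply(LETTERS[1:6], design_weeks))
design_weeks <- function(name) {
  if (length(name) != 1 || !name %in% LETTERS[1:6]) {
    abort("`name` must be one of \"A\"..\"F\".")
  }
  switch(name,
    A = 1:26,
    B = 1:8,
    C = 1:13,
    D = c(1:8, 12, 16, 20, 24, 26),
    E = c(seq(1, 25, by = 2), 26),
    F = 1:18
  )
}

#' All six designs as a tidy table
#'
#' @return A tibble with columns `design`, `n_weeks` and a `weeks`
#'   list-column, one row per design A-F.
#' @export
#' @examples
#' design_options()
design_options <- function() {
  weeks <- purrr::map(LETTERS[1:6], design_weeks)
  tibble(
    design = LETTERS[1:6],
    description = c(
      "all 26 weekly measures (reference)",
      "first 8 weeks",
      "first 13 weeks",
      "first 8 weeks + every 4th week + week 26",
      "every 2nd week + week 26",
      "first 18 weeks"
    ),
    weeks = weeks,
    n_weeks = lengths(weeks)
  )
}

#' Restrict a cohort to a design's measurement weeks
#'
#' Keeps, for every subject, only the weeks measured under the design; the
#' subject set is unchanged and values at shared weeks are identical to
#' the full cohort's.
#'
#' @param data A complete (imputed) cohort tibble.
#' @param design A design letter `"A"`-`"F"`, or an integer vector of
#'   weeks for a custom schedule.
#' @return The subsampled cohort; the week set used is attached as the
#'   `"week_set"` attribute.
#' @export
#' @examples
#' cohort <- simulate_cohort(n_subjects = 5, missing_rate = 0, seed = 1)
#' nrow(subsample_design(cohort, "B")) / 5
subsample_design <- function(data, design) {
  assert_cohort(data)
  weeks <- if (is.character(design)) design_weeks(design) else as.integer(design)
  if (length(weeks) == 0 || is.unsorted(weeks, strictly = TRUE) ||
    any(weeks < 1 | weeks > 26)) {
    abort("A design week set must be a non-empty strictly increasing subset of 1..26.")
  }
  out <- filter(data, .data$week %in% weeks)
  out <- append_exclusions(out, data)
  attr(out, "week_set") <- weeks
  out
}
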