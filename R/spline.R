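#' Fit a two-phase linear spline with a free knot to one subject's series
#'
#' Models the weekly pain course as two straight regression lines joined
#' continuously at an estimated trend break (the knot):
#' \deqn{y(t) = \beta_0 + \beta_1 (t - t_1) + (\beta_2 - \beta_1)\,(t - \kappa)_+}
#' where \eqn{t_1} is the first fitted week, \eqn{\beta_1} and
#' \eqn{\beta_2} are the early and late slopes and \eqn{\kappa} the knot.
#' The knot is chosen by exhaustive search over integer candidate weeks
#' from `first_week + 2` to `last_week - 2` (each candidate must leave at
#' least three points up to the knot and two beyond it); given the knot,
#' the coefficients are ordinary least squares. The search is exact on the
#' candidate grid and fully deterministic; SSE ties are broken towards the
#' earliest knot. Sub-week knots are not considered because the outcome is
#' weekly, so finer breaks are not identifiable in practice.
#'
#' Constant series (possible when a non-constant subject is restricted to
#' a reduced design's weeks) fit exactly as a flat line: both slopes 0,
#' the earliest candidate knot, SSE 0.
#'
#' @param weeks Integer vector of measurement weeks (strictly increasing).
#' @param values Numeric NBD values, one per week.
#' @return An object of class `"spline_fit"`: a list with elements
#'   `intercept` (fitted NBD at the first week), `slope1`, `slope2`
#'   (days/week), `knot` (week), `sse`, `n_obs`, `first_week`,
#'   `last_week`, `level_first` and `level_last` (fitted NBD at the first
#'   and last week - the two regression lines each represented by a point
#'   inside the fitted range).
#' @seealso [fit_splines()] for a whole cohort, [predict.spline_fit()]
#' @export
#' @examples
#' w <- 1:26
#' y <- ifelse(w <= 3, 5 - (w - 1) * 1.5, 2)
#' fit_spline(w, y)
fit_spline <- function(weeks, values) {
  if (length(weeks) != length(values)) {
    abort("`weeks` and `values` must have the same length.")
  }
  keep <- !is.na(values)
  weeks <- weeks[keep]
  values <- values[keep]
  if (length(weeks) < 5) {
    abort("A spline fit needs at least 5 observed points.")
  }
  if (is.unsorted(weeks, strictly = TRUE)) {
    abort("`weeks` must be strictly increasing.")
  }

  t1 <- weeks[1]
  candidates <- seq(t1 + 2, weeks[length(weeks)] - 2)
  candidates <- candidates[
    vapply(candidates, function(k) {
      sum(weeks <= k) >= 3 && sum(weeks > k) >= 2
    }, logical(1))
  ]
  if (length(candidates) == 0) {
    abort("No admissible knot candidate for this week set.")
  }

  best <- NULL
  best_sse <- Inf
  best_knot <- NA_integer_
  for (k in candidates) {
    x <- cbind(1, weeks - t1, pmax(0, weeks - k))
    fit <- lm.fit(x, values)
    sse <- sum(fit$residuals^2)
    if (sse < best_sse - 1e-9) {
      best_sse <- sse
      best <- unname(fit$coefficients)
      best_knot <- k
    }
  }

  slope1 <- best[2]
  slope2 <- best[2] + best[3]
  structure(
    list(
      intercept = best[1],
      slope1 = slope1,
      slope2 = slope2,
      knot = best_knot,
      sse = max(0, best_sse),
      n_obs = length(weeks),
      first_week = t1,
      last_week = weeks[length(weeks)],
      level_first = best[1],
      level_last = best[1] + slope1 * (best_knot - t1) +
        slope2 * (weeks[length(weeks)] - best_knot)
    ),
    class = "spline_fit"
  )
}

#' Evaluate a fitted trajectory at arbitrary weeks
#'
#' Evaluates the continuous piecewise-linear model, including weeks beyond
#' the fitted range: extrapolation follows the post-knot line, which is
#' how cluster trajectories estimated under a reduced design are extended
#' to the full 26 weeks.
#'
#' @param object A `"spline_fit"`.
#' @param weeks Weeks at which to evaluate (may lie outside the fitted
#'   range).
#' @param ... Unused.
#' @return Numeric vector of expected NBD values (unclamped).
#' @export
predict.spline_fit <- function(object, weeks, ...) {
  object$intercept +
    object$slope1 * (weeks - object$first_week) +
    (object$slope2 - object$slope1) * pmax(0, weeks - object$knot)
}

#' @export
print.spline_fit <- function(x, ...) {
  cat(sprintf(
    "Two-phase linear spline: %.2f %+.3f d/wk (weeks %d-%d), %+.3f d/wk after knot %d; SSE %.3f on %d points\n",
    x$intercept, x$slope1, x$first_week, x$knot, x$slope2, x$knot, x$sse, x$n_obs
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.spline_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope1", "slope2", "knot"),
    estimate = c(x$intercept, x$slope1, x$slope2, x$knot)
  )
}

#' @exportS3Method generics::glance
glance.spline_fit <- function(x, ...) {
  tibble(
    knot = x$knot, sse = x$sse, n_obs = x$n_obs,
    first_week = x$first_week, last_week = x$last_week
  )
}

#' Fit trajectory splines for every subject in a cohort
#'
#' @param data A complete (imputed) cohort tibble, typically already
#'   restricted to a design's weeks with [subsample_design()].
#' @return A tibble of class `"spline_fits"` with one row per subject:
#'   the four spline parameters (`intercept`, `slope1`, `slope2`, `knot`),
#'   fit diagnostics (`sse`, `n_obs`) and the derived line levels
#'   (`level_first`, `level_last`). The design's week set is attached as
#'   the `"week_set"` attribute.
#' @seealso [parameter_matrix()], [cluster_subjects()]
#' @export
#' @examples
#' cohort <- simulate_cohort(n_subjects = 8, missing_rate = 0, seed = 1)
#' fit_splines(cohort)
fit_splines <- function(data) {
  assert_cohort(data, complete = TRUE)
  week_set <- attr(data, "week_set", exact = TRUE)
  if (is.null(week_set)) week_set <- sort(unique(data$week))

  fits <- data %>%
    arrange(.data$subject_id, .data$week) %>%
    group_by(.data$subject_id) %>%
    dplyr::group_map(function(d, key) {
      f <- fit_spline(d$week, d$nbd)
      tibble(
        subject_id = key$subject_id,
        intercept = f$intercept, slope1 = f$slope1, slope2 = f$slope2,
        knot = f$knot, sse = f$sse, n_obs = f$n_obs,
        first_week = f$first_week, last_week = f$last_week,
        level_first = f$level_first, level_last = f$level_last
      )
    }) %>%
    bind_rows()

  attr(fits, "week_set") <- week_set
  class(fits) <- c("spline_fits", class(fits))
  fits
}

#' Assemble the subjects-by-parameters matrix used for clustering
#'
#' Each subject's fitted trajectory contributes four parameters. Two
#' readings of "four parameters" are supported:
#' \describe{
#'   \item{`"lines"` (default)}{the two regression lines, each represented
#'     by its slope and its fitted level inside the data range:
#'     `(level_first, slope1, level_last, slope2)`. All four features are
#'     measured in days or days/week, and every feature is identified even
#'     for a flat course (where the knot is arbitrary).}
#'   \item{`"knot"`}{the continuous-spline parameter vector
#'     `(intercept, slope1, slope2, knot)`. Note the knot (in weeks) is
#'     unidentified for near-flat trajectories.}
#' }
#' Because the `"lines"` features share the days scale, they are used
#' unstandardized by default; set `standardize = TRUE` to centre and scale
#' each column to unit variance (a zero-variance column is left centred
#' with a warning).
#'
#' @param fits A `"spline_fits"` tibble from [fit_splines()].
#' @param features `"lines"` or `"knot"`; see Details.
#' @param standardize Centre and scale columns to unit variance?
#' @return A numeric matrix, one row per subject (rownames are subject
#'   ids), columns in the order listed above.
#' @export
parameter_matrix <- function(fits, features = c("lines", "knot"),
                             standardize = FALSE) {
  features <- match.arg(features)
  if (nrow(fits) < 2) abort("Need at least 2 fitted subjects.")
  cols <- switch(features,
    lines = c("level_first", "slope1", "level_last", "slope2"),
    knot = c("intercept", "slope1", "slope2", "knot")
  )
  m <- as.matrix(fits[cols])
  rownames(m) <- fits$subject_id
  if (standardize) {
    centre <- colMeans(m)
    scale <- apply(m, 2, sd)
    if (any(scale == 0)) {
      warn("Zero-variance parameter column(s) left centred but unscaled.")
      scale[scale == 0] <- 1
    }
    m <- scale(m, center = centre, scale = scale)
    attr(m, "scaled:center") <- centre
    attr(m, "scaled:scale") <- scale
  }
  m
}
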