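#' Default trajectory archetypes for the synthetic cohort
#'
#' Four archetype recovery courses emulating the subgroups seen in weekly
#' low back pain follow-up: fast improvers (already part-recovered at entry,
#' fully recovered within about three weeks), normal improvers (recovered
#' over roughly the first two months), slow improvers (trend break in the
#' second trimester, incomplete recovery) and an indifferent group that does
#' not improve. Each archetype is a piecewise-linear mean curve for the
#' weekly Number of Bothersome Days (NBD, days 0-7): linear from
#' `start_level` at week 1 to `end_level` at `knot_week`, constant
#' afterwards; `knot_week = NA` encodes a flat course.
#'
#' Most default levels sit close to the 0/7 boundaries of the NBD scale.
#' That is both clinically sensible for a care-seeking cohort (baseline pain
#' on most days, recovered subjects reporting none, non-improvers bothered
#' most days) and what gives the four archetypes well-separated
#' spline-parameter clouds under binomial observation noise, so that the
#' clustering stage has a recoverable truth; see the package vignette.
#'
#' @return A tibble with columns `archetype`, `start_level`, `knot_week`,
#'   `end_level` and `p_long_duration` (probability that a subject of this
#'   archetype reports more than 30 days of pain in the previous year).
#' @seealso [simulate_cohort()], [simulate_series()]
#' @export
#' @examples
#' default_archetypes()
default_archetypes <- function() {
  tibble(
    archetype = c("fast", "normal", "slow", "indifferent"),
    start_level = c(4.5, 7, 7, 6.75),
    knot_week = c(3, 9, 15, NA),
    end_level = c(0, 0.75, 3.5, 6.75),
    p_long_duration = c(0.30, 0.30, 0.85, 0.85)
  )
}

#' @keywords internal
#' @noRd
validate_archetypes <- function(archetypes, call = rlang::caller_env()) {
  needed <- c("archetype", "start_level", "knot_week", "end_level")
  if (!is.data.frame(archetypes) || !all(needed %in% names(archetypes))) {
    abort(
      "`archetypes` must be a data frame with columns archetype, start_level, knot_week, end_level.",
      call = call
    )
  }
  bad_level <- archetypes$start_level < 0 | archetypes$start_level > 7 |
    archetypes$end_level < 0 | archetypes$end_level > 7
  if (any(bad_level)) {
    abort("Archetype start/end levels must lie in [0, 7] days.", call = call)
  }
  knot <- archetypes$knot_week
  if (any(!is.na(knot) & (knot < 2 | knot > 25))) {
    abort("Archetype knot weeks must lie in [2, 25] (or NA for a flat course).",
      call = call
    )
  }
  invisible(archetypes)
}

#' Piecewise-linear mean NBD curve of an archetype
#'
#' @param start_level Expected NBD (days, 0-7) at week 1.
#' @param knot_week Week of the trend break, or `NA` for a flat course.
#' @param end_level Expected NBD after the knot.
#' @param weeks Integer weeks at which to evaluate the curve.
#' @return Numeric vector of expected NBD values, one per week.
#' @export
#' @examples
#' archetype_mean(7, 3, 0, weeks = 1:6)
archetype_mean <- function(start_level, knot_week, end_level, weeks) {
  if (is.na(knot_week)) {
    return(rep(start_level, length(weeks)))
  }
  out <- ifelse(
    weeks <= knot_week,
    start_level + (end_level - start_level) * (weeks - 1) / (knot_week - 1),
    end_level
  )
  pmin(7, pmax(0, out))
}

#' Simulate one subject's weekly NBD series
#'
#' Weekly counts are drawn `Binomial(7, m_t / 7)` around the archetype's
#' piecewise-linear mean curve `m_t`, independently across weeks. An
#' optional beta-binomial overdispersion parameter `rho` (the intra-week
#' correlation; 0 gives the plain binomial) is available for sensitivity
#' work and is off by default.
#'
#' @param archetype A one-row data frame with columns `start_level`,
#'   `knot_week`, `end_level` (for example one row of
#'   [default_archetypes()]).
#' @param n_weeks Number of weekly measurements (default 26).
#' @param rho Beta-binomial overdispersion in `[0, 1)`; 0 = binomial.
#' @return Integer vector of length `n_weeks` with values in 0-7.
#' @export
#' @examples
#' set.seed(1)
#' simulate_series(default_archetypes()[1, ])
simulate_series <- function(archetype, n_weeks = 26, rho = 0) {
  validate_archetypes(dplyr::mutate(archetype, archetype = "x"))
  if (n_weeks < 2) abort("`n_weeks` must be at least 2.")
  m <- archetype_mean(
    archetype$start_level, archetype$knot_week, archetype$end_level,
    seq_len(n_weeks)
  )
  draw_nbd(m, rho)
}

#' @keywords internal
#' @noRd
draw_nbd <- function(m, rho = 0) {
  p <- m / 7
  if (rho > 0) {
    # beta-binomial: mean p, intra-class correlation rho
    interior <- p > 0 & p < 1
    a <- p * (1 - rho) / rho
    b <- (1 - p) * (1 - rho) / rho
    p[interior] <- stats::rbeta(sum(interior), a[interior], b[interior])
  }
  rbinom(length(p), size = 7, prob = p)
}

#' Simulate a synthetic SMS pain cohort
#'
#' Generates a long-format weekly cohort with the statistical structure the
#' downstream analysis assumes: a mixture of archetype trajectories with
#' binomial weekly NBD counts, a small rate of completely-constant repliers,
#' independent cell-wise missingness, and a binary prior-pain-duration
#' covariate associated with the trajectory archetype. Defaults mirror the
#' motivating study cohort: 129 subjects, 26 weeks, ~2.9% missing cells and
#' archetype proportions (0.13, 0.49, 0.18, 0.20).
#'
#' The duration covariate is drawn per subject with the archetype-specific
#' probability `p_long_duration` from the archetype table (defaults 0.85
#' for slow/indifferent courses, 0.30 for fast/normal), which makes chronic
#' prior pain predictive of a poor course and yields a week-wise relative
#' risk that rises and then plateaus around 2.5-3.5.
#'
#' @param n_subjects Number of subjects (default 129).
#' @param n_weeks Number of weekly measurements (default 26).
#' @param archetypes Archetype table; see [default_archetypes()].
#' @param mixture Archetype mixture proportions (non-negative, summing to 1).
#' @param missing_rate Probability that any one weekly reply is missing.
#' @param constant_rate Probability that a subject is a constant replier
#'   (answers one fixed value every single week).
#' @param rho Beta-binomial overdispersion; see [simulate_series()].
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   cohorts.
#' @return A tibble with one row per subject-week: `subject_id`, `week`,
#'   `nbd` (`NA` where the reply is missing), `duration_gt30` (0/1) and
#'   `true_archetype` (the generating archetype, `"constant"` for constant
#'   repliers) for label-recovery checks.
#' @seealso [add_missingness()], [write_cohort()], [read_cohort()]
#' @export
#' @examples
#' cohort <- simulate_cohort(n_subjects = 10, seed = 42)
#' head(cohort)
simulate_cohort <- function(n_subjects = 129,
                            n_weeks = 26,
                            archetypes = default_archetypes(),
                            mixture = c(0.13, 0.49, 0.18, 0.20),
                            missing_rate = 0.029,
                            constant_rate = 0.03,
                            rho = 0,
                            seed = NULL) {
  validate_archetypes(archetypes)
  if (n_subjects < 1) abort("`n_subjects` must be at least 1.")
  if (length(mixture) != nrow(archetypes)) {
    abort("`mixture` must have one proportion per archetype.")
  }
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-9) {
    abort("`mixture` proportions must be non-negative and sum to 1.")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1).")
  }
  p_long <- archetypes$p_long_duration %||% rep(0.5, nrow(archetypes))

  with_optional_seed(seed, {
    arch_idx <- sample.int(nrow(archetypes), n_subjects,
      replace = TRUE, prob = mixture
    )
    is_constant <- runif(n_subjects) < constant_rate
    constant_value <- sample(0:7, n_subjects, replace = TRUE)
    duration <- rbinom(n_subjects, 1, p_long[arch_idx])

    series <- lapply(seq_len(n_subjects), function(i) {
      if (is_constant[i]) {
        rep(constant_value[i], n_weeks)
      } else {
        a <- archetypes[arch_idx[i], ]
        draw_nbd(
          archetype_mean(a$start_level, a$knot_week, a$end_level, seq_len(n_weeks)),
          rho
        )
      }
    })

    ids <- sprintf("S%03d", seq_len(n_subjects))
    cohort <- tibble(
      subject_id = rep(ids, each = n_weeks),
      week = rep(seq_len(n_weeks), times = n_subjects),
      nbd = as.numeric(unlist(series)),
      duration_gt30 = rep(duration, each = n_weeks),
      true_archetype = rep(
        ifelse(is_constant, "constant", archetypes$archetype[arch_idx]),
        each = n_weeks
      )
    )
    add_missingness(cohort, missing_rate)
  })
}

#' Mask weekly replies at random
#'
#' Each cell is masked (set to `NA`) independently with probability
#' `missing_rate`, emulating skipped weekly text-message replies. Masked
#' cells carry an explicit `NA`, never an in-range sentinel.
#'
#' @param data A long cohort tibble (see [simulate_cohort()]).
#' @param missing_rate Per-cell masking probability in `[0, 1)`.
#' @param seed Optional integer seed for a reproducible mask.
#' @return The cohort with masked `nbd` cells.
#' @export
#' @examples
#' cohort <- simulate_cohort(n_subjects = 5, missing_rate = 0, seed = 1)
#' masked <- add_missingness(cohort, 0.1, seed = 2)
#' sum(is.na(masked$nbd))
add_missingness <- function(data, missing_rate, seed = NULL) {
  assert_cohort(data)
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1).")
  }
  if (missing_rate == 0) {
    return(data)
  }
  with_optional_seed(seed, {
    mask <- runif(nrow(data)) < missing_rate
    data$nbd[mask] <- NA_real_
    data
  })
}

#' Write a cohort to the two-file CSV interchange format
#'
#' The weekly series go to one long CSV (`subject_id,week,nbd`, blank `nbd`
#' for a missing reply) and the per-subject baseline covariates to a second
#' CSV (`subject_id,duration_gt30[,true_archetype]`).
#'
#' @param data A long cohort tibble.
#' @param series_file,covariates_file Output paths.
#' @return `data`, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(data, series_file, covariates_file) {
  assert_cohort(data)
  readr::write_csv(
    dplyr::select(data, "subject_id", "week", "nbd"), series_file,
    na = ""
  )
  cov_cols <- intersect(c("subject_id", "duration_gt30", "true_archetype"), names(data))
  readr::write_csv(distinct(dplyr::select(data, dplyr::all_of(cov_cols))), covariates_file, na = "")
  invisible(data)
}
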