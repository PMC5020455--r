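#' Per-cluster mean trajectories with extrapolation to the full period
#'
#' For every cluster, the trajectory over the design's measured weeks is
#' the plain mean of the member subjects' (imputed) weekly NBD values.
#' Weeks beyond the design's last measured week are extrapolated by
#' evaluating each member's fitted post-knot line there and averaging;
#' the averaged means are clamped to the valid NBD range 0-7 (linear
#' extrapolation can exit it). Extrapolated weeks are flagged in the
#' output, and the extrapolated part joins the fitted part continuously
#' at the last measured week of each member's fit.
#'
#' @param data The design-restricted complete cohort (the same one the
#'   fits were estimated on).
#' @param fits The `"spline_fits"` for that cohort.
#' @param clusters A `"trajectory_clusters"` solution for those fits.
#' @param full_weeks Weeks the trajectory should cover (default `1:26`).
#' @return A tibble of class `"cluster_trajectories"`: `cluster`, `week`,
#'   `mean_nbd`, `extrapolated` (logical), `n_subjects`.
#' @export
#' @examples
#' cohort <- simulate_cohort(n_subjects = 30, missing_rate = 0, seed = 3)
#' short <- subsample_design(cohort, "B")
#' fits <- fit_splines(short)
#' cl <- cluster_subjects(fits, k = 2)
#' cluster_trajectories(short, fits, cl)
cluster_trajectories <- function(data, fits, clusters, full_weeks = 1:26) {
  assert_cohort(data, complete = TRUE)
  labels <- clusters$labels
  measured_weeks <- sort(unique(data$week))
  last_measured <- max(measured_weeks)

  measured <- data %>%
    dplyr::inner_join(labels, by = "subject_id") %>%
    group_by(.data$cluster, .data$week) %>%
    summarise(
      mean_nbd = mean(.data$nbd),
      n_subjects = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(extrapolated = FALSE)

  extra_weeks <- setdiff(full_weeks, measured_weeks)
  extra_weeks <- extra_weeks[extra_weeks > last_measured]
  if (length(extra_weeks) > 0) {
    members <- dplyr::inner_join(fits, labels, by = "subject_id")
    extrapolated <- purrr::map_dfr(extra_weeks, function(w) {
      pred <- members$level_last + members$slope2 * (w - members$last_week)
      members %>%
        mutate(pred = pred) %>%
        group_by(.data$cluster) %>%
        summarise(
          mean_nbd = pmin(7, pmax(0, mean(.data$pred))),
          n_subjects = dplyr::n(),
          .groups = "drop"
        ) %>%
        mutate(week = w, extrapolated = TRUE)
    })
    measured <- bind_rows(measured, extrapolated)
  }

  out <- measured %>%
    dplyr::select("cluster", "week", "mean_nbd", "extrapolated", "n_subjects") %>%
    arrange(.data$cluster, .data$week)
  class(out) <- c("cluster_trajectories", class(out))
  out
}

#' @rdname cluster_trajectories
#' @param object A `"cluster_trajectories"` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_trajectories <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$week, y = .data$mean_nbd,
      colour = factor(.data$cluster), linetype = .data$extrapolated
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid", `TRUE` = "dashed")) +
    ggplot2::scale_y_continuous(limits = c(0, 7)) +
    ggplot2::labs(
      x = "Week", y = "Mean number of bothersome days",
      colour = "Cluster", linetype = "Extrapolated",
      title = "Cluster mean trajectories"
    ) +
    ggplot2::theme_minimal()
}
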