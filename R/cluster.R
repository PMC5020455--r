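#' Ward's hierarchical clustering of the parameter matrix
#'
#' Agglomerative clustering with Ward's minimum-variance linkage on
#' Euclidean distances (`stats::hclust(method = "ward.D2")`), cut at `k`
#' clusters. Used to seed the K-means consolidation, so the whole
#' clustering stage is deterministic.
#'
#' @param x Numeric matrix, one row per subject.
#' @param k Number of clusters, `2 <= k <= nrow(x)`.
#' @return Integer cluster labels in `1..k`.
#' @seealso [kmeans_consolidate()], [cluster_subjects()]
#' @export
ward_cluster <- function(x, k) {
  x <- as.matrix(x)
  if (k > nrow(x)) abort("`k` cannot exceed the number of subjects.")
  if (k < 1) abort("`k` must be at least 1.")
  if (!all(is.finite(x))) abort("Parameter matrix must be finite.")
  cutree(hclust(dist(x), method = "ward.D2"), k = k)
}

#' K-means consolidation of an initial partition
#'
#' Lloyd's algorithm started from the centroids of the initial partition:
#' assign each point to its nearest centroid (squared Euclidean distance,
#' ties to the lowest cluster index), recompute centroids, and repeat
#' until the assignment is unchanged. Deterministic given the
#' initialization; the number of clusters never changes. Should a cluster
#' empty during iteration, its centroid is re-seeded at the point farthest
#' from its currently assigned centroid and the event is recorded in the
#' `"reseeded"` attribute.
#'
#' @param x Numeric matrix, one row per subject.
#' @param init_labels Initial cluster labels in `1..k` (e.g. from
#'   [ward_cluster()]).
#' @return Integer labels in `1..k` after convergence.
#' @export
kmeans_consolidate <- function(x, init_labels) {
  x <- as.matrix(x)
  k <- max(init_labels)
  if (length(init_labels) != nrow(x)) {
    abort("`init_labels` must have one label per row of `x`.")
  }
  if (!setequal(init_labels, seq_len(k))) {
    abort("`init_labels` must use every label in 1..k at least once.")
  }

  labels <- init_labels
  reseeded <- 0L
  for (iter in seq_len(1000L)) {
    centroids <- centroid_matrix(x, labels, k)
    d2 <- sq_dist_to_centroids(x, centroids)
    new_labels <- max.col(-d2, ties.method = "first")

    empty <- setdiff(seq_len(k), unique(new_labels))
    for (cl in empty) {
      # re-seed at the point farthest from its assigned centroid
      far <- which.max(d2[cbind(seq_len(nrow(x)), new_labels)])
      new_labels[far] <- cl
      reseeded <- reseeded + 1L
    }
    if (all(new_labels == labels)) break
    labels <- new_labels
  }
  attr(labels, "reseeded") <- reseeded
  labels
}

#' @keywords internal
#' @noRd
centroid_matrix <- function(x, labels, k = max(labels)) {
  t(vapply(
    seq_len(k),
    function(cl) colMeans(x[labels == cl, , drop = FALSE]),
    numeric(ncol(x))
  ))
}

#' @keywords internal
#' @noRd
sq_dist_to_centroids <- function(x, centroids) {
  # n x k matrix of squared Euclidean distances
  vapply(
    seq_len(nrow(centroids)),
    function(j) colSums((t(x) - centroids[j, ])^2),
    numeric(nrow(x))
  )
}

#' Calinski-Harabasz score of a partition
#'
#' The variance-ratio criterion
#' \deqn{CH = \frac{B/(k-1)}{W/(n-k)}}
#' with `B` the between-cluster and `W` the within-cluster sum of squared
#' Euclidean deviations about centroids. Larger is better; the score is
#' undefined for `k = 1` and `k = n`.
#'
#' @param x Numeric matrix, one row per subject.
#' @param labels Integer cluster labels.
#' @return The CH score (a positive scalar for any non-trivial partition).
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- length(unique(labels))
  if (k < 2 || k >= n) {
    abort("The Calinski-Harabasz score requires 2 <= k < n.")
  }
  grand <- colMeans(x)
  between <- 0
  within <- 0
  for (cl in unique(labels)) {
    rows <- x[labels == cl, , drop = FALSE]
    centre <- colMeans(rows)
    between <- between + nrow(rows) * sum((centre - grand)^2)
    within <- within + sum(sweep(rows, 2, centre)^2)
  }
  (between / (k - 1)) / (within / (n - k))
}

#' Cluster subjects by their fitted trajectory parameters
#'
#' The two-stage procedure of the motivating study: Ward's hierarchical
#' clustering seeds a K-means consolidation, at a fixed `k` or - when `k`
#' is `NULL` - at every `k` in `k_range`, with the Calinski-Harabasz
#' criterion selecting the best `k`. The full score profile is kept so
#' near-ties between adjacent `k` are inspectable. Cluster labels are
#' relabelled on the recovery ordinal scale - 1 = fastest improvement
#' (lowest mean extrapolated NBD at the final study week) up to `k` =
#' indifferent - so labels are comparable across designs and usable with
#' the weighted kappa.
#'
#' @param fits A `"spline_fits"` tibble from [fit_splines()].
#' @param k Fixed number of clusters, or `NULL` to search `k_range`.
#' @param k_range Candidate numbers of clusters for the search.
#' @param features,standardize Passed to [parameter_matrix()].
#' @param final_week Week at which trajectories are compared for the
#'   ordinal relabelling (default 26).
#' @return An object of class `"trajectory_clusters"`: a list with
#'   `labels` (tibble `subject_id`, `cluster`), `k`, `ch_score`,
#'   `profile` (tibble `k`, `ch_score`; a single row in fixed-`k` mode),
#'   `centroids` (tibble of per-cluster feature means and sizes) and the
#'   call settings. Supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' cohort <- simulate_cohort(n_subjects = 40, missing_rate = 0, seed = 7)
#' cl <- cluster_subjects(fit_splines(cohort), k = 4)
#' glance(cl)
cluster_subjects <- function(fits, k = NULL, k_range = 2:8,
                             features = "lines", standardize = FALSE,
                             final_week = 26) {
  x <- parameter_matrix(fits, features = features, standardize = standardize)
  n <- nrow(x)

  solve_k <- function(kk) kmeans_consolidate(x, ward_cluster(x, kk))

  if (is.null(k)) {
    k_range <- k_range[k_range < n & k_range >= 2]
    if (length(k_range) == 0) abort("`k_range` has no admissible value (< n).")
    labels_by_k <- lapply(k_range, solve_k)
    scores <- vapply(
      labels_by_k,
      function(lab) calinski_harabasz(x, lab), numeric(1)
    )
    best <- which.max(scores)
    labels <- labels_by_k[[best]]
    k <- k_range[best]
    profile <- tibble(k = k_range, ch_score = scores)
  } else {
    if (k > n) abort("`k` cannot exceed the number of subjects.")
    labels <- solve_k(k)
    score <- if (k >= 2 && k < n) calinski_harabasz(x, labels) else NA_real_
    profile <- tibble(k = k, ch_score = score)
  }

  labels <- rank_clusters(labels, fits, final_week)
  centroids <- as_tibble(centroid_matrix(x, labels, k))
  names(centroids) <- colnames(x)
  centroids <- dplyr::bind_cols(
    tibble(cluster = seq_len(k), n_subjects = tabulate(labels, k)),
    centroids
  )

  structure(
    list(
      labels = tibble(subject_id = fits$subject_id, cluster = as.integer(labels)),
      k = k,
      ch_score = profile$ch_score[profile$k == k],
      profile = profile,
      centroids = centroids,
      features = features,
      standardize = standardize,
      week_set = attr(fits, "week_set", exact = TRUE)
    ),
    class = "trajectory_clusters"
  )
}

# Relabel clusters on the recovery ordinal scale: ascending mean
# extrapolated NBD at the final study week, i.e. cluster 1 ends best off.
#' @keywords internal
#' @noRd
rank_clusters <- function(labels, fits, final_week = 26) {
  pred_final <- fits$level_last + fits$slope2 * (final_week - fits$last_week)
  means <- vapply(
    seq_len(max(labels)),
    function(cl) mean(pred_final[labels == cl]), numeric(1)
  )
  new_of_old <- order(order(means, seq_along(means)))
  as.integer(new_of_old[labels])
}

#' @export
print.trajectory_clusters <- function(x, ...) {
  cat(sprintf(
    "Trajectory clustering (Ward + K-means): k = %d, Calinski-Harabasz = %.2f\n",
    x$k, x$ch_score
  ))
  print(x$centroids)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.trajectory_clusters <- function(x, ...) x$centroids

#' @exportS3Method generics::glance
glance.trajectory_clusters <- function(x, ...) {
  tibble(
    k = x$k, ch_score = x$ch_score,
    n_subjects = nrow(x$labels),
    features = x$features, standardize = x$standardize
  )
}

#' @rdname cluster_subjects
#' @param object A `"trajectory_clusters"` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.trajectory_clusters <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$k, y = .data$ch_score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(
      data = object$profile[object$profile$k == object$k, ],
      colour = "red", size = 3
    ) +
    ggplot2::labs(
      x = "Number of clusters k",
      y = "Calinski-Harabasz score",
      title = "Cluster-number selection"
    ) +
    ggplot2::theme_minimal()
}
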