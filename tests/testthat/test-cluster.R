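# small helper: wrap a feature matrix in a minimal spline_fits tibble so
# cluster_subjects() can be exercised on hand-built geometry
fits_from_matrix <- function(m) {
  fits <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(nrow(m))),
    intercept = m[, 1], slope1 = m[, 2], slope2 = m[, 4],
    knot = 5, sse = 0, n_obs = 26, first_week = 1, last_week = 26,
    level_first = m[, 1], level_last = m[, 3]
  )
  attr(fits, "week_set") <- 1:26
  class(fits) <- c("spline_fits", class(fits))
  fits
}

two_blobs <- function(n_per = 10, gap = 100, seed = 31) {
  set.seed(seed)
  rbind(
    matrix(rnorm(n_per * 4, 0, 1), ncol = 4),
    matrix(rnorm(n_per * 4, gap, 1), ncol = 4)
  )
}

test_that("Ward clustering honours forced structure", {
  x <- two_blobs()
  expect_equal(length(unique(ward_cluster(x, nrow(x)))), nrow(x))
  lab <- ward_cluster(x, 2)
  expect_true(same_partition(lab, rep(1:2, each = 10)))
  expect_error(ward_cluster(x, 21), "exceed")
})

test_that("Ward agrees with a naive O(n^3) implementation", {
  set.seed(32)
  for (rep in 1:5) {
    x <- matrix(rnorm(20 * 3), ncol = 3)
    ref <- naive_ward(x)
    expect_true(all(diff(ref$heights) >= -1e-9)) # monotone agglomeration
    hc <- hclust(dist(x), method = "ward.D2")
    expect_equal(hc$height, ref$heights, tolerance = 1e-8)
    for (k in c(2, 4, 7)) {
      mine <- ward_cluster(x, k)
      naive <- ref$partitions[[nrow(x) - k]]
      expect_true(same_partition(mine, naive))
    }
  }
})

test_that("K-means consolidation is a fixed point at a local optimum", {
  x <- two_blobs()
  init <- rep(1:2, each = 10)
  out <- kmeans_consolidate(x, init)
  expect_equal(as.integer(out), init)
  expect_equal(attr(out, "reseeded"), 0L)
})

test_that("consolidation never degrades the Ward initialization", {
  wss <- function(x, lab) {
    sum(vapply(unique(lab), function(cl) {
      rows <- x[lab == cl, , drop = FALSE]
      sum(sweep(rows, 2, colMeans(rows))^2)
    }, numeric(1)))
  }
  set.seed(33)
  for (rep in 1:8) {
    x <- matrix(rnorm(40 * 4), ncol = 4)
    init <- ward_cluster(x, 4)
    out <- kmeans_consolidate(x, init)
    expect_lte(wss(x, out), wss(x, init) + 1e-9)
  }
})

test_that("final labels are the nearest-centroid assignment", {
  set.seed(34)
  x <- matrix(rnorm(60 * 4), ncol = 4)
  out <- kmeans_consolidate(x, ward_cluster(x, 5))
  centroids <- t(vapply(
    1:5, function(cl) colMeans(x[out == cl, , drop = FALSE]), numeric(4)
  ))
  d2 <- vapply(
    1:5, function(j) colSums((t(x) - centroids[j, ])^2), numeric(nrow(x))
  )
  expect_equal(as.integer(out), max.col(-d2, ties.method = "first"))
})

test_that("an emptied cluster is re-seeded, preserving k", {
  # third centroid starts midway between two tight blobs and loses all its
  # points in the first assignment round
  set.seed(30)
  x <- rbind(
    cbind(rnorm(10, 0, 0.1), rnorm(10, 0, 0.1)),
    cbind(rnorm(10, 10, 0.1), rnorm(10, 0, 0.1)),
    c(0, 0.2), c(10, 0.2)
  )
  init <- c(rep(1, 10), rep(2, 10), 3, 3)
  out <- kmeans_consolidate(x, init)
  expect_equal(sort(unique(as.integer(out))), 1:3)
  expect_gte(attr(out, "reseeded"), 1L)
  expect_error(kmeans_consolidate(x, c(rep(1, 21), 3)), "every label")
})

test_that("Calinski-Harabasz matches hand arithmetic and the ANOVA identity", {
  # six 1-D points in two clusters: B = 150, W = 4, CH = (150/1)/(4/4) = 150
  x <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  lab <- c(1, 1, 1, 2, 2, 2)
  expect_equal(calinski_harabasz(x, lab), 150)

  # duplicating every point keeps centroids; CH recomputed consistently:
  # B = 300, W = 8, n = 12 -> (300/1)/(8/10) = 375
  expect_equal(calinski_harabasz(rbind(x, x), c(lab, lab)), 375)

  # total = between + within for arbitrary labellings
  set.seed(35)
  y <- matrix(rnorm(30 * 3), ncol = 3)
  for (k in c(2, 3, 5)) {
    labr <- sample(1:k, 30, replace = TRUE)
    if (length(unique(labr)) < 2) next
    total <- sum(sweep(y, 2, colMeans(y))^2)
    parts <- vapply(unique(labr), function(cl) {
      rows <- y[labr == cl, , drop = FALSE]
      c(
        nrow(rows) * sum((colMeans(rows) - colMeans(y))^2),
        sum(sweep(rows, 2, colMeans(rows))^2)
      )
    }, numeric(2))
    expect_equal(sum(parts), total, tolerance = 1e-9)
  }
  expect_error(calinski_harabasz(x, rep(1, 6)), "2 <= k < n")
})

test_that("the CH search finds the planted number of clusters", {
  # four clouds separated by far more than their internal spread
  set.seed(36)
  centres <- rbind(c(0, -3, 0, 0), c(6, -1, 1, 0), c(6, 0, 4, 0), c(6, 0, 7, 0)) * 10
  m <- do.call(rbind, lapply(1:4, function(g) {
    sweep(matrix(rnorm(15 * 4, 0, 1), ncol = 4), 2, centres[g, ], "+")
  }))
  sol <- cluster_subjects(fits_from_matrix(m), k = NULL, k_range = 2:8)
  expect_equal(sol$k, 4)
  expect_equal(nrow(sol$profile), 7)
  expect_equal(sol$profile$k, 2:8)
  truth <- rep(1:4, each = 15)
  joined <- sol$labels$cluster
  expect_true(same_partition(joined, truth))

  two <- fits_from_matrix(two_blobs())
  expect_equal(cluster_subjects(two, k = NULL)$k, 2)
})

test_that("clustering is deterministic and labels follow the recovery order", {
  cohort <- simulate_cohort(n_subjects = 50, seed = 37)
  clean <- cohort |> filter_eligible() |> impute_missing() |> remove_constant()
  fits <- fit_splines(clean)
  a <- cluster_subjects(fits, k = 4)
  b <- cluster_subjects(fits, k = 4)
  expect_identical(a$labels, b$labels)
  expect_identical(a$ch_score, b$ch_score)

  # ordinal contract: cluster 1 ends best off, cluster k worst
  pred26 <- fits$level_last + fits$slope2 * (26 - fits$last_week)
  means <- tapply(pred26, a$labels$cluster, mean)
  expect_false(is.unsorted(means))
})

test_that("tidy, glance and autoplot expose the solution", {
  m <- two_blobs(6)
  sol <- cluster_subjects(fits_from_matrix(m), k = 2)
  expect_equal(nrow(generics::tidy(sol)), 2)
  expect_equal(generics::glance(sol)$k, 2)
  expect_s3_class(ggplot2::autoplot(sol), "ggplot")
})
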