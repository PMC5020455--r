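# Independent oracles used across the suite. These deliberately share no
# code with the package implementations they check.

# Naive O(n^3) Ward agglomeration (Lance-Williams update on squared
# Euclidean distances, heights on the distance scale as in "ward.D2").
naive_ward <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(dist(x))^2
  diag(d2) <- Inf
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  membership <- seq_len(n)
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- d2[idx, idx, drop = FALSE]
    flat <- which.min(sub)
    i <- idx[(flat - 1) %% length(idx) + 1]
    j <- idx[(flat - 1) %/% length(idx) + 1]
    if (i > j) {
      tmp <- i
      i <- j
      j <- tmp
    }
    heights[step] <- sqrt(d2[i, j])
    # merge j into i with the Ward Lance-Williams update
    for (k in which(active)) {
      if (k == i || k == j) next
      d2[i, k] <- ((sizes[i] + sizes[k]) * d2[i, k] +
        (sizes[j] + sizes[k]) * d2[j, k] -
        sizes[k] * d2[i, j]) / (sizes[i] + sizes[j] + sizes[k])
      d2[k, i] <- d2[i, k]
    }
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    membership[membership == j] <- i
    partitions[[step]] <- match(membership, sort(unique(membership)))
  }
  list(heights = heights, partitions = partitions)
}

# TRUE when two label vectors describe the same partition of the points.
same_partition <- function(a, b) {
  identical(outer(a, a, "=="), outer(b, b, "=="))
}

# Exhaustive best-diagonal alignment of a square table, enumerating row
# permutations via expand.grid (independent of the package's recursion).
brute_force_alignment <- function(tab) {
  k <- nrow(tab)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  grid <- grid[apply(grid, 1, function(p) length(unique(p)) == k), , drop = FALSE]
  sums <- apply(grid, 1, function(p) sum(diag(tab[p, , drop = FALSE])))
  max(sums)
}

# Free-knot spline fit re-implemented through stats::lm on an explicit
# formula, same candidate rule and tie-break as the package documents.
oracle_spline <- function(weeks, values) {
  t1 <- min(weeks)
  cands <- seq(t1 + 2, max(weeks) - 2)
  cands <- cands[vapply(
    cands,
    function(k) sum(weeks <= k) >= 3 && sum(weeks > k) >= 2, logical(1)
  )]
  best <- NULL
  best_sse <- Inf
  best_knot <- NA
  for (k in cands) {
    df <- data.frame(y = values, a = weeks - t1, b = pmax(0, weeks - k))
    m <- lm(y ~ a + b, data = df)
    sse <- sum(residuals(m)^2)
    if (sse < best_sse - 1e-9) {
      best_sse <- sse
      best <- unname(coef(m))
      best_knot <- k
    }
  }
  list(
    intercept = best[1], slope1 = best[2], slope2 = best[2] + best[3],
    knot = best_knot, sse = best_sse
  )
}

# Default synthetic cohort cleaned by the standard pipeline, cached per
# test run (several tests reuse it).
default_clean_cohort <- local({
  cache <- NULL
  function(seed = 1) {
    if (is.null(cache)) {
      cohort <- simulate_cohort(seed = seed)
      cache <<- cohort |>
        filter_eligible() |>
        impute_missing() |>
        remove_constant()
    }
    cache
  }
})
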