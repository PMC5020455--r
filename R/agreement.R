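#' Cross-tabulate two cluster labelings of the same subjects
#'
#' @param labels_ref Reference-design cluster labels (columns).
#' @param labels_alt Comparison-design cluster labels (rows).
#' @return A square integer matrix: `counts[i, j]` is the number of
#'   subjects in comparison cluster `i` and reference cluster `j`.
#' @export
#' @examples
#' crosstab(c(1, 1, 2, 2), c(1, 2, 2, 2))
crosstab <- function(labels_ref, labels_alt) {
  if (length(labels_ref) != length(labels_alt)) {
    abort("The two labelings must cover the same subjects in the same order.")
  }
  k <- max(labels_ref, labels_alt)
  counts <- matrix(0L, k, k,
    dimnames = list(alt = seq_len(k), ref = seq_len(k))
  )
  for (i in seq_along(labels_ref)) {
    counts[labels_alt[i], labels_ref[i]] <- counts[labels_alt[i], labels_ref[i]] + 1L
  }
  counts
}

#' Match comparison clusters to reference clusters
#'
#' Fresh cluster runs label their clusters arbitrarily, so before any
#' agreement statistic the comparison clusters are matched to the
#' reference clusters by the row permutation that maximizes the diagonal
#' sum of the contingency table (exhaustive search over all `k!`
#' permutations - exact for the `k <= 8` used here). After alignment the
#' rows follow the reference's ordinal cluster order.
#'
#' @param table A square contingency table (see [crosstab()]).
#' @return A list with the permuted `table` and the `permutation` applied
#'   (`permutation[i]` = original row now in position `i`).
#' @export
align_labels <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table)) abort("`table` must be square.")
  k <- nrow(table)
  perms <- permutations(k)
  diag_sum <- vapply(
    seq_len(nrow(perms)),
    function(i) sum(diag(table[perms[i, ], , drop = FALSE])),
    numeric(1)
  )
  best <- perms[which.max(diag_sum), ]
  aligned <- table[best, , drop = FALSE]
  rownames(aligned) <- colnames(table)
  list(table = aligned, permutation = best)
}

#' @keywords internal
#' @noRd
permutations <- function(k) {
  if (k == 1) {
    return(matrix(1L, 1, 1))
  }
  sub <- permutations(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- seq_len(k)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1)))
  }
  out
}

#' Cohen's kappa of a contingency table
#'
#' Chance-corrected agreement
#' \deqn{\kappa = \frac{p_o - p_e}{1 - p_e}}
#' with observed agreement \eqn{p_o} the diagonal share and expected
#' agreement \eqn{p_e = \sum_i r_i c_i} the product of the row and column
#' margins.
#'
#' @param table A square contingency table with a positive total.
#' @return A list of class `"kappa_result"` with elements `kappa`,
#'   `observed_agreement`, `expected_agreement` and `interpretation`
#'   (see [interpret_kappa()]). `unclass()` or `$kappa` for the number.
#' @seealso [weighted_kappa()], [interpret_kappa()]
#' @export
#' @examples
#' tab <- crosstab(c(1, 1, 2, 2), c(1, 2, 2, 2))
#' cohen_kappa(tab)$kappa
cohen_kappa <- function(table) {
  kappa_impl(table, weights = NULL)
}

#' Quadratic-weighted kappa of a contingency table
#'
#' Kappa variant for ordinal cluster labels crediting near-misses, with
#' agreement weights
#' \deqn{w_{ij} = 1 - \frac{(i - j)^2}{(k - 1)^2}.}
#' For `k = 2` the quadratic weights reduce to the identity and the
#' weighted kappa equals Cohen's kappa.
#'
#' @inheritParams cohen_kappa
#' @return A list of class `"kappa_result"`; `$kappa` holds the weighted
#'   kappa.
#' @export
weighted_kappa <- function(table) {
  k <- nrow(as.matrix(table))
  w <- 1 - (outer(seq_len(k), seq_len(k), "-") / (k - 1))^2
  kappa_impl(table, weights = w)
}

#' @keywords internal
#' @noRd
kappa_impl <- function(table, weights = NULL) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table)) abort("`table` must be square.")
  n <- sum(table)
  if (n <= 0) abort("`table` must have a positive total.")
  if (is.null(weights)) weights <- diag(nrow(table))
  p <- table / n
  expected <- outer(rowSums(p), colSums(p))
  po <- sum(weights * p)
  pe <- sum(weights * expected)
  if (abs(1 - pe) < 1e-12) {
    abort("Expected agreement is 1 (all mass in one category); kappa is undefined.")
  }
  kappa <- (po - pe) / (1 - pe)
  structure(
    list(
      kappa = kappa,
      observed_agreement = po,
      expected_agreement = pe,
      interpretation = interpret_kappa(kappa)
    ),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf(
    "kappa = %.3f (observed %.3f, expected %.3f): %s agreement\n",
    x$kappa, x$observed_agreement, x$expected_agreement, x$interpretation
  ))
  invisible(x)
}

#' Landis-Koch interpretation band of a kappa value
#'
#' `"excellent"` above 0.75, `"poor"` below 0.40, `"fair-to-good"` in the
#' closed range 0.40-0.75.
#'
#' @param kappa A kappa value (at most 1).
#' @return Character band.
#' @export
#' @examples
#' interpret_kappa(c(0.823, 0.4, 0.272))
interpret_kappa <- function(kappa) {
  if (any(kappa > 1 + 1e-12)) abort("kappa cannot exceed 1.")
  ifelse(kappa > 0.75, "excellent",
    ifelse(kappa >= 0.40, "fair-to-good", "poor")
  )
}

#' Agreement between two clusterings of the same cohort
#'
#' Cross-tabulates the two cluster solutions on their common subjects,
#' aligns the comparison labels to the reference by [align_labels()], and
#' reports Cohen's kappa and the quadratic-weighted kappa.
#'
#' @param ref,alt `"trajectory_clusters"` objects (the reference design's
#'   and the comparison design's solutions), or plain label vectors of
#'   equal length.
#' @param align Match labels by maximal diagonal before computing kappa?
#'   (Keep `TRUE` unless the labelings are already matched.)
#' @return A one-row tibble: `k_ref`, `k_alt`, `kappa`,
#'   `weighted_kappa`, `observed_agreement`, `expected_agreement`,
#'   `interpretation` (band of the weighted kappa), with the aligned
#'   contingency table in the `"table"` attribute.
#' @export
cluster_agreement <- function(ref, alt, align = TRUE) {
  pair <- common_labels(ref, alt)
  tab <- crosstab(pair$ref, pair$alt)
  if (align) tab <- align_labels(tab)$table
  raw <- cohen_kappa(tab)
  weighted <- weighted_kappa(tab)
  out <- tibble(
    k_ref = length(unique(pair$ref)),
    k_alt = length(unique(pair$alt)),
    kappa = raw$kappa,
    weighted_kappa = weighted$kappa,
    observed_agreement = raw$observed_agreement,
    expected_agreement = raw$expected_agreement,
    interpretation = weighted$interpretation
  )
  attr(out, "table") <- tab
  out
}

#' @keywords internal
#' @noRd
common_labels <- function(ref, alt) {
  if (inherits(ref, "trajectory_clusters") && inherits(alt, "trajectory_clusters")) {
    joined <- dplyr::inner_join(
      ref$labels, alt$labels,
      by = "subject_id", suffix = c("_ref", "_alt")
    )
    list(ref = joined$cluster_ref, alt = joined$cluster_alt)
  } else {
    list(ref = as.integer(ref), alt = as.integer(alt))
  }
}

#' Reference contingency tables of the motivating study
#'
#' The motivating SMS low back pain study printed, for each reduced design
#' B-F, the 4x4 contingency table of its four-cluster solution against the
#' reference design A (all 26 weeks). These printed counts ship with the
#' package; each table totals 129 subjects with reference column margins
#' (17, 63, 23, 26).
#'
#' @return A named list of five 4x4 integer matrices (designs B-F), rows =
#'   comparison clusters, columns = reference clusters.
#' @seealso [kappa_reference()]
#' @export
reference_kappa_tables <- function() {
  path <- system.file("extdata", "reference_kappa_tables.csv",
    package = "painfreq", mustWork = TRUE
  )
  long <- readr::read_csv(path, col_types = readr::cols(
    design = readr::col_character(),
    alt_cluster = readr::col_integer(),
    ref_cluster = readr::col_integer(),
    n = readr::col_integer()
  ))
  split(long, long$design) %>%
    purrr::map(function(d) {
      m <- matrix(0L, 4, 4, dimnames = list(alt = 1:4, ref = 1:4))
      m[cbind(d$alt_cluster, d$ref_cluster)] <- d$n
      m
    })
}

#' Kappa agreement recomputed from the reference tables
#'
#' Recomputes Cohen's kappa and the quadratic-weighted kappa for every
#' design B-F from the printed contingency tables of the motivating study
#' (a pure verification mode - the tables are already label-matched, so
#' no alignment is applied).
#'
#' @return A tibble with one row per design: `design`, `kappa`,
#'   `weighted_kappa`, `interpretation` (band of the weighted kappa).
#' @export
#' @examples
#' kappa_reference()
kappa_reference <- function() {
  tables <- reference_kappa_tables()
  purrr::imap(tables, function(tab, nm) {
    tibble(
      design = nm,
      kappa = cohen_kappa(tab)$kappa,
      weighted_kappa = weighted_kappa(tab)$kappa,
      interpretation = interpret_kappa(weighted_kappa(tab)$kappa)
    )
  }) %>%
    bind_rows() %>%
    arrange(.data$design)
}
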