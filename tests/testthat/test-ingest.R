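test_that("write-then-read round trip preserves the cohort", {
  cohort <- simulate_cohort(n_subjects = 6, seed = 2)
  sf <- withr::local_tempfile(fileext = ".csv")
  cf <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, sf, cf)
  back <- read_cohort(sf, cf)
  expect_equal(
    as.data.frame(back[names(cohort)]),
    as.data.frame(cohort)
  )
})

test_that("blank nbd and absent week rows are read as missing", {
  sf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,week,nbd",
    "S1,1,3", "S1,2,", "S1,3,4",
    "S2,1,5", "S2,3,5" # week 2 absent entirely
  ), sf)
  cohort <- read_cohort(sf)
  expect_true(is.na(cohort$nbd[cohort$subject_id == "S1" & cohort$week == 2]))
  expect_true(is.na(cohort$nbd[cohort$subject_id == "S2" & cohort$week == 2]))
  expect_equal(nrow(cohort), 6)
})

test_that("raw input validation rejects bad rows and flags odd covariates", {
  sf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,week,nbd", "S1,1,3", "S1,2,9"), sf)
  expect_error(read_cohort(sf), "0-7")

  writeLines(c("subject_id,week,nbd", "S1,1,3", "S1,1,4"), sf)
  expect_error(read_cohort(sf), "Duplicated")

  writeLines(c("subject_id,week,nbd", "S1,1,3", "S1,2,2.5"), sf)
  expect_error(read_cohort(sf), "integer")

  writeLines(c("subject_id,week,nbd", "S1,1,3", "S1,2,4"), sf)
  cf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,duration_gt30", "S1,1", "GHOST,0"), cf)
  expect_warning(read_cohort(sf, cf), "GHOST")
})

test_that("eligibility boundary sits exactly at the minimum reply count", {
  base <- simulate_cohort(n_subjects = 3, missing_rate = 0, seed = 4)
  # S001 loses 3 weeks (23 observed, excluded), S002 loses 2 (24, kept)
  base$nbd[base$subject_id == "S001" & base$week %in% 1:3] <- NA
  base$nbd[base$subject_id == "S002" & base$week %in% 1:2] <- NA
  kept <- filter_eligible(base)
  expect_setequal(unique(kept$subject_id), c("S002", "S003"))
  expect_equal(exclusions(kept)$subject_id, "S001")
  expect_match(exclusions(kept)$reason, "23/26")
})

test_that("missing covariates exclude a subject; full cohorts pass untouched", {
  base <- simulate_cohort(n_subjects = 4, missing_rate = 0, seed = 4)
  base$duration_gt30[base$subject_id == "S004"] <- NA
  kept <- filter_eligible(base)
  expect_false("S004" %in% kept$subject_id)
  expect_match(exclusions(kept)$reason, "covariates")

  clean <- simulate_cohort(n_subjects = 4, missing_rate = 0, seed = 4)
  out <- filter_eligible(clean)
  expect_equal(nrow(out), nrow(clean))
  expect_equal(nrow(exclusions(out)), 0)
})

test_that("eligibility filtering conserves counts and is idempotent", {
  cohort <- simulate_cohort(n_subjects = 60, missing_rate = 0.15, seed = 6)
  kept <- filter_eligible(cohort)
  n_kept <- length(unique(kept$subject_id))
  n_excl <- nrow(exclusions(kept))
  expect_equal(n_kept + n_excl, 60)
  twice <- filter_eligible(kept)
  expect_equal(
    as.data.frame(dplyr::select(twice, subject_id, week, nbd)),
    as.data.frame(dplyr::select(kept, subject_id, week, nbd))
  )
})

test_that("imputation implements the nearest-observations rule", {
  x <- tibble::tibble(subject_id = "S1", week = 1:3, nbd = c(2, NA, 4))
  expect_equal(impute_missing(x)$nbd, c(2, 3, 4))

  # boundary missingness copies the nearest observed value
  y <- tibble::tibble(subject_id = "S1", week = 1:6, nbd = c(NA, 5, 4, 4, 5, NA))
  out <- impute_missing(y)
  expect_equal(out$nbd, c(5, 5, 4, 4, 5, 5))
  expect_equal(out$imputed, c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))

  # multi-week interior gaps interpolate linearly between the flanks
  z <- tibble::tibble(subject_id = "S1", week = 1:4, nbd = c(2, NA, NA, 5))
  expect_equal(impute_missing(z)$nbd, c(2, 3, 4, 5))
})

test_that("imputation never alters observed values nor leaves their range", {
  set.seed(8)
  for (i in 1:20) {
    nbd <- as.numeric(rbinom(26, 7, runif(1, 0.2, 0.8)))
    mask <- runif(26) < 0.25
    masked <- ifelse(mask, NA_real_, nbd)
    if (all(is.na(masked))) next
    out <- impute_missing(
      tibble::tibble(subject_id = "S1", week = 1:26, nbd = masked)
    )
    expect_equal(out$nbd[!mask], nbd[!mask])
    expect_true(all(out$nbd >= min(masked, na.rm = TRUE)))
    expect_true(all(out$nbd <= max(masked, na.rm = TRUE)))
    expect_false(anyNA(out$nbd))
  }
})

test_that("all-missing series are rejected", {
  x <- tibble::tibble(subject_id = "S1", week = 1:5, nbd = NA_real_)
  expect_error(impute_missing(x), "no observed values")
})

test_that("constant repliers are removed, near-constant kept", {
  cohort <- dplyr::bind_rows(
    tibble::tibble(subject_id = "A", week = 1:26, nbd = 7),
    tibble::tibble(subject_id = "B", week = 1:26, nbd = c(rep(7, 25), 6)),
    tibble::tibble(subject_id = "C", week = 1:26, nbd = 0)
  )
  kept <- remove_constant(cohort)
  expect_setequal(unique(kept$subject_id), "B")
  expect_setequal(exclusions(kept)$subject_id, c("A", "C"))

  no_const <- remove_constant(dplyr::filter(cohort, subject_id == "B"))
  expect_equal(nrow(exclusions(no_const)), 0)
})

test_that("the pipeline accumulates one exclusion log across steps", {
  cohort <- simulate_cohort(n_subjects = 80, seed = 9, constant_rate = 0.1)
  clean <- cohort |>
    filter_eligible() |>
    impute_missing() |>
    remove_constant()
  log <- exclusions(clean)
  expect_true(all(c("subject_id", "reason") %in% names(log)))
  expect_equal(
    length(unique(clean$subject_id)) + nrow(log), 80
  )
  expect_true(any(grepl("constant", log$reason)))
})
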