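test_that("validation enforces the study data model", {
  # state outside {1,2,3} rejected with the row number
  d <- rbind(subject_rows("A", c(0, 30, 60), c(1, 1, 3)),
             subject_rows("B", c(0, 30), c(2, 3)))
  d$state[2] <- 4
  expect_error(panel_dataset(d), "row 2")

  # non-increasing times name the subject
  d2 <- subject_rows("S1", c(0, 30, 30), c(1, 2, 3))
  expect_error(panel_dataset(d2), "S1")

  # normal state only as the final observation
  d3 <- subject_rows("S1", c(0, 30, 60), c(1, 3, 2))
  expect_error(panel_dataset(d3), "final observation")

  # first state must be hypothermic
  d4 <- rbind(subject_rows("S1", c(0, 30), c(3, 3)))
  expect_error(panel_dataset(d4), "hypothermic")

  # unknown covariate level rejected
  d5 <- subject_rows("S1", c(0, 30), c(1, 3))
  d5$birth_weight <- "huge"
  expect_error(panel_dataset(d5), "birth_weight")

  # fewer than two observations rejected
  d6 <- subject_rows("S1", 0, 1)
  expect_error(panel_dataset(d6), "fewer than 2")
})

test_that("CSV round trip is the identity on a simulated cohort", {
  sim <- small_cohort(n = 25, seed = 7)
  path <- tempfile(fileext = ".csv")
  write_panel_csv(sim$dataset, path)
  back <- read_panel_csv(path)
  expect_equal(back$data, sim$dataset$data)
  # row count equals total observations
  expect_equal(nrow(utils::read.csv(path)), nrow(sim$dataset$data))

  # schema remapping works and missing columns give a schema error
  d <- utils::read.csv(path)
  names(d)[1] <- "id"
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(d, path2, row.names = FALSE, na = "")
  expect_equal(read_panel_csv(path2, schema = c(subject_id = "id"))$data,
               sim$dataset$data)
  expect_error(read_panel_csv(path2), "subject_id")
})

test_that("study filters exclude by observation count and persistence", {
  d <- rbind(subject_rows("few", c(0, 30), c(2, 3)),
             subject_rows("persist", c(0, 30, 60, 90, 120, 150, 180),
                          c(1, 1, 2, 2, 2, 2, 2)),
             subject_rows("ok", c(0, 30, 60, 90), c(1, 2, 2, 3)))
  ds <- panel_dataset(d)
  res <- apply_study_filters(ds)
  expect_setequal(res$exclusions$subject_id, c("few", "persist"))
  expect_equal(res$exclusions$reason[res$exclusions$subject_id == "few"],
               "min_obs")
  expect_equal(res$exclusions$reason[res$exclusions$subject_id == "persist"],
               "persistent hypothermia")
  # retained subject unchanged
  expect_equal(unique(res$dataset$data$subject_id), "ok")
  expect_equal(res$dataset$data$state, c(1, 2, 2, 3))
  # with min_obs = 2 the first-scan recovery is retained
  res2 <- apply_study_filters(ds, min_obs = 2)
  expect_setequal(unique(res2$dataset$data$subject_id), c("few", "ok"))
})

test_that("post-filter invariant: >= min_obs observations, terminal state 3", {
  sim <- generate_cohort(fixture_config("paper-null", n_subjects = 150, seed = 3))
  filt <- apply_study_filters(sim$prefilter, min_obs = 3)
  for (id in unique(filt$dataset$data$subject_id)) {
    rows <- filt$dataset$data[filt$dataset$data$subject_id == id, ]
    expect_gte(nrow(rows), 3)
    expect_equal(rows$state[nrow(rows)], 3)
    expect_lte(max(rows$time_min), 180)
  }
})

test_that("occupancy table counts exact grid matches only", {
  ds <- toy_dataset()
  occ <- state_occupancy_table(ds, c(0, 30, 60))
  expect_equal(unname(occ[1, ]), c(1, 1, 0))
  expect_equal(unname(occ[2, ]), c(1, 0, 1))
  expect_equal(unname(occ[3, ]), c(0, 0, 1))
  # baseline: all subjects hypothermic, none normal
  sim <- small_cohort(n = 40, seed = 9)
  occ2 <- state_occupancy_table(sim$dataset, seq(0, 180, 30))
  expect_equal(sum(occ2[1, ]), n_subjects(sim$dataset))
  expect_equal(occ2[1, 3], c(normal = 0L), ignore_attr = TRUE)
})

test_that("transition counts follow the absorbed-cohort convention", {
  counts <- transition_count_table(toy_dataset())
  expected <- matrix(0L, 3, 3)
  expected[1, 1] <- 1L; expected[1, 3] <- 1L; expected[2, 3] <- 1L
  expected[3, 3] <- 2L
  expect_equal(unclass(counts), expected, ignore_attr = TRUE)

  # total = sum over subjects of (n_obs - 1) + number of absorbed subjects
  sim <- small_cohort(n = 35, seed = 5)
  ct <- transition_count_table(sim$dataset)
  d <- sim$dataset$data
  n_pairs <- sum(tapply(d$time_min, d$subject_id, length) - 1)
  n_abs <- sum(tapply(d$state, d$subject_id, function(s) s[length(s)] == 3))
  expect_equal(sum(unclass(ct)), n_pairs + n_abs)
})

test_that("row normalization and percent rendering match the printed table", {
  counts <- rbind(c(376, 137, 85), c(46, 542, 306), c(0, 0, 391))
  prop <- row_normalize(counts)
  expect_true(all(abs(rowSums(prop) - 1) < 1e-12))
  expect_true(all(prop >= 0 & prop <= 1))
  pct <- percent_matrix(counts)
  expect_equal(unname(pct[1, ]), c(63L, 23L, 14L))
  expect_equal(unname(pct[2, ]), c(5L, 61L, 34L))
  expect_equal(unname(pct[3, ]), c(0L, 0L, 100L))
  # zero rows stay zero; identity counts give identity proportions
  expect_equal(row_normalize(diag(3)), diag(3))
  z <- matrix(0, 3, 3)
  expect_equal(row_normalize(z), z)
})
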