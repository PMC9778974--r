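test_that("covariate sampling matches the configured frequencies", {
  cfg <- fixture_config("paper-null", seed = 1)
  set.seed(1)
  covs <- sample_covariates(cfg, 10000)
  # male fraction within 3 SE of 0.522
  p <- 204 / 391
  expect_lt(abs(mean(covs$sex == "male") - p), 3 * sqrt(p * (1 - p) / 10000))
  # birth-weight marginals renormalized from 35/246/120
  expect_lt(abs(mean(covs$birth_weight == "vlbw") - 35 / 401), 0.012)
  # degenerate frequencies always give that category
  cfg2 <- simulation_config(covariate_freqs = within(default_covariate_freqs(), {
    sex <- c(female = 0, male = 1)
  }))
  set.seed(2)
  expect_true(all(sample_covariates(cfg2, 50)$sex == "male"))
  # determinism
  set.seed(3); a <- sample_covariates(cfg, 100)
  set.seed(3); b <- sample_covariates(cfg, 100)
  expect_identical(a, b)
})

test_that("exact trajectory simulation obeys the jump-chain law", {
  Q <- build_Q(c("1->2" = 0.02, "2->1" = 0.01, "2->3" = 0.03))
  set.seed(7)
  # holding times in state 1 are Exp(0.02): mean 50 within 3 SE at n = 10000
  hold <- replicate(10000, {
    tr <- simulate_trajectory(Q, 1, 1e6)
    tr$times[2]
  })
  expect_lt(abs(mean(hold) - 50), 3 * 50 / sqrt(10000))
  # jumps from state 2 split q21 : q23 = 1 : 3
  set.seed(8)
  to <- replicate(10000, {
    tr <- simulate_trajectory(Q, 2, 1e6)
    tr$states[2]
  })
  p <- 0.03 / 0.04
  expect_lt(abs(mean(to == 3) - p), 3 * sqrt(p * (1 - p) / 10000))
  # absorbed start returns immediately
  expect_equal(simulate_trajectory(Q, 3, 100)$states, 3L)
})

test_that("panel observation stops at the first observed normal state", {
  # trajectory entering state 3 at 75 min: observed 1,?,?,3 at 0/30/60/90
  traj <- list(times = c(0, 40, 75), states = c(1, 2, 3))
  obs <- panel_observe(traj, 30, 180)
  expect_equal(obs$time_min, c(0, 30, 60, 90))
  expect_equal(obs$state, c(1, 1, 2, 3))
  # never reaching state 3: full 7-point grid
  traj2 <- list(times = 0, states = 2)
  expect_equal(nrow(panel_observe(traj2, 30, 180)), 7)
  # excursion through state 1 between scans is invisible: back in 2 each scan
  traj3 <- list(times = c(0, 31, 58), states = c(2, 1, 2))
  expect_equal(panel_observe(traj3, 30, 60)$state, c(2, 2, 2))
})

test_that("generated cohorts are reproducible and satisfy the data model", {
  cfg <- fixture_config("paper-null", n_subjects = 100, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$dataset$data, b$dataset$data)
  # every generated subject passes validation (validate_panel_dataset throws
  # on violation)
  expect_silent(validate_panel_dataset(a$prefilter))
  # ledger and dataset reconcile exactly through the filters
  expect_equal(length(a$ledger), 100)
  expect_equal(n_subjects(a$prefilter), 100)
  expect_equal(n_subjects(a$dataset) + nrow(a$exclusions), 100)
  # baseline severe fraction near 176/391
  p <- 176 / 391
  base <- a$prefilter$data[a$prefilter$data$time_min == 0, ]
  expect_lt(abs(mean(base$state == 1) - p), 3 * sqrt(p * (1 - p) / 100))
})

test_that("very fast recovery interacts with the min-obs filter as documented", {
  cfg <- simulation_config(n_subjects = 60,
                           q0 = c("1->2" = 0.5, "2->1" = 0.0, "2->3" = 0.5),
                           min_obs = 3, seed = 12)
  # nearly everyone absorbed by the first scan -> excluded under min_obs = 3
  sim <- tryCatch(suppressWarnings(generate_cohort(cfg)),
                  error = function(e) e)
  if (inherits(sim, "error")) {
    expect_match(conditionMessage(sim), "no subjects")
  } else {
    expect_gt(sum(sim$exclusions$reason == "min_obs"), 30)
  }
})

test_that("empirical panel transition fractions match P(interval) of the truth", {
  cfg <- fixture_config("paper-null", n_subjects = 3000, seed = 17)
  sim <- generate_cohort(cfg)
  # use the prefilter cohort: the law of one scan interval is P(30) exactly
  counts <- transition_count_table(sim$prefilter)
  P <- transition_probability_matrix(build_Q(cfg$q0), 30)
  emp <- row_normalize(unclass(counts))
  for (r in 1:2) for (s in 1:3) {
    n_r <- sum(unclass(counts)[r, ])
    se <- sqrt(P[r, s] * (1 - P[r, s]) / n_r)
    expect_lt(abs(emp[r, s] - P[r, s]), 4 * se + 1e-12)
  }
})
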