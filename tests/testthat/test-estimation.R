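test_that("crude initial rates follow the events-over-exposure definition", {
  # two 1->2 events over 120 person-minutes in state 1 -> 1/60 per minute
  d <- rbind(subject_rows("a", c(0, 30), c(1, 2)),
             subject_rows("b", c(0, 30, 60, 90), c(1, 1, 1, 2)))
  ds <- panel_dataset(d)
  init <- suppressWarnings(crude_initial_rates(ds))
  expect_equal(exp(unname(init$log_q0["1->2"])), 1 / 60)
  # zero observed 2->1 pairs floored at 1e-4 with a warning
  w <- capture_warnings(crude_initial_rates(ds))
  expect_true(any(grepl("2->1", w)))
  expect_equal(exp(unname(init$log_q0["2->1"])), 1e-4)
})

test_that("fit_msm maximizes the panel likelihood and satisfies the AIC identity", {
  sim <- generate_cohort(fixture_config("paper-null", n_subjects = 200, seed = 21))
  fit <- suppressWarnings(fit_msm(sim$dataset))
  expect_true(fit$converged)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params)
  expect_equal(fit$n_params, 3)
  # recovers truth loosely even at N = 200
  expect_lt(abs(exp(fit$par[1]) - 0.027) / 0.027, 0.35)
  expect_lt(abs(exp(fit$par[3]) - 0.020) / 0.020, 0.35)
  # the fitted point is a local maximum of the likelihood
  theta_hat <- fit$params
  ll_hat <- log_likelihood(theta_hat, NULL, fit$structure, sim$dataset)
  expect_equal(ll_hat, fit$loglik, tolerance = 1e-8)
  for (k in 1:3) {
    bump <- fit$par; bump[k] <- bump[k] + 0.05
    th <- model_params(log_q0 = setNames(bump[1:3], names(fit$params$log_q0)))
    expect_lt(log_likelihood(th, NULL, fit$structure, sim$dataset), ll_hat)
  }
  # vcov symmetric positive semidefinite
  expect_true(all(abs(fit$vcov - t(fit$vcov)) < 1e-8))
  expect_true(all(eigen(fit$vcov, symmetric = TRUE)$values > -1e-10))
})

test_that("estimates are invariant to subject order", {
  sim <- generate_cohort(fixture_config("paper-null", n_subjects = 80, seed = 31))
  d <- sim$dataset$data
  rev_ds <- panel_dataset(d[order(-match(d$subject_id, unique(d$subject_id)),
                                  d$time_min), ])
  f1 <- suppressWarnings(fit_msm(sim$dataset))
  f2 <- suppressWarnings(fit_msm(rev_ds))
  expect_equal(f1$par, f2$par, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("hazard ratios apply the delta-method Wald interval", {
  sim <- generate_cohort(fixture_config("paper-effects", n_subjects = 250,
                                        seed = 41))
  fit <- suppressWarnings(fit_msm(sim$dataset,
                                  model = covariate_model("birth_weight")))
  hr <- hazard_ratios(fit)
  expect_equal(nrow(hr), 3)
  expect_true(all(hr$lower <= hr$hr & hr$hr <= hr$upper))
  expect_true(all(hr$hr > 0))
  # closed form: hr = exp(beta), CI = exp(beta -/+ 1.96 se)
  i <- which(hr$transition == "1->2")
  b <- fit$par["beta(1->2).birth_weight"]
  se <- sqrt(diag(fit$vcov)["beta(1->2).birth_weight"])
  expect_equal(hr$hr[i], unname(exp(b)))
  expect_equal(hr$lower[i], unname(exp(b - qnorm(0.975) * se)))
  expect_equal(hr$upper[i], unname(exp(b + qnorm(0.975) * se)))
})

test_that("sojourn table reflects the covariate-adjusted intensities", {
  sim <- generate_cohort(fixture_config("paper-effects", n_subjects = 250,
                                        seed = 43))
  fit <- suppressWarnings(fit_msm(sim$dataset,
                                  model = covariate_model("birth_weight")))
  sj <- sojourn_table(fit, data.frame(birth_weight = c("vlbw", "lbw", "normal")))
  expect_true(all(sj$severe_minutes > 0 & is.finite(sj$severe_minutes)))
  # positive fitted effect on all severe exits => sojourn decreases in score
  b12 <- fit$params$beta["1->2", "birth_weight"]
  if (b12 > 0) expect_true(all(diff(sj$severe_minutes) < 0))
  # closed form at vlbw (score 0): 1 / q12_hat
  expect_equal(sj$severe_minutes[1], 1 / exp(unname(fit$par[1])))
  expect_error(sojourn_table(fit, data.frame(birth_weight = "tiny")),
               "unknown")
})

test_that("likelihood ratio test compares nested fits", {
  sim <- generate_cohort(fixture_config("paper-effects", n_subjects = 250,
                                        seed = 47))
  f0 <- suppressWarnings(fit_msm(sim$dataset))
  f1 <- suppressWarnings(fit_msm(sim$dataset,
                                 model = covariate_model("birth_weight")))
  lrt <- likelihood_ratio_test(f0, f1)
  expect_gte(unname(lrt$statistic), 0)
  expect_equal(unname(lrt$parameter), 3)
  expect_equal(unname(lrt$statistic), 2 * (f1$loglik - f0$loglik),
               tolerance = 1e-6)
  expect_error(likelihood_ratio_test(f1, f0), "nested")
  other <- generate_cohort(fixture_config("paper-null", n_subjects = 100,
                                          seed = 1))
  fo <- suppressWarnings(fit_msm(other$dataset))
  expect_error(likelihood_ratio_test(fo, f1), "same dataset")
})

test_that("epoch model generalizes the homogeneous fit", {
  sim <- generate_cohort(fixture_config("paper-null", n_subjects = 150, seed = 51))
  f0 <- suppressWarnings(fit_msm(sim$dataset))
  # no changepoints: identical to fit_msm
  fe0 <- suppressWarnings(fit_time_epoch_model(sim$dataset))
  expect_equal(fe0$loglik, f0$loglik, tolerance = 1e-8)
  expect_equal(fe0$n_params, f0$n_params)
  # one changepoint adds one multiplier per transition and cannot fit worse
  fe <- suppressWarnings(fit_time_epoch_model(sim$dataset, changepoints = 90))
  expect_equal(fe$n_params, f0$n_params + 3)
  expect_gte(fe$loglik, f0$loglik - 1e-6)
  # changepoint beyond follow-up: late epoch empty, multiplier frozen
  expect_warning(fit_time_epoch_model(sim$dataset, changepoints = 175),
                 "frozen")
  expect_error(fit_time_epoch_model(sim$dataset, changepoints = c(90, 60)),
               "increasing")
})

test_that("null model equals a beta-frozen covariate model", {
  sim <- generate_cohort(fixture_config("paper-null", n_subjects = 120, seed = 61))
  f0 <- suppressWarnings(fit_msm(sim$dataset))
  theta0 <- model_params(log_q0 = f0$params$log_q0,
                         beta = matrix(0, 3, 1,
                                       dimnames = list(c("1->2", "2->1", "2->3"),
                                                       "birth_weight")))
  ll <- log_likelihood(theta0, covariate_model("birth_weight"),
                       transition_structure(), sim$dataset)
  expect_equal(ll, f0$loglik, tolerance = 1e-8)
})
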