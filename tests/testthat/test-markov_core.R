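test_that("build_Q enforces structure and row sums", {
  Q <- build_Q(c("1->2" = 0.027, "2->1" = 0.005, "2->3" = 0.020))
  expect_equal(unname(Q[1, ]), c(-0.027, 0.027, 0))
  expect_equal(unname(Q[2, ]), c(0.005, -0.025, 0.020))
  expect_equal(unname(Q[3, ]), c(0, 0, 0))
  expect_equal(rowSums(Q), c(severe = 0, mild = 0, normal = 0))

  expect_equal(unname(build_Q(c("1->2" = 0))), matrix(0, 3, 3))
  expect_error(build_Q(c("1->3" = 0.01)), "disallowed")
  expect_error(build_Q(c("1->2" = -0.1)), "non-negative")
  expect_error(transition_structure("3->1"), "absorbing")
})

test_that("covariate action scales intensities log-linearly", {
  Q0 <- build_Q(c("1->2" = 0.027, "2->1" = 0.005, "2->3" = 0.020))
  prof <- list(birth_weight = "lbw") # ordinal score 1

  # zero effects leave Q unchanged
  beta0 <- matrix(0, 3, 1, dimnames = list(c("1->2", "2->1", "2->3"),
                                           "birth_weight"))
  m0 <- covariate_model("birth_weight", beta = beta0)
  expect_equal(apply_covariates(Q0, m0, prof), Q0)

  # beta = ln 1.5 multiplies the (1,2) intensity by exactly 1.5 at z = 1
  b <- beta0; b["1->2", 1] <- log(1.5)
  m1 <- covariate_model("birth_weight", beta = b)
  Q1 <- apply_covariates(Q0, m1, prof)
  expect_equal(Q1[1, 2], 0.027 * 1.5)
  expect_equal(rowSums(Q1), rowSums(Q0))

  # restricted mode: regressive scaling is the reciprocal of progressive
  mr <- covariate_model("birth_weight", mode = "restricted",
                        beta = c(birth_weight = 0.3))
  Qr <- apply_covariates(Q0, mr, prof)
  expect_equal(Qr[1, 2] / Q0[1, 2], exp(0.3))
  expect_equal(Qr[2, 1] / Q0[2, 1], 1 / exp(0.3))

  # dimension mismatch caught
  expect_error(apply_covariates(Q0, covariate_model("birth_weight",
                                                    beta = matrix(0, 3, 2)),
                                prof), "columns")
})

test_that("transition probabilities match the closed form and the ODE oracle", {
  # two-state sub-model: P11(30) = exp(-0.6)
  st <- transition_structure("1->2")
  Q <- build_Q(c("1->2" = 0.02), st)
  expect_equal(transition_probability_matrix(Q, 30)[1, 1], exp(-0.6),
               tolerance = 1e-10)
  expect_equal(transition_probability_ode(Q, 30)[1, 1], exp(-0.6),
               tolerance = 1e-8)

  # t = 0 and zero generator give the identity
  expect_equal(transition_probability_matrix(Q, 0), diag(3))
  expect_equal(unname(transition_probability_matrix(build_Q(c("1->2" = 0)), 45)),
               diag(3))
  expect_error(transition_probability_matrix(Q, -1), "non-negative")

  # expm path vs ODE oracle on random instances; stochasticity; monotone
  # absorption; semigroup property
  set.seed(101)
  for (i in 1:40) {
    Qr <- random_Q()
    for (t in c(5, 30, 90)) {
      P <- transition_probability_matrix(Qr, t)
      Po <- transition_probability_ode(Qr, t)
      expect_lt(max(abs(P - Po)), 1e-6)
      expect_true(all(abs(rowSums(P) - 1) < 1e-10))
      expect_true(all(P > -1e-12 & P < 1 + 1e-12))
    }
    s <- runif(1, 0, 180); t <- runif(1, 0, 180)
    expect_lt(max(abs(transition_probability_matrix(Qr, s + t) -
                      transition_probability_matrix(Qr, s) %*%
                      transition_probability_matrix(Qr, t))), 1e-8)
    probs13 <- vapply(c(15, 30, 60, 120, 180),
                      function(u) transition_probability_matrix(Qr, u)[1, 3],
                      numeric(1))
    expect_true(all(diff(probs13) > -1e-10))
  }
})

test_that("mean sojourn is the negative reciprocal of the diagonal", {
  Q <- build_Q(c("1->2" = 0.027, "2->1" = 0.005, "2->3" = 0.020))
  expect_equal(mean_sojourn(Q, 1), 1 / 0.027)
  expect_equal(mean_sojourn(Q, 2), 40)
  expect_error(mean_sojourn(Q, 3), "absorbing")
  # doubling all exit intensities halves the sojourn
  Q2 <- build_Q(c("1->2" = 0.054, "2->1" = 0.010, "2->3" = 0.040))
  expect_equal(mean_sojourn(Q2, 1), mean_sojourn(Q, 1) / 2)
  expect_equal(mean_sojourn(Q2, 2), mean_sojourn(Q, 2) / 2)
})

test_that("panel log-likelihood matches closed forms and the ODE oracle", {
  # one subject observed 1 -> 1 over 30 minutes in the two-state sub-model
  st <- transition_structure("1->2")
  d <- subject_rows("S1", c(0, 30), c(1, 1))
  ds <- panel_dataset(d)
  theta <- model_params(log_q0 = c("1->2" = log(0.02)))
  expect_equal(log_likelihood(theta, NULL, st, ds), -0.6, tolerance = 1e-10)

  # oracle equivalence on a simulated cohort: recompute with ODE probabilities
  sim <- small_cohort(n = 20, seed = 11)
  theta2 <- model_params(log_q0 = c("1->2" = log(0.027), "2->1" = log(0.005),
                                    "2->3" = log(0.020)))
  ll <- log_likelihood(theta2, NULL, transition_structure(), sim$dataset)
  Q <- build_Q(exp(theta2$log_q0))
  brute <- 0
  d <- sim$dataset$data
  for (id in unique(d$subject_id)) {
    rows <- d[d$subject_id == id, ]
    for (j in 2:nrow(rows)) {
      P <- transition_probability_ode(Q, rows$time_min[j] - rows$time_min[j - 1])
      brute <- brute + log(P[rows$state[j - 1], rows$state[j]])
    }
  }
  expect_equal(ll, brute, tolerance = 1e-6)

  # invariant to subject order and to splitting the dataset and summing
  perm <- panel_dataset(d[order(-match(d$subject_id, unique(d$subject_id)),
                                d$time_min), ])
  expect_equal(log_likelihood(theta2, NULL, transition_structure(), perm), ll)
  ids <- unique(d$subject_id)
  half <- ids[1:10]
  ll_a <- log_likelihood(theta2, NULL, transition_structure(),
                         panel_dataset(d[d$subject_id %in% half, ]))
  ll_b <- log_likelihood(theta2, NULL, transition_structure(),
                         panel_dataset(d[!d$subject_id %in% half, ]))
  expect_equal(ll_a + ll_b, ll, tolerance = 1e-10)
})
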