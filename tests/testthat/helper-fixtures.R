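# Small in-code fixtures shared across the test files.

default_covs <- function() {
  list(sex = "male", birth_weight = "lbw", apgar5 = "moderate",
       pulse = "normal", resp_rate = "normal", spo2 = "normal")
}

subject_rows <- function(id, times, states, covs = default_covs()) {
  cbind(data.frame(subject_id = id, time_min = times, state = states,
                   stringsAsFactors = FALSE),
        as.data.frame(covs, stringsAsFactors = FALSE))
}

# the two-subject toy cohort: A observes 1,1,3 at 0/30/60; B observes 2,3 at 0/30
toy_dataset <- function() {
  panel_dataset(rbind(subject_rows("A", c(0, 30, 60), c(1, 1, 3)),
                      subject_rows("B", c(0, 30), c(2, 3))))
}

# random valid generator under the default transition structure
random_Q <- function() {
  build_Q(c("1->2" = runif(1, 0.001, 0.05),
            "2->1" = runif(1, 0.001, 0.05),
            "2->3" = runif(1, 0.001, 0.05)))
}

# small simulated cohort for round-trip and likelihood tests
small_cohort <- function(n = 30, seed = 42, fixture = "paper-null") {
  generate_cohort(fixture_config(fixture, n_subjects = n, seed = seed))
}
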