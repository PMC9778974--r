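#' Binning scheme for the Pearson-type goodness-of-fit test
#'
#' Observation pairs are cross-classified by covariate stratum, elapsed
#' interval-length category, time since study start (the pair's start time)
#' and from-state before comparing observed and model-expected destination
#' counts. Defaults: interval terciles (which collapse to a single category
#' on an exact 30-minute grid), start-time terciles (the dimension that gives
#' the test power against time-inhomogeneity when all intervals are equal),
#' strata by the ordinal score of the first model covariate (a single
#' stratum for covariate-free fits), and cells pooled below an expected
#' count of 5.
#'
#' @param interval_breaks explicit cut points on interval length, or NULL for
#'   terciles of the observed intervals.
#' @param time_breaks explicit cut points on the pair's start time, or NULL
#'   for terciles of the observed start times; NA disables this dimension.
#' @param strata_covariate covariate name used for stratification, or NULL
#'   for the fit's first covariate (no strata if the fit has none).
#' @param min_expected minimum expected count per retained cell.
#' @return object of class `gof_binning`.
#' @export
gof_binning <- function(interval_breaks = NULL, time_breaks = NULL,
                        strata_covariate = NULL, min_expected = 5) {
  if (!is.null(interval_breaks) && is.unsorted(interval_breaks, strictly = TRUE))
    stop("interval_breaks must be strictly increasing")
  if (!is.null(time_breaks) && !anyNA(time_breaks) &&
      is.unsorted(time_breaks, strictly = TRUE))
    stop("time_breaks must be strictly increasing")
  stopifnot(min_expected > 0)
  structure(list(interval_breaks = interval_breaks,
                 time_breaks = time_breaks,
                 strata_covariate = strata_covariate,
                 min_expected = min_expected),
            class = "gof_binning")
}

# pair-level frame with fitted transition probabilities
gof_pair_frame <- function(fit, ds, binning) {
  d <- ds$data
  q0 <- build_Q(exp(fit$params$log_q0), fit$structure)
  strat_cov <- binning$strata_covariate
  if (is.null(strat_cov) && !is.null(fit$model))
    strat_cov <- fit$model$covariates[1]
  rows <- list()
  for (id in unique(d$subject_id)) {
    sub <- d[d$subject_id == id, , drop = FALSE]
    n <- nrow(sub)
    if (n < 2) next
    stratum <- if (is.null(strat_cov)) {
      "all"
    } else {
      as.character(sub[[strat_cov]][1])
    }
    Q <- if (is.null(fit$model)) {
      q0
    } else {
      m <- fit$model; m$beta <- fit$params$beta
      apply_covariates(q0, m, sub[1, ], fit$structure)
    }
    rows[[id]] <- data.frame(
      from = sub$state[-n], to = sub$state[-1],
      dt = diff(sub$time_min), tstart = sub$time_min[-n], stratum = stratum,
      qkey = paste(round(Q[cbind(c(1, 2, 2), c(2, 1, 3))], 12), collapse = ","),
      stringsAsFactors = FALSE)
    rows[[id]]$Q <- replicate(n - 1, Q, simplify = FALSE)
  }
  do.call(rbind, rows)
}

#' Pearson-type goodness-of-fit test for panel-observed Markov models
#'
#' Observation pairs are partitioned into cells by covariate stratum,
#' interval-length category and from-state; within each cell the observed
#' destination counts are compared with the fitted expected counts (sum over
#' the cell's pairs of the fitted transition probabilities `P_rs(dt; z)`).
#' Cells with small expected counts are pooled (smallest merged together)
#' until every retained cell reaches the threshold. The statistic is
#' `sum (obs - exp)^2 / exp`. Because parameters are estimated, the
#' chi-square reference with `df = retained cells - free parameters`
#' (floored at 1) is a heuristic; a parametric bootstrap (simulate from the
#' fitted model, refit, recompute) is available as the principled
#' alternative.
#'
#' @param fit a `panel_msm` fitted to `ds`.
#' @param ds the `panel_dataset` the fit was produced from.
#' @param binning a [gof_binning()].
#' @param p_method "chisq" or "parametric_bootstrap".
#' @param n_boot bootstrap replicates when `p_method` is
#'   "parametric_bootstrap".
#' @return object of class `gof_result`: list with `statistic`, `df`,
#'   `p_value`, `method` and the cell table (`cells`).
#' @export
pearson_gof <- function(fit, ds, binning = gof_binning(),
                        p_method = c("chisq", "parametric_bootstrap"),
                        n_boot = 200) {
  p_method <- match.arg(p_method)
  if (fit$n_subjects != n_subjects(ds))
    stop("fit was not produced from this dataset (subject count mismatch)")
  stat_cells <- gof_statistic(fit, ds, binning)
  df <- max(1L, nrow(stat_cells$cells) - fit$n_params)
  p <- pchisq(stat_cells$statistic, df, lower.tail = FALSE)
  method <- sprintf("Pearson-type GOF, chi-square reference (df = %d)", df)
  if (p_method == "parametric_bootstrap") {
    boot <- replicate(n_boot, {
      sim <- simulate_from_fit(fit, ds)
      refit <- tryCatch(
        suppressWarnings(fit_msm(sim, fit$structure, fit$model,
                                 fit_options(max_iterations = 200))),
        error = function(e) NULL)
      if (is.null(refit)) NA_real_
      else gof_statistic(refit, sim, binning)$statistic
    })
    boot <- boot[is.finite(boot)]
    p <- (1 + sum(boot >= stat_cells$statistic)) / (1 + length(boot))
    method <- sprintf("Pearson-type GOF, parametric bootstrap (%d replicates)",
                      length(boot))
  }
  structure(list(statistic = stat_cells$statistic, df = df, p_value = p,
                 method = method, cells = stat_cells$cells),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

# observed/expected cells and the Pearson statistic
gof_statistic <- function(fit, ds, binning) {
  pf <- gof_pair_frame(fit, ds, binning)
  if (is.null(pf) || nrow(pf) == 0) stop("no observation pairs for GOF")
  breaks <- binning$interval_breaks
  if (is.null(breaks)) {
    qs <- unique(quantile(pf$dt, c(1 / 3, 2 / 3)))
    breaks <- qs[qs > min(pf$dt) & qs < max(pf$dt)]
  }
  pf$interval_cat <- if (length(breaks) == 0) {
    "all"
  } else {
    as.character(cut(pf$dt, c(-Inf, breaks, Inf), labels = FALSE))
  }
  tbreaks <- binning$time_breaks
  if (is.null(tbreaks)) {
    qs <- unique(quantile(pf$tstart, c(1 / 3, 2 / 3)))
    tbreaks <- qs[qs > min(pf$tstart) & qs < max(pf$tstart)]
  } else if (anyNA(tbreaks)) {
    tbreaks <- numeric(0)
  }
  pf$time_cat <- if (length(tbreaks) == 0) {
    "all"
  } else {
    as.character(cut(pf$tstart, c(-Inf, tbreaks, Inf), labels = FALSE))
  }
  cells <- list()
  for (g in split(pf, list(pf$stratum, pf$interval_cat, pf$time_cat, pf$from),
                  drop = TRUE)) {
    expd <- obs <- numeric(3)
    for (i in seq_len(nrow(g))) {
      P <- transition_probability_matrix(g$Q[[i]], g$dt[i])
      expd <- expd + P[g$from[i], ]
      obs[g$to[i]] <- obs[g$to[i]] + 1
    }
    keep <- expd > 1e-12 # destinations structurally reachable
    cl <- data.frame(stratum = g$stratum[1], interval_cat = g$interval_cat[1],
                     time_cat = g$time_cat[1],
                     from = g$from[1], to = which(keep),
                     observed = obs[keep], expected = expd[keep],
                     stringsAsFactors = FALSE)
    # pool: merge the two smallest-expected cells until all pass the threshold
    while (nrow(cl) > 1 && any(cl$expected < binning$min_expected)) {
      ord <- order(cl$expected)
      i1 <- ord[1]; i2 <- ord[2]
      cl$observed[i2] <- cl$observed[i2] + cl$observed[i1]
      cl$expected[i2] <- cl$expected[i2] + cl$expected[i1]
      cl$to[i2] <- NA # pooled destination
      cl <- cl[-i1, , drop = FALSE]
    }
    if (nrow(cl) == 1 && cl$expected[1] < binning$min_expected) next
    cells[[length(cells) + 1]] <- cl
  }
  if (length(cells) == 0)
    stop("data too sparse for GOF: all cells pooled away")
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  statistic <- sum((cells$observed - cells$expected)^2 / cells$expected)
  list(statistic = statistic, cells = cells)
}

#' Simulate a dataset from a fitted model
#'
#' Generates a new panel dataset from the fitted intensities, keeping each
#' subject's covariates, initial state and observation schedule (scans stop
#' at the first simulated normal state, as in the study design; no cohort
#' filters are re-applied). This is the parametric-bootstrap generator behind
#' [pearson_gof()] and the natural source of correctly-specified data for
#' calibration studies. Uses the current RNG state.
#'
#' @param fit a `panel_msm`.
#' @param ds the `panel_dataset` the fit was produced from.
#' @return a `panel_dataset`.
#' @export
simulate_from_fit <- function(fit, ds) {
  d <- ds$data
  q0 <- build_Q(exp(fit$params$log_q0), fit$structure)
  out <- list()
  for (id in unique(d$subject_id)) {
    sub <- d[d$subject_id == id, , drop = FALSE]
    Q <- if (is.null(fit$model)) {
      q0
    } else {
      m <- fit$model; m$beta <- fit$params$beta
      apply_covariates(q0, m, sub[1, ], fit$structure)
    }
    max_t <- max(sub$time_min)
    traj <- simulate_trajectory(Q, sub$state[1], max_t + 1)
    grid <- sub$time_min
    states <- trajectory_state_at(traj, grid)
    hit <- which(states == 3)
    keep <- if (length(hit) > 0) seq_len(hit[1]) else seq_along(grid)
    if (length(keep) < 2) keep <- seq_len(2) # keep at least one pair
    obs <- sub[keep, , drop = FALSE]
    obs$state <- states[keep]
    out[[id]] <- obs
  }
  d2 <- do.call(rbind, out)
  rownames(d2) <- NULL
  panel_dataset(d2, provenance = "bootstrap:simulated-from-fit",
                validate = FALSE)
}

#' Stay-probability curve for a transient state
#'
#' Two readings of "probability of remaining in a state" are provided:
#' `no_exit` is `exp(q_ss t)` — the probability of not yet having left state
#' s — and `occupancy` is `P_ss(t)` — the probability of being in s at time t
#' given a start in s, allowing re-entries. Both are evaluated at the
#' cohort-average covariate profile of the fit.
#'
#' @param fit a `panel_msm`.
#' @param state transient state (1 or 2).
#' @param grid evaluation times in minutes.
#' @param mode "no_exit" or "occupancy".
#' @return data.frame with columns `time`, `probability`, `mode`.
#' @export
stay_probability_curve <- function(fit, state, grid = seq(0, 180, by = 10),
                                   mode = c("no_exit", "occupancy")) {
  mode <- match.arg(mode)
  Q <- fitted_Q_mean(fit)
  if (Q[state, state] >= 0)
    stop("state ", state, " is absorbing; stay probability is degenerate")
  prob <- if (mode == "no_exit") {
    exp(Q[state, state] * grid)
  } else {
    vapply(grid, function(t) transition_probability_matrix(Q, t)[state, state],
           numeric(1))
  }
  data.frame(time = grid, probability = prob, mode = mode)
}

# covariate-adjusted Q at the (pair-weighted) average design vector
fitted_Q_mean <- function(fit) {
  q0 <- build_Q(exp(fit$params$log_q0), fit$structure)
  zbar <- fit$mean_design
  if (is.null(fit$params$beta) || length(zbar) == 0) return(q0)
  Q <- q0
  for (k in seq_len(nrow(fit$structure))) {
    nm <- transition_names(fit$structure)[k]
    b <- beta_for_transition(fit$params$beta, fit$model, nm, fit$structure)
    Q[fit$structure[k, 1], fit$structure[k, 2]] <-
      q0[fit$structure[k, 1], fit$structure[k, 2]] * exp(sum(b * zbar))
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Expected versus observed state prevalence over time
#'
#' Per grid time, the observed state counts alongside the model-expected
#' counts (sum over subjects of `P_{x0, s}(t; z)` from each subject's
#' baseline state). Subjects absorbed before t are counted in the normal
#' state on both sides, so every row totals the number of subjects.
#'
#' @param fit a `panel_msm` fitted to `ds`.
#' @param ds the `panel_dataset`.
#' @param grid times (minutes), a subset of the observation grid.
#' @return data.frame with columns `time`, `state`, `observed`, `expected`.
#' @export
expected_vs_observed_prevalence <- function(fit, ds,
                                            grid = seq(0, 180, by = 30)) {
  d <- ds$data
  q0 <- build_Q(exp(fit$params$log_q0), fit$structure)
  out <- list()
  subj_ids <- unique(d$subject_id)
  Qs <- lapply(subj_ids, function(id) {
    sub <- d[d$subject_id == id, , drop = FALSE]
    if (is.null(fit$model)) {
      q0
    } else {
      m <- fit$model; m$beta <- fit$params$beta
      apply_covariates(q0, m, sub[1, ], fit$structure)
    }
  })
  first_state <- vapply(subj_ids, function(id)
    d$state[d$subject_id == id][1], integer(1))
  for (t in grid) {
    obs <- numeric(3); expd <- numeric(3)
    for (i in seq_along(subj_ids)) {
      sub <- d[d$subject_id == subj_ids[i], , drop = FALSE]
      at <- sub$state[sub$time_min == t]
      if (length(at) == 1) {
        obs[at] <- obs[at] + 1
      } else if (max(sub$time_min) < t && sub$state[nrow(sub)] == 3) {
        obs[3] <- obs[3] + 1 # absorbed before t
      }
      P <- transition_probability_matrix(Qs[[i]], t)
      expd <- expd + P[first_state[i], ]
    }
    out[[as.character(t)]] <- data.frame(time = t, state = .state_labels,
                                         observed = obs, expected = expd)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
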