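#' Fitting options for the panel Markov model
#'
#' @param initializer "crude" (rates from [crude_initial_rates()]) or "user"
#'   (supply `start`).
#' @param start a [model_params()] used when `initializer = "user"`.
#' @param max_iterations maximum quasi-Newton iterations.
#' @param tol convergence tolerance on the relative log-likelihood change.
#' @param restarts number of random restarts around the initializer.
#' @param seed seed for the restart perturbations.
#' @return object of class `fit_options`.
#' @export
fit_options <- function(initializer = c("crude", "user"), start = NULL,
                        max_iterations = 500, tol = 1e-8, restarts = 0,
                        seed = NULL) {
  initializer <- match.arg(initializer)
  stopifnot(tol > 0, restarts >= 0)
  structure(list(initializer = initializer, start = start,
                 max_iterations = max_iterations, tol = tol,
                 restarts = restarts, seed = seed),
            class = "fit_options")
}

#' Crude initial transition rates from observed panel pairs
#'
#' For each allowed transition (r,s), the number of observed r-to-s pairs
#' divided by the total person-minutes observed in state r (sum of interval
#' lengths over pairs starting in r), floored at 1e-4; covariate coefficients
#' start at zero. This treats panel pairs as if transitions were observed
#' exactly — a standard, consistent-enough starting value for the
#' quasi-Newton search.
#'
#' @param ds a valid `panel_dataset`.
#' @param structure a [transition_structure()].
#' @return a [model_params()] with `log_q0` filled in and no beta.
#' @export
crude_initial_rates <- function(ds, structure = transition_structure()) {
  pairs <- prepare_pairs(ds, model = NULL)
  crude_from_pairs(pairs, structure)
}

crude_from_pairs <- function(pairs, structure) {
  tab <- pairs$table
  rates <- numeric(nrow(structure))
  names(rates) <- transition_names(structure)
  exposure <- vapply(1:3, function(r) sum(tab$n[tab$from == r] * tab$dt[tab$from == r]),
                     numeric(1))
  any_event <- FALSE
  for (k in seq_len(nrow(structure))) {
    r <- structure[k, 1]; s <- structure[k, 2]
    ev <- sum(tab$n[tab$from == r & tab$to == s])
    if (ev > 0) any_event <- TRUE
    rate <- if (exposure[r] > 0) ev / exposure[r] else 0
    if (rate < 1e-4) {
      warning("no (or almost no) observed ", transition_names(structure)[k],
              " pairs; crude rate floored at 1e-4")
      rate <- 1e-4
    }
    rates[k] <- rate
  }
  if (!any_event)
    stop("degenerate data: no observed transitions for any allowed pair")
  model_params(log_q0 = log(rates))
}

# ---- parameter (un)flattening ----------------------------------------------
flat_names <- function(structure, model, design_cols) {
  nms <- paste0("logq(", transition_names(structure), ")")
  if (length(design_cols) > 0) {
    if (!is.null(model) && model$mode == "restricted") {
      nms <- c(nms, paste0("beta.", design_cols))
    } else {
      nms <- c(nms, as.vector(outer(transition_names(structure), design_cols,
                                    function(tr, cl) paste0("beta(", tr, ").", cl))))
    }
  }
  nms
}

unflatten <- function(par, structure, model, design_cols) {
  K <- nrow(structure)
  log_q0 <- setNames(par[seq_len(K)], transition_names(structure))
  beta <- NULL
  if (length(design_cols) > 0) {
    rest <- par[-seq_len(K)]
    if (!is.null(model) && model$mode == "restricted") {
      beta <- setNames(rest, design_cols)
    } else {
      beta <- matrix(rest, nrow = K,
                     dimnames = list(transition_names(structure), design_cols))
    }
  }
  model_params(log_q0 = log_q0, beta = beta)
}

# ---- core fitter over an aggregated pair table ------------------------------
fit_core <- function(pairs, structure, model, options, design_cols) {
  init <- if (options$initializer == "user" && !is.null(options$start)) {
    options$start
  } else {
    crude_from_pairs(pairs, structure)
  }
  K <- nrow(structure)
  nbeta <- if (is.null(model) || model$mode != "restricted") {
    K * length(design_cols)
  } else {
    length(design_cols)
  }
  if (length(design_cols) == 0) nbeta <- 0
  par0 <- c(init$log_q0, rep(0, nbeta))
  if (!is.null(init$beta)) par0 <- c(init$log_q0, as.vector(init$beta))
  names(par0) <- flat_names(structure, model, design_cols)

  negll <- function(par) {
    theta <- unflatten(par, structure, model, design_cols)
    -loglik_pairs(theta, structure, pairs, model)
  }
  f0 <- negll(par0)
  if (!is.finite(f0)) stop("non-finite likelihood at the initial values")

  run_one <- function(p0) {
    optim(p0, negll, method = "BFGS", hessian = FALSE,
          control = list(maxit = options$max_iterations,
                         reltol = options$tol))
  }
  best <- run_one(par0)
  if (options$restarts > 0) {
    if (!is.null(options$seed)) set.seed(options$seed)
    for (r in seq_len(options$restarts)) {
      cand <- tryCatch(run_one(par0 + stats::rnorm(length(par0), sd = 0.5)),
                       error = function(e) NULL)
      if (!is.null(cand) && cand$value < best$value) best <- cand
    }
  }
  hess <- tryCatch(stats::optimHess(best$par, negll), error = function(e) NULL)
  vcov <- NULL
  if (!is.null(hess)) {
    vcov <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vcov)) {
      dimnames(vcov) <- list(names(par0), names(par0))
      if (any(diag(vcov) < -1e-8)) vcov <- NULL
    }
  }
  if (is.null(vcov))
    warning("observed information is singular or not positive definite; ",
            "covariance unavailable")
  theta_hat <- unflatten(setNames(best$par, names(par0)), structure, model,
                         design_cols)
  ll <- -best$value
  p <- length(par0)
  structure(list(
    params = theta_hat,
    par = setNames(best$par, names(par0)),
    vcov = vcov,
    loglik = ll,
    n_params = p,
    aic = -2 * ll + 2 * p,
    converged = best$convergence == 0,
    structure = structure,
    model = model,
    design_cols = design_cols,
    n_subjects = pairs$n_subjects,
    n_transitions = pairs$n_pairs,
    mean_design = pairs$mean_design,
    optim = list(value = best$value, counts = best$counts,
                 convergence = best$convergence)
  ), class = "panel_msm")
}

#' Fit the three-state panel Markov model by maximum likelihood
#'
#' Maximizes the panel log-likelihood over the log baseline intensities and
#' (optionally) covariate coefficients by quasi-Newton (BFGS) iteration,
#' starting from [crude_initial_rates()]. Uncertainty comes from the observed
#' information: the covariance is the inverse numerical Hessian at the
#' optimum. `aic = -2 loglik + 2 p` with `p` the number of free parameters.
#'
#' @param ds a valid `panel_dataset` (ideally already passed through
#'   [apply_study_filters()]).
#' @param structure a [transition_structure()].
#' @param model a [covariate_model()] (its `beta` is ignored and estimated),
#'   or NULL for the no-covariate null model.
#' @param options a [fit_options()].
#' @return object of class `panel_msm` with elements `params`, `par`, `vcov`,
#'   `loglik`, `n_params`, `aic`, `converged`, plus echoes of the structure,
#'   model and data size.
#' @export
fit_msm <- function(ds, structure = transition_structure(), model = NULL,
                    options = fit_options()) {
  if (n_subjects(ds) < 20)
    warning("fewer than 20 subjects; estimates may be unstable")
  pairs <- prepare_pairs(ds, model)
  design_cols <- if (is.null(model)) character(0) else design_names(model)
  # small-sample guard on free transitions
  for (k in seq_len(nrow(structure))) {
    r <- structure[k, 1]; s <- structure[k, 2]
    npairs <- sum(pairs$table$n[pairs$table$from == r & pairs$table$to == s])
    if (npairs < 5)
      warning("fewer than 5 observed ", transition_names(structure)[k],
              " pairs; consider the restricted (Marshall-Jones) mode")
  }
  fit <- fit_core(pairs, structure, model, options, design_cols)
  fit$changepoints <- NULL
  fit
}

#' @export
print.panel_msm <- function(x, ...) {
  cat("Three-state panel Markov model fit\n")
  cat(sprintf("  subjects: %d   observation pairs: %d\n",
              x$n_subjects, x$n_transitions))
  cat(sprintf("  log-likelihood: %.4f   AIC: %.4f   parameters: %d%s\n",
              x$loglik, x$aic, x$n_params,
              if (x$converged) "" else "   [NOT CONVERGED]"))
  cat("  baseline intensities (per minute):\n")
  q <- exp(x$params$log_q0)
  for (nm in names(q)) cat(sprintf("    %s: %.5f\n", nm, q[[nm]]))
  if (!is.null(x$params$beta)) {
    cat("  covariate coefficients (log hazard-ratio scale):\n")
    print(x$params$beta)
  }
  invisible(x)
}

#' @export
logLik.panel_msm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' Hazard ratios with Wald 95% confidence intervals
#'
#' `exp(beta)` per (transition, design column), with delta-method 95%
#' intervals `exp(beta +/- 1.96 SE)` from the observed-information
#' covariance.
#'
#' @param fit a converged `panel_msm` with available `vcov`.
#' @param conf confidence level (default 0.95).
#' @return data.frame with columns `transition`, `covariate`, `hr`, `lower`,
#'   `upper`, `se_log`.
#' @export
hazard_ratios <- function(fit, conf = 0.95) {
  if (is.null(fit$vcov))
    stop("covariance unavailable for this fit; see fit diagnostics ",
         "(singular observed information)")
  idx <- grep("^beta", names(fit$par))
  if (length(idx) == 0) stop("fit has no covariate coefficients")
  zq <- qnorm(1 - (1 - conf) / 2)
  b <- fit$par[idx]
  se <- sqrt(diag(fit$vcov)[idx])
  nm <- names(fit$par)[idx]
  trans <- sub("^beta\\(([^)]*)\\)\\..*$", "\\1", nm)
  trans[!grepl("^beta\\(", nm)] <- "(shared)"
  covar <- sub("^beta(\\([^)]*\\))?\\.", "", nm)
  data.frame(transition = trans, covariate = covar,
             hr = exp(b), lower = exp(b - zq * se), upper = exp(b + zq * se),
             se_log = se, row.names = NULL, stringsAsFactors = FALSE)
}

#' Mean sojourn times for a set of covariate profiles
#'
#' For each profile, builds the covariate-adjusted intensity matrix from the
#' fitted parameters and reports the mean sojourn time (minutes) in the
#' severe and mild states.
#'
#' @param fit a converged `panel_msm`.
#' @param profiles data.frame with one row per profile (columns = the model's
#'   covariates), or a list of named lists/vectors.
#' @return data.frame with one row per profile: the profile columns plus
#'   `severe_minutes` and `mild_minutes`.
#' @export
sojourn_table <- function(fit, profiles) {
  if (!fit$converged) warning("fit did not converge; sojourn table may be unreliable")
  if (is.data.frame(profiles)) {
    plist <- split(profiles, seq_len(nrow(profiles)))
  } else {
    plist <- profiles
  }
  q0 <- build_Q(exp(fit$params$log_q0), fit$structure)
  rows <- lapply(plist, function(pr) {
    Q <- if (is.null(fit$model)) {
      q0
    } else {
      m <- fit$model; m$beta <- fit$params$beta
      apply_covariates(q0, m, pr, fit$structure)
    }
    data.frame(severe_minutes = mean_sojourn(Q, 1),
               mild_minutes = mean_sojourn(Q, 2))
  })
  out <- do.call(rbind, rows)
  if (is.data.frame(profiles)) out <- cbind(profiles, out)
  rownames(out) <- NULL
  out
}

#' Likelihood-ratio test of nested panel Markov models
#'
#' Statistic `2 (loglik_alt - loglik_null)` clipped at zero, degrees of
#' freedom the difference in free parameter counts, p-value from the
#' chi-square upper tail.
#'
#' @param fit_null,fit_alt nested `panel_msm` fits of the same dataset (the
#'   null's parameter set contained in the alternative's).
#' @return object of class `htest`.
#' @export
likelihood_ratio_test <- function(fit_null, fit_alt) {
  if (fit_alt$n_params <= fit_null$n_params)
    stop("models are not nested: the alternative must have more free parameters")
  if (fit_null$n_subjects != fit_alt$n_subjects ||
      fit_null$n_transitions != fit_alt$n_transitions)
    stop("fits are not based on the same dataset")
  stat <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  df <- fit_alt$n_params - fit_null$n_params
  structure(list(
    statistic = c("LR chi-square" = stat),
    parameter = c(df = df),
    p.value = pchisq(stat, df, lower.tail = FALSE),
    method = "Likelihood ratio test of nested panel Markov models",
    data.name = sprintf("%d subjects, %d observation pairs",
                        fit_alt$n_subjects, fit_alt$n_transitions)
  ), class = "htest")
}

#' Piecewise-constant (time-epoch) intensity model
#'
#' Tests time homogeneity: follow-up is split at the given changepoints into
#' epochs, each observation pair is attributed to the epoch containing its
#' start time, and the epoch index enters the intensity of every allowed
#' transition as a log-linear multiplier (first epoch = reference). With no
#' changepoints this is identical to the homogeneous [fit_msm()] null model.
#' Comparing the two with [likelihood_ratio_test()] tests homogeneity.
#'
#' @param ds a valid `panel_dataset`.
#' @param structure a [transition_structure()].
#' @param changepoints strictly increasing times (minutes) within the
#'   follow-up window.
#' @param options a [fit_options()].
#' @return object of class `panel_msm`.
#' @export
fit_time_epoch_model <- function(ds, structure = transition_structure(),
                                 changepoints = numeric(0),
                                 options = fit_options()) {
  if (length(changepoints) == 0) return(fit_msm(ds, structure, NULL, options))
  if (is.unsorted(changepoints, strictly = TRUE) || any(changepoints <= 0))
    stop("changepoints must be strictly increasing and positive")
  pairs <- prepare_pairs(ds, model = NULL, changepoints = changepoints)
  design_cols <- paste0("epoch", seq_along(changepoints) + 1)
  # freeze the multiplier of any epoch with zero observed pairs
  pat <- do.call(rbind, pairs$patterns)
  w <- vapply(names(pairs$patterns),
              function(k) sum(pairs$table$n[pairs$table$zkey == k]), numeric(1))
  seen <- colSums(pat * w) > 0
  if (!all(seen)) {
    dropped <- design_cols[!seen]
    warning("epoch(s) with zero observed pairs: multiplier frozen at 1 for ",
            paste(dropped, collapse = ", "))
    pairs$patterns <- lapply(pairs$patterns, function(z) z[seen])
    design_cols <- design_cols[seen]
  }
  fit <- fit_core(pairs, structure, model = NULL, options, design_cols)
  fit$changepoints <- changepoints
  fit
}
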