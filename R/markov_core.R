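#' Transition structure of the three-state recovery model
#'
#' Declares which instantaneous transitions have nonzero intensity. The
#' default allows severe <-> mild and mild -> normal; the direct severe ->
#' normal jump is disallowed (observed severe-to-normal panel pairs are
#' explained by passing through the mild state between scans) but can be
#' switched on. The normal state is absorbing: no pair may leave state 3.
#'
#' @param allowed character vector of "r->s" strings (or list of length-2
#'   integer vectors).
#' @return object of class `transition_structure`: an integer matrix with
#'   columns `from`, `to` and rownames "r->s".
#' @export
#' @examples
#' transition_structure()                         # default
#' transition_structure(c("1->2", "1->3", "2->1", "2->3"))
transition_structure <- function(allowed = c("1->2", "2->1", "2->3")) {
  if (is.list(allowed))
    allowed <- vapply(allowed, function(p) paste0(p[1], "->", p[2]), character(1))
  parts <- strsplit(allowed, "->", fixed = TRUE)
  m <- t(vapply(parts, function(p) as.integer(p), integer(2)))
  colnames(m) <- c("from", "to")
  rownames(m) <- allowed
  if (any(is.na(m)) || any(m < 1) || any(m > 3))
    stop("transitions must be between states 1, 2, 3")
  if (any(m[, 1] == m[, 2])) stop("self-transitions are not allowed")
  if (any(m[, 1] == 3))
    stop("state 3 (normal) is absorbing: no transition may leave it")
  if (nrow(m) == 0) stop("at least one transition must be allowed")
  structure(m, class = c("transition_structure", class(m)))
}

transition_names <- function(structure) rownames(structure)

#' Build an intensity matrix from baseline transition rates
#'
#' Constructs the 3x3 generator Q (units: per minute): supplied off-diagonal
#' intensities, diagonal set to minus the row sum so rows sum exactly to
#' zero, and an identically zero absorbing row for the normal state.
#'
#' @param baseline named numeric vector of intensities, names "r->s", keys a
#'   subset of the allowed transitions.
#' @param structure a [transition_structure()].
#' @return 3x3 numeric generator matrix.
#' @export
#' @examples
#' build_Q(c("1->2" = 0.027, "2->1" = 0.005, "2->3" = 0.020))
build_Q <- function(baseline, structure = transition_structure()) {
  if (any(baseline < 0)) stop("transition intensities must be non-negative")
  bad <- setdiff(names(baseline), transition_names(structure))
  if (length(bad) > 0)
    stop("intensity supplied for disallowed transition(s): ",
         paste(bad, collapse = ", "))
  Q <- matrix(0, 3, 3, dimnames = list(from = .state_labels, to = .state_labels))
  for (nm in names(baseline)) {
    idx <- which(transition_names(structure) == nm)
    Q[structure[idx, 1], structure[idx, 2]] <- baseline[[nm]]
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# design vector z for one covariate profile under a covariate model
design_vector <- function(model, profile) {
  z <- numeric(0)
  for (v in model$covariates) {
    levs <- .cov_levels[[v]]
    val <- as.character(profile[[v]])
    if (is.null(val) || is.na(val) || !(val %in% levs))
      stop("profile has unknown or missing level for covariate '", v, "'")
    score <- match(val, levs) - 1L
    if (model$coding == "ordinal") {
      z <- c(z, setNames(score, v))
    } else { # dummy (treatment) coding against the first level
      dum <- as.numeric(seq_along(levs)[-1] - 1L == score)
      z <- c(z, setNames(dum, paste0(v, levs[-1])))
    }
  }
  z
}

# names of the design columns implied by a covariate model
design_names <- function(model) {
  unlist(lapply(model$covariates, function(v) {
    if (model$coding == "ordinal") v else paste0(v, .cov_levels[[v]][-1])
  }))
}

#' Covariate model on transition intensities
#'
#' Log-linear (proportional-intensity) covariate action: the intensity of an
#' allowed transition (r,s) for a subject with design vector z is
#' `q_rs(0) * exp(beta_rs . z)`. Three-level covariates are coded ordinally
#' by default (scores 0/1/2 in the level order of [covariate_levels()]);
#' dummy (treatment) coding is available. In `restricted` (Marshall-Jones)
#' mode all progressive transitions (towards recovery: 1->2, 2->3, 1->3)
#' share one coefficient vector and all regressive transitions (2->1) use
#' its negation.
#'
#' @param covariates character vector of covariate names (default: the three
#'   covariates of the fitted study model).
#' @param coding "ordinal" or "dummy".
#' @param mode "full" (one coefficient vector per transition) or "restricted"
#'   (Marshall-Jones).
#' @param beta coefficient values: in full mode a matrix with one row per
#'   allowed transition (rownames "r->s") and one column per design column;
#'   in restricted mode a single numeric vector. NULL = to be estimated.
#' @return object of class `covariate_model`.
#' @export
covariate_model <- function(covariates = c("birth_weight", "apgar5", "pulse"),
                            coding = c("ordinal", "dummy"),
                            mode = c("full", "restricted"),
                            beta = NULL) {
  coding <- match.arg(coding)
  mode <- match.arg(mode)
  unknown <- setdiff(covariates, names(.cov_levels))
  if (length(unknown) > 0)
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "))
  structure(list(covariates = covariates, coding = coding, mode = mode,
                 beta = beta),
            class = "covariate_model")
}

# beta row (named numeric) for transition "r->s" given a covariate model and
# structure; handles full and restricted modes
beta_for_transition <- function(beta, model, trans_name, structure) {
  if (!is.null(model) && model$mode == "restricted") {
    idx <- which(transition_names(structure) == trans_name)
    sgn <- if (structure[idx, 2] > structure[idx, 1]) 1 else -1
    sgn * beta
  } else {
    beta[trans_name, , drop = TRUE]
  }
}

#' Apply covariate effects to a baseline intensity matrix
#'
#' Scales each allowed off-diagonal intensity by `exp(beta_rs . z)` for the
#' given covariate profile; zero intensities stay zero and the diagonal is
#' recomputed so rows sum to zero.
#'
#' @param q0 baseline 3x3 generator (from [build_Q()]).
#' @param model a [covariate_model()] whose `beta` is set.
#' @param profile named list/vector of covariate levels for one subject.
#' @param structure the [transition_structure()] used to build `q0`.
#' @return covariate-adjusted 3x3 generator.
#' @export
apply_covariates <- function(q0, model, profile,
                             structure = transition_structure()) {
  z <- design_vector(model, profile)
  nz <- length(z)
  if (model$mode == "restricted") {
    if (length(model$beta) != nz)
      stop("beta length ", length(model$beta),
           " does not match design dimension ", nz)
  } else {
    if (is.null(dim(model$beta)) || ncol(model$beta) != nz)
      stop("beta must be a matrix with ", nz, " columns (one per design column)")
  }
  Q <- q0
  for (k in seq_len(nrow(structure))) {
    r <- structure[k, 1]; s <- structure[k, 2]
    b <- beta_for_transition(model$beta, model, transition_names(structure)[k],
                             structure)
    Q[r, s] <- q0[r, s] * exp(sum(b * z))
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Interval transition probabilities via the matrix exponential
#'
#' Solves the Kolmogorov forward equations dP/dt = P Q with P(0) = I in
#' closed form, P(t) = expm(Q t), using a scaling-and-squaring matrix
#' exponential.
#'
#' @param Q 3x3 generator matrix.
#' @param t elapsed time in minutes (non-negative scalar).
#' @return 3x3 stochastic matrix P(t).
#' @export
transition_probability_matrix <- function(Q, t) {
  if (length(t) != 1 || is.na(t) || t < 0) stop("t must be a non-negative scalar")
  if (t == 0) return(diag(3))
  P <- as.matrix(Matrix::expm(Q * t))
  dimnames(P) <- dimnames(Q)
  P
}

#' Interval transition probabilities by direct ODE integration
#'
#' Numerically integrates the Kolmogorov forward equations dP/dt = P Q from
#' the identity with tight tolerances. This path is independent of the
#' matrix-exponential implementation and serves as a cross-check of
#' [transition_probability_matrix()].
#'
#' @param Q 3x3 generator matrix.
#' @param t elapsed time in minutes (non-negative scalar).
#' @param rtol,atol integrator tolerances.
#' @return 3x3 stochastic matrix P(t).
#' @export
transition_probability_ode <- function(Q, t, rtol = 1e-10, atol = 1e-12) {
  if (length(t) != 1 || is.na(t) || t < 0) stop("t must be a non-negative scalar")
  if (t == 0) return(diag(3))
  deriv <- function(time, y, parms) {
    P <- matrix(y, 3, 3)
    list(as.vector(P %*% parms))
  }
  sol <- deSolve::ode(y = as.vector(diag(3)), times = c(0, t), func = deriv,
                      parms = Q, rtol = rtol, atol = atol)
  if (any(is.na(sol[nrow(sol), -1])))
    stop("ODE integration of the forward equations failed")
  P <- matrix(sol[nrow(sol), -1], 3, 3)
  dimnames(P) <- dimnames(Q)
  P
}

#' Mean sojourn time in a transient state
#'
#' The expected continuous time spent in a transient state per visit,
#' `-1 / q_ss` (minutes).
#'
#' @param Q 3x3 generator matrix.
#' @param state state code (1 or 2; must be transient, i.e. `q_ss < 0`).
#' @return mean sojourn time in minutes.
#' @export
#' @examples
#' mean_sojourn(build_Q(c("1->2" = 0.027, "2->1" = 0.005, "2->3" = 0.020)), 1)
mean_sojourn <- function(Q, state) {
  if (Q[state, state] >= 0)
    stop("state ", state, " is absorbing; mean sojourn is undefined")
  -1 / Q[state, state]
}

#' Model parameters of the intensity regression
#'
#' @param log_q0 named numeric vector of log baseline intensities, names
#'   "r->s" covering every allowed transition.
#' @param beta coefficient matrix/vector as in [covariate_model()], or NULL
#'   for a model without covariates.
#' @return object of class `model_params`.
#' @export
model_params <- function(log_q0, beta = NULL) {
  if (any(!is.finite(log_q0))) stop("log baseline intensities must be finite")
  if (!is.null(beta) && any(!is.finite(beta))) stop("beta must be finite")
  structure(list(log_q0 = log_q0, beta = beta), class = "model_params")
}

# --- internal pair-table machinery -----------------------------------------
# Aggregates a dataset into unique (design pattern, dt, from, to) cells so the
# likelihood costs one matrix exponential per unique (pattern, dt).
#
# extra_design: optional function(subject_rows, pair_start_time) -> named
# numeric, used by the epoch model to append pair-level design columns.
prepare_pairs <- function(ds, model = NULL, changepoints = NULL) {
  d <- ds$data
  ids <- unique(d$subject_id)
  from <- integer(0); to <- integer(0); dt <- numeric(0)
  zkey <- character(0); zrows <- list()
  for (id in ids) {
    rows <- d[d$subject_id == id, , drop = FALSE]
    z <- if (is.null(model)) numeric(0) else design_vector(model, rows[1, ])
    n <- nrow(rows)
    if (n < 2) next
    for (j in 2:n) {
      zj <- z
      if (!is.null(changepoints) && length(changepoints) > 0) {
        ep <- findInterval(rows$time_min[j - 1], changepoints)
        dum <- as.numeric(seq_along(changepoints) == ep)
        zj <- c(z, setNames(dum, paste0("epoch", seq_along(changepoints) + 1)))
      }
      key <- paste0("z:", paste(zj, collapse = ","))
      if (is.null(zrows[[key]])) zrows[[key]] <- zj
      from <- c(from, rows$state[j - 1]); to <- c(to, rows$state[j])
      dt <- c(dt, rows$time_min[j] - rows$time_min[j - 1])
      zkey <- c(zkey, key)
    }
  }
  tab <- aggregate(list(n = rep(1L, length(from))),
                   by = list(zkey = zkey, dt = dt, from = from, to = to),
                   FUN = sum)
  list(table = tab, patterns = zrows,
       n_subjects = length(ids), n_pairs = length(from),
       mean_design = if (length(zrows) > 0 && length(zrows[[1]]) > 0) {
         w <- table(zkey)[names(zrows)]
         colSums(do.call(rbind, zrows) * as.numeric(w)) / sum(w)
       } else numeric(0))
}

# log-likelihood from an aggregated pair table; theta is a model_params whose
# beta columns must match the pattern design columns
loglik_pairs <- function(theta, structure, pairs, model = NULL) {
  q0 <- build_Q(exp(theta$log_q0), structure)
  tab <- pairs$table
  ll <- 0
  for (key in names(pairs$patterns)) {
    z <- pairs$patterns[[key]]
    Q <- q0
    if (length(z) > 0 && !is.null(theta$beta)) {
      for (k in seq_len(nrow(structure))) {
        nm <- transition_names(structure)[k]
        b <- beta_for_transition(theta$beta, model, nm, structure)
        Q[structure[k, 1], structure[k, 2]] <-
          q0[structure[k, 1], structure[k, 2]] * exp(sum(b * z))
      }
      diag(Q) <- 0
      diag(Q) <- -rowSums(Q)
    }
    sub <- tab[tab$zkey == key, , drop = FALSE]
    for (delta in unique(sub$dt)) {
      P <- transition_probability_matrix(Q, delta)
      if (any(!is.finite(P))) return(-1e10) # expm overflow at extreme rates
      cells <- sub[sub$dt == delta, , drop = FALSE]
      p <- P[cbind(cells$from, cells$to)]
      # floor before log (underflow-safe) and cap at 1 so that rounding
      # error in the matrix exponential can never reward the optimizer
      p <- pmin(pmax(p, 1e-300), 1)
      ll <- ll + sum(cells$n * log(p))
    }
  }
  ll
}

#' Panel log-likelihood of the multi-state Markov model
#'
#' Sum over subjects and consecutive observation pairs of
#' `log P_{x(j-1), x(j)}(t_j - t_{j-1}; z_subject)`, the likelihood of
#' interval-censored panel observations under a time-homogeneous Markov
#' process. Transition probabilities are floored at 1e-300 before taking
#' logs, so the result is a finite (large negative) value rather than -Inf
#' when a required probability underflows.
#'
#' @param theta a [model_params()].
#' @param model a [covariate_model()] or NULL for no covariates.
#' @param structure a [transition_structure()].
#' @param ds a valid `panel_dataset`.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(theta, model = NULL,
                           structure = transition_structure(), ds) {
  pairs <- prepare_pairs(ds, model)
  loglik_pairs(theta, structure, pairs, model)
}
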