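#' Construct a panel dataset of neonatal hypothermia observations
#'
#' A `panel_dataset` holds long-format panel observations: one row per
#' (subject, observation time), with the hypothermia state coded 1 (severe or
#' moderate), 2 (mild) or 3 (normal) and subject-level covariates repeated on
#' every row. Validation enforces the study's data model: strictly increasing
#' times within subject, at least two observations, a hypothermic state (1 or
#' 2) at the first observation, and the normal state appearing at most once
#' and only as the final observation (first-hitting-time design; state 3 is
#' absorbing).
#'
#' @param data data.frame with columns `subject_id`, `time_min`, `state`, the
#'   required covariates `sex`, `birth_weight`, `apgar5`, `pulse`, and
#'   optionally `resp_rate` and `spo2` (NA = missing optional covariate).
#' @param provenance free-text metadata (source file or simulation config
#'   digest).
#' @param validate run full validation (default TRUE).
#' @return An object of class `panel_dataset`.
#' @seealso [read_panel_csv()], [generate_cohort()]
#' @export
panel_dataset <- function(data, provenance = "", validate = TRUE) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (v in .optional_covs) if (!v %in% names(data)) data[[v]] <- NA_character_
  # normalize storage so that write/read round trips compare equal
  if ("subject_id" %in% names(data)) data$subject_id <- as.character(data$subject_id)
  if ("time_min" %in% names(data)) data$time_min <- as.numeric(data$time_min)
  if ("state" %in% names(data) && !anyNA(suppressWarnings(as.integer(data$state))))
    data$state <- as.integer(data$state)
  for (v in intersect(c(.required_covs, .optional_covs), names(data)))
    data[[v]] <- as.character(data[[v]])
  rownames(data) <- NULL
  ds <- structure(list(data = data, provenance = provenance),
                  class = "panel_dataset")
  if (validate) validate_panel_dataset(ds)
  ds
}

#' Validate a panel dataset against the study data model
#'
#' @param ds a `panel_dataset`.
#' @return `ds`, invisibly, if valid; otherwise an error describing the first
#'   violation (naming the offending subject or row).
#' @export
validate_panel_dataset <- function(ds) {
  d <- ds$data
  req <- c("subject_id", "time_min", "state", .required_covs)
  miss <- setdiff(req, names(d))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(d) == 0) stop("dataset is empty")
  bad <- which(!(d$state %in% 1:3))
  if (length(bad) > 0)
    stop("invalid state label '", d$state[bad[1]], "' at row ", bad[1],
         " (states must be 1, 2 or 3)")
  if (!is.numeric(d$time_min) || any(is.na(d$time_min)) || any(d$time_min < 0))
    stop("time_min must be non-negative numeric with no missing values")
  for (v in c(.required_covs, .optional_covs)) {
    vals <- as.character(d[[v]])
    ok <- vals %in% .cov_levels[[v]]
    if (v %in% .optional_covs) ok <- ok | is.na(vals) | vals == ""
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop("unknown level '", vals[bad], "' for covariate '", v,
           "' at row ", bad)
    }
    if (v %in% .required_covs && anyNA(vals))
      stop("missing required covariate '", v, "'")
  }
  for (id in unique(d$subject_id)) {
    rows <- d[d$subject_id == id, , drop = FALSE]
    if (nrow(rows) < 2)
      stop("subject '", id, "' has fewer than 2 observations")
    if (is.unsorted(rows$time_min, strictly = TRUE))
      stop("times not strictly increasing within subject '", id, "'")
    if (!(rows$state[1] %in% c(1, 2)))
      stop("subject '", id, "' is not hypothermic (state 1 or 2) at first observation")
    i3 <- which(rows$state == 3)
    if (length(i3) > 1 || (length(i3) == 1 && i3 != nrow(rows)))
      stop("subject '", id,
           "': normal state (3) may appear at most once and only as the final observation")
    cv <- rows[, c(.required_covs, .optional_covs), drop = FALSE]
    if (any(vapply(cv, function(x) length(unique(as.character(x))) > 1, logical(1))))
      stop("subject '", id, "' has time-varying covariates; covariates are subject-level constants")
  }
  invisible(ds)
}

#' @export
print.panel_dataset <- function(x, ...) {
  d <- x$data
  n <- length(unique(d$subject_id))
  cat("panel_dataset:", n, "subjects,", nrow(d), "observations\n")
  absorbed <- sum(tapply(d$state, d$subject_id, function(s) s[length(s)] == 3))
  cat("  reached normal state:", absorbed, "subjects\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
as.data.frame.panel_dataset <- function(x, ...) x$data

#' Number of subjects in a panel dataset
#' @param ds a `panel_dataset`.
#' @return integer count.
#' @export
n_subjects <- function(ds) length(unique(ds$data$subject_id))

#' Read a long-format panel CSV
#'
#' Expected header (the canonical schema):
#' `subject_id,time_min,state,sex,birth_weight,apgar5,pulse,resp_rate,spo2`,
#' with `state` coded 1/2/3 and categories as the lowercase tokens of
#' [covariate_levels()]; an empty cell is a missing optional covariate.
#' `schema` remaps non-canonical column names.
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(subject_id = "id")`.
#' @return A validated `panel_dataset`, rows grouped by subject and sorted by
#'   time.
#' @export
read_panel_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(d))
        stop("schema error: column '", schema[[canon]], "' (mapped to '",
             canon, "') not found in ", path)
      names(d)[names(d) == schema[[canon]]] <- canon
    }
  }
  req <- c("subject_id", "time_min", "state", .required_covs)
  miss <- setdiff(req, names(d))
  if (length(miss) > 0)
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  for (v in .optional_covs) {
    if (!v %in% names(d)) d[[v]] <- NA_character_
    d[[v]][!is.na(d[[v]]) & d[[v]] == ""] <- NA_character_
  }
  d <- d[order(match(d$subject_id, unique(d$subject_id)), d$time_min), ,
         drop = FALSE]
  rownames(d) <- NULL
  panel_dataset(d, provenance = paste0("csv:", path))
}

#' Write a panel dataset to long-format CSV
#'
#' One row per observation, covariates repeated per row. The canonical column
#' order is used so that `read_panel_csv(write_panel_csv(ds))` returns a
#' dataset equal to `ds`.
#'
#' @param ds a valid `panel_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(ds, path) {
  validate_panel_dataset(ds)
  cols <- c("subject_id", "time_min", "state", .required_covs, .optional_covs)
  utils::write.csv(ds$data[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply the study's inclusion/exclusion filters
#'
#' Emulates the cohort definition: subjects observed at fewer than `min_obs`
#' time points are excluded, as are subjects still hypothermic (state 1 or 2)
#' at their last observation within `max_followup` minutes (persistent
#' hypothermia — never reached the normal state within three hours). Nothing
#' else is truncated.
#'
#' @param ds a valid `panel_dataset`.
#' @param max_followup follow-up horizon in minutes (default 180).
#' @param min_obs minimum number of observation time points (default 3).
#' @return list with elements `dataset` (the filtered `panel_dataset`; may be
#'   empty) and `exclusions` (data.frame `subject_id`, `reason` with one row
#'   per excluded subject).
#' @export
apply_study_filters <- function(ds, max_followup = 180, min_obs = 3) {
  d <- ds$data
  ids <- unique(d$subject_id)
  reasons <- character(0); excl <- character(0)
  for (id in ids) {
    rows <- d[d$subject_id == id, , drop = FALSE]
    within <- rows[rows$time_min <= max_followup, , drop = FALSE]
    if (nrow(rows) < min_obs) {
      excl <- c(excl, id); reasons <- c(reasons, "min_obs")
    } else if (nrow(within) == 0 || within$state[nrow(within)] != 3) {
      excl <- c(excl, id); reasons <- c(reasons, "persistent hypothermia")
    }
  }
  keep <- d[!(d$subject_id %in% excl), , drop = FALSE]
  report <- data.frame(subject_id = excl, reason = reasons,
                       stringsAsFactors = FALSE)
  out <- if (nrow(keep) > 0) {
    panel_dataset(keep, provenance = ds$provenance)
  } else {
    warning("all subjects excluded by study filters")
    structure(list(data = keep, provenance = ds$provenance),
              class = "panel_dataset")
  }
  list(dataset = out, exclusions = report)
}

#' State occupancy counts on an observation grid
#'
#' Entry (t, s) is the number of subjects whose observation at exact grid
#' time t is in state s. Subjects with no observation at t (already exited
#' under the first-hitting design) contribute nothing; off-grid observation
#' times are skipped.
#'
#' @param ds a `panel_dataset`.
#' @param grid numeric vector of observation times (minutes).
#' @return integer matrix, rows = grid times, columns = states
#'   severe/mild/normal.
#' @export
state_occupancy_table <- function(ds, grid = seq(0, 180, by = 30)) {
  stopifnot(length(grid) > 0)
  d <- ds$data
  out <- matrix(0L, nrow = length(grid), ncol = 3,
                dimnames = list(time = as.character(grid),
                                state = .state_labels))
  for (i in seq_along(grid)) {
    at <- d[d$time_min == grid[i], , drop = FALSE]
    if (nrow(at) > 0) out[i, ] <- tabulate(at$state, nbins = 3)
  }
  out
}

#' Transition count table between consecutive panel observations
#'
#' Counts consecutive observation pairs (r to s) over all subjects, plus one
#' terminal (3, 3) self-count per subject whose final observation is the
#' normal state, so that the normal row shows the absorbed cohort (the
#' display convention of the source study: the table total equals the number
#' of observation pairs plus the number of absorbed subjects).
#'
#' @param ds a `panel_dataset`.
#' @return 3x3 integer matrix of class `transition_count_table`.
#' @export
transition_count_table <- function(ds) {
  d <- ds$data
  counts <- matrix(0L, 3, 3,
                   dimnames = list(from = .state_labels, to = .state_labels))
  for (id in unique(d$subject_id)) {
    s <- d$state[d$subject_id == id]
    if (length(s) >= 2) {
      for (j in 2:length(s)) counts[s[j - 1], s[j]] <- counts[s[j - 1], s[j]] + 1L
    }
    if (s[length(s)] == 3) counts[3, 3] <- counts[3, 3] + 1L
  }
  structure(counts, class = c("transition_count_table", class(counts)))
}

#' Row-normalize a transition count table
#'
#' Each row with a positive total is divided by its total; all-zero rows are
#' returned as zero.
#'
#' @param counts 3x3 non-negative count matrix (e.g. from
#'   [transition_count_table()]).
#' @return 3x3 matrix of row proportions.
#' @export
row_normalize <- function(counts) {
  m <- unclass(as.matrix(counts))
  storage.mode(m) <- "double"
  tot <- rowSums(m)
  for (i in seq_len(nrow(m))) if (tot[i] > 0) m[i, ] <- m[i, ] / tot[i]
  m
}

#' Whole-percent rendering of a transition count table
#'
#' Row percentages rounded half away from zero to whole percent — the display
#' convention under which counts 376/137/85 render as 63/23/14.
#'
#' @param counts 3x3 non-negative count matrix.
#' @return 3x3 integer matrix of whole percentages.
#' @export
percent_matrix <- function(counts) {
  p <- round_half_up(100 * row_normalize(counts))
  storage.mode(p) <- "integer"
  p
}

#' @export
print.transition_count_table <- function(x, ...) {
  pct <- percent_matrix(x)
  disp <- matrix(sprintf("%d (%d%%)", unclass(x), pct), 3, 3,
                 dimnames = dimnames(unclass(x)))
  cat("Transition counts (row %):\n")
  print(disp, quote = FALSE)
  invisible(x)
}
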