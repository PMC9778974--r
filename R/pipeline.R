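#' Configuration of the end-to-end analysis pipeline
#'
#' Describes one full run: input (a simulated cohort or a CSV file), the
#' transition structure, the covariate model, which models to fit, the
#' goodness-of-fit binning, and output handling. Can also be read from a YAML
#' file with [read_pipeline_config()].
#'
#' @param input either `list(simulate = <simulation_config>)` or
#'   `list(csv = <path>)`.
#' @param structure a [transition_structure()].
#' @param model a [covariate_model()] for the covariate fit.
#' @param models character subset of `c("null", "covariate", "restricted",
#'   "epoch")` (at least one).
#' @param changepoints epoch changepoints (minutes) for the "epoch" model.
#' @param gof a [gof_binning()], or NULL to skip the GOF stage.
#' @param out_dir output directory (created if needed), or NULL to skip
#'   writing artifacts.
#' @param seed integer seed for the whole run.
#' @param grid observation grid for descriptive tables and curves.
#' @param verbose print one structured line per stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input,
                            structure = transition_structure(),
                            model = covariate_model(),
                            models = c("null", "covariate"),
                            changepoints = c(90),
                            gof = gof_binning(),
                            out_dir = NULL,
                            seed = 1L,
                            grid = seq(0, 180, by = 30),
                            verbose = FALSE) {
  models <- match.arg(models, c("null", "covariate", "restricted", "epoch"),
                      several.ok = TRUE)
  if (length(models) == 0) stop("at least one model must be requested")
  if (!is.list(input) || !any(c("simulate", "csv") %in% names(input)))
    stop("input must be list(simulate = <simulation_config>) or list(csv = <path>)")
  structure(list(input = input, structure = structure, model = model,
                 models = models, changepoints = changepoints, gof = gof,
                 out_dir = out_dir, seed = seed, grid = grid,
                 verbose = verbose),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `input` (`simulate:` with fixture name or
#' simulation-config fields, or `csv:` path), `structure` (list of "r->s"
#' strings), `covariates`, `coding`, `mode`, `models`, `changepoints`,
#' `out_dir`, `seed`.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  structure_ <- if (!is.null(y$structure)) {
    transition_structure(unlist(y$structure))
  } else {
    transition_structure()
  }
  model <- covariate_model(
    covariates = if (!is.null(y$covariates)) unlist(y$covariates)
                 else c("birth_weight", "apgar5", "pulse"),
    coding = if (!is.null(y[["coding"]])) y[["coding"]] else "ordinal",
    mode = if (!is.null(y[["mode"]])) y[["mode"]] else "full")
  input <- if (!is.null(y$input$csv)) {
    list(csv = y$input$csv)
  } else if (!is.null(y$input$simulate)) {
    s <- y$input$simulate
    if (is.character(s)) {
      list(simulate = fixture_config(s, seed = y$seed))
    } else {
      cfg <- fixture_config(if (is.null(s$fixture)) "paper-null" else s$fixture,
                            n_subjects = if (is.null(s$n_subjects)) 391
                                         else s$n_subjects,
                            seed = y$seed)
      list(simulate = cfg)
    }
  } else {
    stop("config must declare input: simulate or input: csv")
  }
  pipeline_config(input = input, structure = structure_, model = model,
                  models = if (!is.null(y$models)) unlist(y$models)
                           else c("null", "covariate"),
                  changepoints = if (!is.null(y$changepoints))
                    unlist(y$changepoints) else c(90),
                  out_dir = y$out_dir,
                  seed = if (!is.null(y$seed)) y$seed else 1L)
}

stage_log <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Executes the study's analysis sequence: load or simulate the cohort,
#' apply the study filters, compute descriptive tables (occupancy and
#' transition counts), fit the requested models (null first), rank by AIC,
#' run likelihood-ratio tests against the null, tabulate hazard ratios and
#' sojourn times, run the goodness-of-fit test and compute stay-probability
#' curves. If `config$out_dir` is set, all artifacts are written there
#' (report.md, report.json, fit.json, tables/*.csv, curves.csv,
#' exclusions.csv).
#'
#' @param config a [pipeline_config()].
#' @return object of class `analysis_report`.
#' @export
run_pipeline <- function(config) {
  v <- config$verbose
  set.seed(config$seed)
  # --- load / simulate -------------------------------------------------------
  if (!is.null(config$input$csv)) {
    ds0 <- read_panel_csv(config$input$csv)
    filt <- apply_study_filters(ds0)
    stage_log(v, "load", "csv %s: %d subjects in, %d retained",
              config$input$csv, n_subjects(ds0), n_subjects(filt$dataset))
  } else {
    sim <- generate_cohort(config$input$simulate)
    filt <- list(dataset = sim$dataset, exclusions = sim$exclusions)
    stage_log(v, "simulate", "%d subjects generated, %d retained",
              config$input$simulate$n_subjects, n_subjects(sim$dataset))
  }
  ds <- filt$dataset
  if (n_subjects(ds) == 0) stop("stage filter: no subjects retained")

  # --- descriptives ----------------------------------------------------------
  occupancy <- state_occupancy_table(ds, config$grid)
  counts <- transition_count_table(ds)
  stage_log(v, "descriptives", "%d observation pairs",
            sum(unclass(counts)) - unclass(counts)[3, 3])

  # --- model fits (null first) -----------------------------------------------
  fits <- list()
  order_models <- intersect(c("null", "covariate", "restricted", "epoch"),
                            config$models)
  for (m in order_models) {
    fits[[m]] <- switch(m,
      null = fit_msm(ds, config$structure, NULL),
      covariate = fit_msm(ds, config$structure, config$model),
      restricted = {
        rm_ <- config$model; rm_$mode <- "restricted"
        fit_msm(ds, config$structure, rm_)
      },
      epoch = fit_time_epoch_model(ds, config$structure, config$changepoints))
    stage_log(v, "fit", "%s: loglik %.2f AIC %.2f", m, fits[[m]]$loglik,
              fits[[m]]$aic)
  }
  aic_table <- data.frame(model = names(fits),
                          loglik = vapply(fits, function(f) f$loglik, 1),
                          n_params = vapply(fits, function(f) f$n_params, 1L),
                          aic = vapply(fits, function(f) f$aic, 1),
                          row.names = NULL)
  aic_table <- aic_table[order(aic_table$aic), ]

  # --- LR tests against the null --------------------------------------------
  lr_tests <- list()
  if ("null" %in% names(fits)) {
    for (m in setdiff(names(fits), "null")) {
      lr_tests[[m]] <- tryCatch(likelihood_ratio_test(fits$null, fits[[m]]),
                                error = function(e) NULL)
    }
  }

  # --- hazard ratios & sojourn table -----------------------------------------
  hr <- NULL; sojourns <- NULL
  if ("covariate" %in% names(fits) && !is.null(fits$covariate$vcov)) {
    hr <- hazard_ratios(fits$covariate)
    sojourns <- sojourn_profiles_table(fits$covariate)
  }

  # --- goodness of fit (on the preferred available fit) ----------------------
  gof <- NULL
  if (!is.null(config$gof)) {
    gfit <- if ("covariate" %in% names(fits)) fits$covariate else fits[[1]]
    gof <- tryCatch(pearson_gof(gfit, ds, config$gof), error = function(e) NULL)
    if (!is.null(gof))
      stage_log(v, "gof", "statistic %.2f p %.3f", gof$statistic, gof$p_value)
  }

  # --- curves ----------------------------------------------------------------
  cfit <- if ("covariate" %in% names(fits)) fits$covariate else fits[[1]]
  curves <- rbind(
    stay_probability_curve(cfit, 1, config$grid, "no_exit"),
    stay_probability_curve(cfit, 1, config$grid, "occupancy"),
    stay_probability_curve(cfit, 2, config$grid, "no_exit"),
    stay_probability_curve(cfit, 2, config$grid, "occupancy"))
  curves$state <- rep(c(1L, 1L, 2L, 2L), each = length(config$grid))

  report <- structure(list(
    occupancy = occupancy, transition_counts = counts,
    transition_percents = percent_matrix(counts),
    fits = fits, aic_table = aic_table, lr_tests = lr_tests,
    hazard_ratios = hr, sojourns = sojourns, gof = gof, curves = curves,
    exclusions = filt$exclusions,
    n_subjects = n_subjects(ds),
    seed = config$seed,
    config_echo = list(models = config$models,
                       structure = transition_names(config$structure),
                       covariates = config$model$covariates,
                       coding = config$model$coding,
                       changepoints = config$changepoints),
    version = as.character(utils::packageVersion("neotherm"))
  ), class = "analysis_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Table-3-style sojourn table: vary one covariate at a time over its levels,
# holding the others at their middle (reference) level
sojourn_profiles_table <- function(fit) {
  covs <- fit$model$covariates
  mid_profile <- lapply(covs, function(v) {
    levs <- .cov_levels[[v]]
    levs[ceiling(length(levs) / 2)]
  })
  names(mid_profile) <- covs
  rows <- list()
  for (v in covs) {
    for (lev in .cov_levels[[v]]) {
      pr <- mid_profile; pr[[v]] <- lev
      sj <- sojourn_table(fit, list(pr))
      rows[[paste(v, lev)]] <- data.frame(covariate = v, level = lev,
                                          severe_minutes = sj$severe_minutes,
                                          mild_minutes = sj$mild_minutes,
                                          stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report:", x$n_subjects, "subjects (seed", x$seed, ")\n\n")
  cat("Model ranking by AIC:\n")
  print(x$aic_table, row.names = FALSE)
  if (!is.null(x$hazard_ratios)) {
    cat("\nHazard ratios (95% CI):\n")
    print(x$hazard_ratios, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$gof)) { cat("\n"); print(x$gof) }
  invisible(x)
}

# serializable view of the report (drops fitted-model closures/echoes)
report_as_list <- function(report) {
  list(
    n_subjects = report$n_subjects,
    seed = report$seed,
    version = report$version,
    config = report$config_echo,
    occupancy = as.data.frame.table(report$occupancy,
                                    responseName = "count"),
    transition_counts = unclass(report$transition_counts),
    transition_percents = unclass(report$transition_percents),
    aic = report$aic_table,
    lr_tests = lapply(report$lr_tests, function(t) if (is.null(t)) NULL else
      list(statistic = unname(t$statistic), df = unname(t$parameter),
           p_value = t$p.value)),
    fits = lapply(report$fits, function(f) list(
      par = as.list(f$par), loglik = f$loglik, n_params = f$n_params,
      aic = f$aic, converged = f$converged,
      vcov = if (is.null(f$vcov)) NULL else unclass(f$vcov))),
    hazard_ratios = report$hazard_ratios,
    sojourns = report$sojourns,
    gof = if (is.null(report$gof)) NULL else
      list(statistic = report$gof$statistic, df = report$gof$df,
           p_value = report$gof$p_value),
    curves = report$curves,
    exclusions = report$exclusions
  )
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
  jsonlite::write_json(report_as_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE)
  jsonlite::write_json(report_as_list(report)$fits,
                       file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  render_tables(report, fmt = "csv", dir = file.path(out_dir, "tables"))
  utils::write.csv(report$curves, file.path(out_dir, "curves.csv"),
                   row.names = FALSE)
  utils::write.csv(report$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  writeLines(render_report_md(report), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' Render the report's tables to files
#'
#' Occupancy table (rows = grid times), transition table in the
#' "count (percent)" display convention, AIC ranking, hazard-ratio and
#' sojourn tables (covariate x level x state-minutes layout).
#'
#' @param report an `analysis_report`.
#' @param fmt "csv", "markdown" or "json".
#' @param dir output directory.
#' @return character vector of written file paths, invisibly.
#' @export
render_tables <- function(report, fmt = c("csv", "markdown", "json"),
                          dir = ".") {
  fmt <- match.arg(fmt)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- c(csv = "csv", markdown = "md", json = "json")[[fmt]]
  counts <- unclass(report$transition_counts)
  pct <- unclass(report$transition_percents)
  disp <- matrix(sprintf("%d (%d%%)", counts, pct), 3, 3,
                 dimnames = dimnames(counts))
  occ <- data.frame(time = rownames(report$occupancy),
                    unclass(report$occupancy), row.names = NULL)
  tabs <- list(
    occupancy = occ,
    transitions = data.frame(from = rownames(disp), disp, row.names = NULL),
    aic = report$aic_table,
    hazard_ratios = report$hazard_ratios,
    sojourns = report$sojourns)
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  paths <- character(0)
  for (nm in names(tabs)) {
    path <- file.path(dir, paste0(nm, ".", ext))
    if (fmt == "csv") {
      utils::write.csv(tabs[[nm]], path, row.names = FALSE)
    } else if (fmt == "json") {
      jsonlite::write_json(tabs[[nm]], path, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE)
    } else {
      writeLines(md_table(tabs[[nm]]), path)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}

md_table <- function(df) {
  hdr <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  body <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(hdr, sep, body)
}

render_report_md <- function(report) {
  lines <- c("# Neonatal hypothermia recovery: multi-state Markov analysis",
             "",
             sprintf("Subjects analysed: %d (seed %s, neotherm %s)",
                     report$n_subjects, report$seed, report$version),
             "", "## State occupancy by observation time", "",
             md_table(data.frame(time = rownames(report$occupancy),
                                 unclass(report$occupancy))),
             "", "## Transition counts (row %)", "")
  counts <- unclass(report$transition_counts)
  pct <- unclass(report$transition_percents)
  disp <- matrix(sprintf("%d (%d%%)", counts, pct), 3, 3,
                 dimnames = dimnames(counts))
  lines <- c(lines, md_table(data.frame(from = rownames(disp), disp)),
             "", "## Model comparison (AIC)", "",
             md_table(report$aic_table))
  for (nm in names(report$lr_tests)) {
    t <- report$lr_tests[[nm]]
    if (!is.null(t))
      lines <- c(lines, "",
                 sprintf("LR test null vs %s: statistic %.3f, df %d, p = %.4g",
                         nm, unname(t$statistic), unname(t$parameter),
                         t$p.value))
  }
  if (!is.null(report$hazard_ratios))
    lines <- c(lines, "", "## Hazard ratios (95% CI)", "",
               md_table(within(report$hazard_ratios, {
                 hr <- sprintf("%.3f", hr); lower <- sprintf("%.3f", lower)
                 upper <- sprintf("%.3f", upper)
                 se_log <- sprintf("%.3f", se_log)
               })))
  if (!is.null(report$sojourns))
    lines <- c(lines, "", "## Mean sojourn times (minutes)", "",
               md_table(within(report$sojourns, {
                 severe_minutes <- sprintf("%.1f", severe_minutes)
                 mild_minutes <- sprintf("%.1f", mild_minutes)
               })))
  if (!is.null(report$gof))
    lines <- c(lines, "", sprintf(
      "Goodness of fit: %s — statistic %.3f, df %d, p = %.4g",
      report$gof$method, report$gof$statistic, report$gof$df,
      report$gof$p_value))
  else
    lines <- c(lines, "", "Goodness of fit: not run")
  lines
}
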