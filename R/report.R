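#' Descriptive summary of a trial dataset
#'
#' Per-parameter n, mean and SD by arm and visit, for baseline values
#' (visit `"baseline"`) and changes from baseline (post-baseline visits),
#' in the overall and monotherapy populations. Missing cells are excluded
#' from `n`.
#'
#' @param dataset a `trial_dataset`.
#' @param populations character subset of `c("overall", "monotherapy")`.
#' @return Data frame: `population`, `parameter`, `visit`, `arm`, `n`,
#'   `mean`, `sd`.
#' @export
descriptive_table <- function(dataset,
                              populations = c("overall", "monotherapy")) {
  one_pop <- function(popname) {
    d <- if (popname == "monotherapy") {
      dataset[!dataset$baseline_tafamidis, , drop = FALSE]
    } else dataset
    val <- ifelse(d$visit == "baseline", d$baseline_value,
                  d$change_from_baseline)
    keep <- !is.na(val)
    df <- data.frame(parameter = d$parameter[keep], visit = d$visit[keep],
                     arm = d$arm[keep], value = val[keep],
                     stringsAsFactors = FALSE)
    agg_n <- aggregate(value ~ parameter + visit + arm, df, length)
    agg_m <- aggregate(value ~ parameter + visit + arm, df, mean)
    agg_s <- aggregate(value ~ parameter + visit + arm, df,
                       function(x) if (length(x) > 1) sd(x) else 0)
    out <- agg_n
    names(out)[4] <- "n"
    out$mean <- agg_m$value
    out$sd <- agg_s$value
    out$population <- popname
    out[, c("population", "parameter", "visit", "arm", "n", "mean", "sd")]
  }
  out <- do.call(rbind, lapply(populations, one_pop))
  out[order(out$population, out$parameter,
            match(out$visit, VISITS), out$arm), , drop = FALSE]
}

#' Primary repeated-measures analysis of a trial dataset
#'
#' End-to-end primary analysis: builds the design for the requested
#' population, fits the REML repeated-measures model and reports the
#' per-visit LS means by arm and placebo-corrected differences with CI
#' and p-value (the shape of the published per-visit trajectory and
#' month-30 difference tables).
#'
#' @param dataset a `trial_dataset`.
#' @param spec an [mmrm_spec()].
#' @param visits visits to report (default all modelled visits).
#' @return Data frame with one row per visit (columns as
#'   [treatment_contrast()]), plus `parameter` and `population`; the
#'   `mmrm_fit` in `attr(, "fit")`.
#' @export
run_primary <- function(dataset, spec = mmrm_spec(), visits = NULL) {
  design <- build_design(dataset, spec)
  fit <- fit_mmrm(design)
  if (!fit$converged) stop("repeated-measures model did not converge",
                           call. = FALSE)
  visits <- visits %||% design$visits
  rows <- do.call(rbind, lapply(visits, function(v)
    treatment_contrast(fit, v)))
  out <- cbind(data.frame(
    parameter = spec$parameter %||% unique(dataset$parameter)[1],
    population = spec$population, stringsAsFactors = FALSE), rows)
  attr(out, "fit") <- fit
  out
}

#' Sensitivity analysis of a trial dataset
#'
#' Runs the pattern-mixture multiple imputation and pools the month-30
#' ANCOVA treatment differences by Rubin's rules.
#'
#' @param dataset a `trial_dataset`.
#' @param spec an [mmrm_spec()].
#' @param m number of imputations (default 100).
#' @param seed integer seed.
#' @param ... forwarded to [run_pattern_mixture()].
#' @return The pooled one-row data frame from [sensitivity_report()];
#'   the `imputation_run` in `attr(, "run")`.
#' @export
run_sensitivity <- function(dataset, spec = mmrm_spec(), m = 100L,
                            seed = 1L, ...) {
  run <- run_pattern_mixture(dataset, m = m, seed = seed, ...)
  out <- sensitivity_report(run, spec)
  attr(out, "run") <- run
  out
}

#' Write a trial dataset to long-format CSV
#'
#' One row per patient-visit; empty field = missing change. RFC-4180
#' quoting, UTF-8, one header line.
#'
#' @param dataset a `trial_dataset`.
#' @param path output file.
#' @export
write_trial_csv <- function(dataset, path) {
  cols <- c("patient_id", "arm", "baseline_tafamidis", "attr_type",
            "age_group", "nyha", "ntprobnp_high", "death_day",
            "last_dose_day", "discontinued", "visit", "nominal_day",
            "parameter", "baseline_value", "change_from_baseline")
  write.csv(as.data.frame(dataset)[, cols], path, row.names = FALSE,
            na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a long-format trial CSV
#'
#' @param path file written by [write_trial_csv()] (or schema-compatible).
#' @return A `trial_dataset`; `observed` is reconstructed from the
#'   presence of `change_from_baseline`. Schema violations report the
#'   missing columns.
#' @export
read_trial_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("patient_id", "arm", "baseline_tafamidis", "attr_type",
            "age_group", "nyha", "ntprobnp_high", "death_day",
            "last_dose_day", "discontinued", "visit", "nominal_day",
            "parameter", "baseline_value", "change_from_baseline")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop("trial CSV is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d$baseline_tafamidis <- as.logical(d$baseline_tafamidis)
  d$ntprobnp_high <- as.logical(d$ntprobnp_high)
  d$discontinued <- as.logical(d$discontinued)
  d$death_day <- as.integer(d$death_day)
  d$last_dose_day <- as.integer(d$last_dose_day)
  d$change_from_baseline <- as.numeric(d$change_from_baseline)
  d$observed <- !is.na(d$change_from_baseline)
  bad_visit <- which(!d$visit %in% VISITS)
  if (length(bad_visit)) {
    stop("unknown visit at data line(s): ",
         paste(utils::head(bad_visit + 1L, 5), collapse = ", "),
         call. = FALSE)
  }
  structure(d, class = c("trial_dataset", "data.frame"))
}

# small stable content hash (FNV-1a over the serialized object); avoids a
# digest dependency for manifest bookkeeping
content_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes[seq(1, length(bytes),
                                 by = max(1L, length(bytes) %/% 4096L))])) {
    h <- ((h + b + 1) * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run manifest for reproducibility
#'
#' Records the configuration hash, seed, package version, timestamp and
#' per-stage row counts so that an emitted table can be traced back to
#' the exact run that produced it.
#'
#' @param config the `trial_config` (or any configuration list).
#' @param seed analysis seed.
#' @param counts named list of per-stage row counts / exclusions.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(config, seed, counts = list()) {
  structure(list(
    config_hash = content_hash(unclass(config)),
    seed = seed,
    package_version = as.character(utils::packageVersion("echosens")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    counts = counts
  ), class = "run_manifest")
}

#' Write a fitted-model report as JSON
#'
#' Serializes the fixed effects, unstructured covariance, per-visit
#' treatment contrasts and convergence diagnostics of a fitted
#' repeated-measures model.
#'
#' @param fit an `mmrm_fit`.
#' @param path output file (JSON).
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "mmrm_fit"))
  contrasts <- if (fit$design$two_arm && fit$converged) {
    do.call(rbind, lapply(fit$design$visits,
                          function(v) treatment_contrast(fit, v)))
  }
  report <- list(
    beta = as.list(fit$beta),
    sigma = apply(fit$sigma, 1, as.numeric, simplify = FALSE),
    visits = fit$design$visits,
    contrasts = contrasts,
    reml_loglik = fit$reml_loglik,
    converged = fit$converged,
    grad_norm = fit$grad_norm,
    n_subjects = fit$n_subjects,
    n_observations = fit$n_observations,
    population = fit$design$spec$population
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Save / load a trial configuration as JSON
#'
#' @param config a `trial_config`.
#' @param path file path (JSON).
#' @return `read_trial_config` returns a `trial_config`.
#' @export
write_trial_config <- function(config, path) {
  x <- unclass(config)
  x$within_subject_covariance <-
    apply(x$within_subject_covariance, 1, as.numeric, simplify = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trial_config
#' @export
read_trial_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$within_subject_covariance <-
    matrix(unlist(x$within_subject_covariance), 4, 4, byrow = TRUE)
  x$mean_profile_by_arm <- lapply(x$mean_profile_by_arm, as.numeric)
  do.call(trial_config, x[setdiff(names(x), character(0))])
}
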