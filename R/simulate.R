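VISITS <- c("baseline", "m12", "m18", "m24", "m30")
POST_VISITS <- VISITS[-1]
NOMINAL_DAYS <- c(baseline = 0, m12 = 365, m18 = 548, m24 = 730, m30 = 913)
DOSING_INTERVAL_DAYS <- 84L
STUDY_END_DAY <- 913L

#' Parameter presets for the synthetic trial
#'
#' Baseline distributions, arm-specific mean change profiles and
#' within-subject covariance scales calibrated to the published overall
#' population of a 655-patient ATTR-CM trial: baseline means/SDs from the
#' descriptive table, month-30 LS-mean changes per arm from the primary
#' repeated-measures analysis (with earlier visits interpolated along the
#' roughly linear published trajectories), and change-score SDs back-solved
#' from the reported standard errors and per-visit sample sizes.
#'
#' @keywords internal
trial_presets <- function() {
  corr <- matrix(c(
    1.00, 0.65, 0.60, 0.55,
    0.65, 1.00, 0.65, 0.60,
    0.60, 0.65, 1.00, 0.65,
    0.55, 0.60, 0.65, 1.00
  ), 4, 4)
  mk <- function(baseline_mean, baseline_sd, placebo, vutrisiran, sds) {
    list(
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      mean_profile_by_arm = list(placebo = placebo, vutrisiran = vutrisiran),
      within_subject_covariance = diag(sds) %*% corr %*% diag(sds)
    )
  }
  list(
    lvef = mk(55.8, 12.5,
              c(-2.5, -3.7, -5.0, -6.2), c(-1.6, -2.5, -3.3, -4.1),
              c(8, 9, 9.5, 10)),
    stroke_volume = mk(52.2, 17.7,
                       c(-2.6, -3.9, -5.2, -6.5), c(-1.0, -1.4, -1.9, -2.4),
                       c(10, 11, 11.5, 12.4)),
    mean_lv_wall_thickness = mk(18.2, 2.65,
                                c(0.35, 0.55, 0.70, 0.90),
                                c(0.20, 0.30, 0.40, 0.50),
                                c(1.2, 1.3, 1.4, 1.5)),
    lv_mass_index = mk(181.5, 45.2,
                       c(10, 15, 20, 25.4), c(6, 9, 12, 14.8),
                       c(30, 34, 37, 41))
  )
}

#' Configuration for a synthetic ATTR-CM trial
#'
#' Defines the study conditions for [simulate_trial()]: a two-arm trial
#' (placebo / vutrisiran) with echo assessments at baseline and months 12,
#' 18, 24 and 30 (nominal days 0/365/548/730/913), q84-day dosing,
#' stratification factors, exponential death and treatment-discontinuation
#' processes and a configurable missingness mechanism. Defaults emulate the
#' published overall population: 326 patients per arm, 40% baseline
#' tafamidis use, 88% wild-type ATTR, 9% NYHA III, 27% NT-proBNP above
#' 3,000 ng/l, 55% aged >= 75.
#'
#' @param parameter registry key of the simulated parameter; presets exist
#'   for `"lvef"`, `"stroke_volume"`, `"mean_lv_wall_thickness"` and
#'   `"lv_mass_index"`. Other keys require explicit profiles.
#' @param n_per_arm patients per arm.
#' @param tafamidis_fraction probability of baseline tafamidis use.
#' @param attr_wild_type_fraction,age_ge75_fraction,nyha_iii_fraction,ntprobnp_high_fraction
#'   stratification fractions.
#' @param mean_profile_by_arm list with `placebo` and `vutrisiran` numeric
#'   vectors of length 4: mean change from baseline at m12/m18/m24/m30 in
#'   parameter units. Defaults from the preset.
#' @param within_subject_covariance 4x4 symmetric positive-definite
#'   covariance of the change vector. Defaults from the preset.
#' @param baseline_mean,baseline_sd baseline distribution of the parameter.
#' @param baseline_effect slope of change on the centred baseline value
#'   (regression to the mean; default -0.2).
#' @param death_hazard per-day exponential hazard of death (includes
#'   transplant / LV assist device, which the analysis treats identically);
#'   default 9e-5 (about 8% by month 30).
#' @param discontinuation_hazard per-day hazard of stopping study drug;
#'   default 1.4e-4 (about 12% by month 30).
#' @param off_treatment_retention probability that a scheduled visit more
#'   than `window_days` after the last dose is still assessed (retrieved
#'   dropouts); default 0.5.
#' @param missingness_mode `"none"`, `"mcar"`, `"mar"` (monotone dropout
#'   with hazard depending on the last observed change) or `"mnar"`
#'   (cell-wise missingness depending on the deleted change itself).
#' @param missingness_rate per-visit base missingness/dropout probability.
#' @param mar_slope,mnar_slope logistic slopes per worse-direction SD of
#'   the conditioning change value.
#' @param window_days on-treatment window after the last dose; default 126
#'   (1.5 x the 84-day dosing interval).
#' @param seed integer seed; the dataset is a deterministic function of the
#'   configuration including the seed.
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(parameter = "lvef",
                         n_per_arm = 326L,
                         tafamidis_fraction = 0.40,
                         attr_wild_type_fraction = 0.88,
                         age_ge75_fraction = 0.55,
                         nyha_iii_fraction = 0.09,
                         ntprobnp_high_fraction = 0.27,
                         mean_profile_by_arm = NULL,
                         within_subject_covariance = NULL,
                         baseline_mean = NULL,
                         baseline_sd = NULL,
                         baseline_effect = -0.2,
                         death_hazard = 9e-5,
                         discontinuation_hazard = 1.4e-4,
                         off_treatment_retention = 0.5,
                         missingness_mode = c("none", "mcar", "mar", "mnar"),
                         missingness_rate = 0.05,
                         mar_slope = 0.5,
                         mnar_slope = 1.0,
                         window_days = 126L,
                         seed = 1L) {
  missingness_mode <- match.arg(missingness_mode)
  preset <- trial_presets()[[parameter]]
  if (is.null(mean_profile_by_arm)) {
    if (is.null(preset)) stop("no preset for parameter '", parameter,
                              "': supply mean_profile_by_arm", call. = FALSE)
    mean_profile_by_arm <- preset$mean_profile_by_arm
  }
  if (is.null(within_subject_covariance)) {
    if (is.null(preset)) stop("no preset for parameter '", parameter,
                              "': supply within_subject_covariance", call. = FALSE)
    within_subject_covariance <- preset$within_subject_covariance
  }
  if (is.null(baseline_mean)) baseline_mean <- preset$baseline_mean
  if (is.null(baseline_sd)) baseline_sd <- preset$baseline_sd
  if (is.null(baseline_mean) || is.null(baseline_sd)) {
    stop("no preset for parameter '", parameter,
         "': supply baseline_mean and baseline_sd", call. = FALSE)
  }
  stopifnot(
    n_per_arm >= 1, tafamidis_fraction >= 0, tafamidis_fraction <= 1,
    death_hazard >= 0, discontinuation_hazard >= 0,
    off_treatment_retention >= 0, off_treatment_retention <= 1,
    length(mean_profile_by_arm$placebo) == 4L,
    length(mean_profile_by_arm$vutrisiran) == 4L
  )
  V <- as.matrix(within_subject_covariance)
  if (!isTRUE(all.equal(V, t(V), tolerance = 1e-8)) ||
      min(eigen(V, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("within_subject_covariance is not symmetric positive definite",
         call. = FALSE)
  }
  structure(list(
    parameter = parameter,
    n_per_arm = as.integer(n_per_arm),
    tafamidis_fraction = tafamidis_fraction,
    attr_wild_type_fraction = attr_wild_type_fraction,
    age_ge75_fraction = age_ge75_fraction,
    nyha_iii_fraction = nyha_iii_fraction,
    ntprobnp_high_fraction = ntprobnp_high_fraction,
    mean_profile_by_arm = mean_profile_by_arm,
    within_subject_covariance = V,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    baseline_effect = baseline_effect,
    death_hazard = death_hazard,
    discontinuation_hazard = discontinuation_hazard,
    off_treatment_retention = off_treatment_retention,
    missingness_mode = missingness_mode,
    missingness_rate = missingness_rate,
    mar_slope = mar_slope,
    mnar_slope = mnar_slope,
    window_days = as.integer(window_days),
    seed = as.integer(seed)
  ), class = "trial_config")
}

mvn_draw <- function(n, mu, sigma) {
  R <- chol(sigma)
  Z <- matrix(rnorm(n * ncol(sigma)), n, ncol(sigma))
  sweep(Z %*% R, 2, mu, "+")
}

#' Simulate a complete synthetic trial
#'
#' Draws patients, strata, baseline values and multivariate-normal
#' change-from-baseline trajectories with arm-specific mean profiles, plus
#' death and treatment-discontinuation times from exponential hazards.
#' The returned dataset is complete: no assessment is missing until
#' [apply_missingness()] is applied.
#'
#' Dosing is every 84 days from day 0; `last_dose_day` is the last
#' scheduled dose before death, discontinuation or study end (both arms
#' carry a dosing record, placebo dosing being placebo administration).
#'
#' @param config a [trial_config()].
#' @return Long-format data frame of class `trial_dataset`: one row per
#'   patient x visit with patient descriptors, `baseline_value`,
#'   `change_from_baseline` and `observed`.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed)
  n_arm <- config$n_per_arm
  n <- 2L * n_arm
  arm <- rep(c("placebo", "vutrisiran"), each = n_arm)
  id <- sprintf("pt%04d", seq_len(n))

  taf <- runif(n) < config$tafamidis_fraction
  attr_type <- ifelse(runif(n) < config$attr_wild_type_fraction,
                      "wild_type", "variant")
  age_group <- ifelse(runif(n) < config$age_ge75_fraction, "ge75", "lt75")
  nyha <- ifelse(runif(n) < config$nyha_iii_fraction, "III", "I_II")
  ntp_high <- runif(n) < config$ntprobnp_high_fraction

  baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)

  mu <- rbind(config$mean_profile_by_arm$placebo,
              config$mean_profile_by_arm$vutrisiran)
  changes <- mvn_draw(n, rep(0, 4), config$within_subject_covariance)
  changes <- changes + mu[ifelse(arm == "vutrisiran", 2L, 1L), , drop = FALSE]
  changes <- changes + config$baseline_effect * (baseline - config$baseline_mean)

  death_day <- rep(NA_integer_, n)
  if (config$death_hazard > 0) {
    t_death <- floor(rexp(n, config$death_hazard))
    death_day[t_death < STUDY_END_DAY] <-
      as.integer(t_death[t_death < STUDY_END_DAY])
  }
  disc_day <- rep(NA_integer_, n)
  if (config$discontinuation_hazard > 0) {
    t_disc <- floor(rexp(n, config$discontinuation_hazard))
    disc_day[t_disc < STUDY_END_DAY] <-
      as.integer(t_disc[t_disc < STUDY_END_DAY])
  }
  discontinued <- !is.na(disc_day) & (is.na(death_day) | disc_day < death_day)
  end_of_dosing <- pmin(
    ifelse(discontinued, disc_day, STUDY_END_DAY),
    ifelse(is.na(death_day), STUDY_END_DAY, death_day)
  )
  last_dose_day <- as.integer(DOSING_INTERVAL_DAYS *
                                (end_of_dosing %/% DOSING_INTERVAL_DAYS))

  per_patient <- data.frame(
    patient_id = id, arm = arm, baseline_tafamidis = taf,
    attr_type = attr_type, age_group = age_group, nyha = nyha,
    ntprobnp_high = ntp_high, death_day = death_day,
    last_dose_day = last_dose_day, discontinued = discontinued,
    baseline_value = baseline, stringsAsFactors = FALSE
  )

  k <- length(VISITS)
  long <- per_patient[rep(seq_len(n), each = k), , drop = FALSE]
  long$visit <- rep(VISITS, n)
  long$nominal_day <- rep(unname(NOMINAL_DAYS), n)
  long$parameter <- config$parameter
  cfb <- cbind(0, changes)  # baseline change identically 0
  long$change_from_baseline <- as.numeric(t(cfb))
  long$observed <- TRUE
  rownames(long) <- NULL

  structure(long, class = c("trial_dataset", "data.frame"), config = config)
}

#' Apply the configured missingness mechanism
#'
#' With `missingness_mode = "none"` the dataset is returned untouched.
#' Otherwise deterministic rules apply first: every assessment at or after the patient's
#' death day is missing; assessments more than `window_days` after the last
#' dose are missing with probability `1 - off_treatment_retention` (the
#' retained ones are the retrieved-dropout observations). The configured
#' stochastic mechanism is then layered on top of the on-treatment cells:
#' MCAR deletes cells independently; MAR generates monotone dropout whose
#' per-visit hazard is logistic in the previous observed change (baseline
#' z-score for the first visit), so missingness depends on observed data
#' only; MNAR deletes a cell with probability logistic in the (deleted)
#' change itself, oriented so that clinically worse values are more likely
#' to be missing.
#'
#' @param dataset a complete `trial_dataset`.
#' @param config the [trial_config()] that generated it.
#' @return The dataset with `change_from_baseline` set to `NA` and
#'   `observed` to `FALSE` for missing cells; baseline rows are never
#'   removed.
#' @export
apply_missingness <- function(dataset, config) {
  stopifnot(inherits(config, "trial_config"))
  if (config$missingness_mode == "none") {
    return(dataset)
  }
  set.seed(config$seed + 1L)
  post <- dataset$visit != "baseline"
  d <- dataset

  # rule 1: death (transplant / LVAD collapsed into death_day)
  dead <- post & !is.na(d$death_day) & d$nominal_day >= d$death_day
  miss <- dead

  # rule 2: off-treatment visits missing unless retained
  off <- post & (d$nominal_day - d$last_dose_day) > config$window_days
  drop_off <- off & runif(nrow(d)) > config$off_treatment_retention
  miss <- miss | drop_off

  mode <- config$missingness_mode
  if (mode == "mcar") {
    miss <- miss | (post & runif(nrow(d)) < config$missingness_rate)
  } else if (mode == "mnar") {
    dir_sign <- if (worse_direction(config$parameter) == "decrease_is_worse")
      -1 else 1
    sds <- sqrt(diag(config$within_subject_covariance))
    vi <- match(d$visit, POST_VISITS)
    mu <- rbind(config$mean_profile_by_arm$placebo,
                config$mean_profile_by_arm$vutrisiran)
    armi <- ifelse(d$arm == "vutrisiran", 2L, 1L)
    z <- (d$change_from_baseline - mu[cbind(armi, vi)]) / sds[vi]
    p <- plogis(qlogis(config$missingness_rate) +
                  config$mnar_slope * dir_sign * z)
    miss <- miss | (post & !is.na(z) & runif(nrow(d)) < p)
  } else if (mode == "mar") {
    # monotone dropout: hazard at visit v depends on the change observed at
    # visit v-1 (baseline z-score for v = m12); once out, always out
    wide <- matrix(d$change_from_baseline[post], ncol = 4, byrow = TRUE)
    ids <- unique(d$patient_id)
    base <- d$baseline_value[match(ids, d$patient_id)]
    sds <- sqrt(diag(config$within_subject_covariance))
    zprev <- (base - config$baseline_mean) / config$baseline_sd
    dropped <- rep(FALSE, length(ids))
    miss_wide <- matrix(FALSE, length(ids), 4)
    for (v in 1:4) {
      haz <- plogis(qlogis(config$missingness_rate) +
                      config$mar_slope * zprev)
      dropped <- dropped | (runif(length(ids)) < haz)
      miss_wide[, v] <- dropped
      zprev <- ifelse(dropped, zprev, (wide[, v] -
        mean(c(config$mean_profile_by_arm$placebo[v],
               config$mean_profile_by_arm$vutrisiran[v]))) / sds[v])
    }
    mar_miss <- rep(FALSE, nrow(d))
    mar_miss[post] <- as.vector(t(miss_wide))
    miss <- miss | mar_miss
  }

  d$change_from_baseline[miss] <- NA_real_
  d$observed[miss] <- FALSE
  d
}

#' Convert a long trial dataset to one row per patient
#'
#' @param dataset a `trial_dataset`.
#' @return Data frame with one row per patient: descriptors,
#'   `baseline_value` and change columns `y_m12 ... y_m30` (`NA` =
#'   missing).
#' @export
to_wide <- function(dataset) {
  post <- dataset[dataset$visit != "baseline", , drop = FALSE]
  post <- post[order(match(post$patient_id, unique(post$patient_id)),
                     match(post$visit, POST_VISITS)), , drop = FALSE]
  ids <- unique(post$patient_id)
  first <- post[match(ids, post$patient_id), , drop = FALSE]
  Y <- matrix(post$change_from_baseline, nrow = length(ids), ncol = 4,
              byrow = TRUE)
  colnames(Y) <- paste0("y_", POST_VISITS)
  out <- data.frame(
    patient_id = ids, arm = first$arm,
    baseline_tafamidis = first$baseline_tafamidis,
    attr_type = first$attr_type, age_group = first$age_group,
    nyha = first$nyha, ntprobnp_high = first$ntprobnp_high,
    death_day = first$death_day, last_dose_day = first$last_dose_day,
    discontinued = first$discontinued,
    baseline_value = first$baseline_value,
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(Y))
}

#' Convert a wide patient table back to the long trial format
#'
#' @param wide data frame as returned by [to_wide()].
#' @param parameter registry key recorded in the output.
#' @return A `trial_dataset`.
#' @export
from_wide <- function(wide, parameter) {
  n <- nrow(wide)
  k <- length(VISITS)
  meta_cols <- c("patient_id", "arm", "baseline_tafamidis", "attr_type",
                 "age_group", "nyha", "ntprobnp_high", "death_day",
                 "last_dose_day", "discontinued", "baseline_value")
  long <- wide[rep(seq_len(n), each = k), meta_cols, drop = FALSE]
  long$visit <- rep(VISITS, n)
  long$nominal_day <- rep(unname(NOMINAL_DAYS), n)
  long$parameter <- parameter
  Y <- as.matrix(wide[, paste0("y_", POST_VISITS), drop = FALSE])
  cfb <- cbind(0, Y)
  long$change_from_baseline <- as.numeric(t(cfb))
  long$observed <- !is.na(long$change_from_baseline)
  rownames(long) <- NULL
  structure(long, class = c("trial_dataset", "data.frame"))
}
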