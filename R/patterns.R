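PATTERNS <- c("P1_death", "P2_vutri_on_treatment", "P3i_vutri_retrieved",
              "P3ii_vutri_copy_reference", "P4i_placebo_retrieved",
              "P4ii_placebo_mar")

#' Retrieved dropouts in an arm and baseline-tafamidis group
#'
#' Retrieved dropouts are patients who discontinued study treatment yet
#' still provided a month-30 assessment more than `window_days` after
#' their last dose; their off-treatment data anchor the imputation of
#' off-treatment missingness. The pool is "sufficient" when it contains at
#' least 10 patients.
#'
#' @param dataset a `trial_dataset`.
#' @param arm `"placebo"` or `"vutrisiran"`.
#' @param tafamidis_group logical: baseline tafamidis users (`TRUE`) or
#'   non-users (`FALSE`).
#' @param window_days on-treatment window (default 126 = 1.5 dosing
#'   intervals of 84 days).
#' @return List with `patients` (ids) and `sufficient` (count >= 10).
#' @export
find_retrieved_dropouts <- function(dataset, arm, tafamidis_group,
                                    window_days = 126L) {
  m30 <- dataset[dataset$visit == "m30" & dataset$arm == arm &
                   dataset$baseline_tafamidis == tafamidis_group &
                   dataset$observed & dataset$discontinued &
                   (NOMINAL_DAYS[["m30"]] - dataset$last_dose_day) >
                     window_days, , drop = FALSE]
  list(patients = unique(m30$patient_id),
       sufficient = length(unique(m30$patient_id)) >= 10L)
}

#' Classify missing patient-visits into the four imputation patterns
#'
#' Every missing post-baseline assessment receives exactly one pattern:
#' \describe{
#'   \item{P1_death}{patient died (or underwent transplant/LVAD) before
#'     the month-30 visit and the cell falls at/after the death day;
#'     imputed by worst-decile sampling.}
#'   \item{P2_vutri_on_treatment}{vutrisiran cell within `window_days` of
#'     the last dose; treated as MAR and imputed by MCMC MI estimated from
#'     on-treatment vutrisiran data in the same tafamidis group.}
#'   \item{P3i/P3ii}{vutrisiran cell more than `window_days` after the
#'     last dose; retrieved-dropout imputation when at least 10 retrieved
#'     dropouts exist at month 30 in the same tafamidis group, otherwise
#'     copy reference from placebo.}
#'   \item{P4i/P4ii}{placebo cells: retrieved-dropout imputation for
#'     off-treatment cells with a sufficient placebo retrieved-dropout
#'     pool, otherwise MAR MI estimated from all placebo patients in the
#'     tafamidis group.}
#' }
#'
#' @param dataset a `trial_dataset` with dosing and death fields.
#' @param window_days on-treatment window, default 126.
#' @param pattern1_all_missing if `TRUE`, all missing cells of a decedent
#'   are P1, not only those at/after the death day.
#' @return Data frame with one row per missing cell: `patient_id`,
#'   `visit`, `nominal_day`, `arm`, `baseline_tafamidis`,
#'   `days_since_last_dose`, `pattern`.
#' @export
classify_patterns <- function(dataset, window_days = 126L,
                              pattern1_all_missing = FALSE) {
  cells <- dataset[dataset$visit != "baseline" & !dataset$observed, ,
                   drop = FALSE]
  if (!nrow(cells)) {
    return(data.frame(patient_id = character(), visit = character(),
                      nominal_day = integer(), arm = character(),
                      baseline_tafamidis = logical(),
                      days_since_last_dose = integer(),
                      pattern = character(), stringsAsFactors = FALSE))
  }
  died <- !is.na(cells$death_day) & cells$death_day < NOMINAL_DAYS[["m30"]]
  p1 <- died & (pattern1_all_missing | cells$nominal_day >= cells$death_day)

  no_dose <- !p1 & is.na(cells$last_dose_day)
  if (any(no_dose)) {
    stop("missing last_dose_day for patient(s): ",
         paste(unique(cells$patient_id[no_dose]), collapse = ", "),
         call. = FALSE)
  }
  days_off <- cells$nominal_day - cells$last_dose_day

  suff <- list()
  for (a in c("placebo", "vutrisiran")) for (tf in c(FALSE, TRUE)) {
    suff[[paste(a, tf)]] <-
      find_retrieved_dropouts(dataset, a, tf, window_days)$sufficient
  }
  suff_cell <- unlist(suff[paste(cells$arm, cells$baseline_tafamidis)])

  pattern <- character(nrow(cells))
  pattern[p1] <- "P1_death"
  vu <- !p1 & cells$arm == "vutrisiran"
  pattern[vu & days_off <= window_days] <- "P2_vutri_on_treatment"
  pattern[vu & days_off > window_days & suff_cell] <- "P3i_vutri_retrieved"
  pattern[vu & days_off > window_days & !suff_cell] <-
    "P3ii_vutri_copy_reference"
  pl <- !p1 & cells$arm == "placebo"
  pattern[pl & days_off > window_days & suff_cell] <- "P4i_placebo_retrieved"
  pattern[pl & (days_off <= window_days | !suff_cell)] <- "P4ii_placebo_mar"

  data.frame(
    patient_id = cells$patient_id, visit = cells$visit,
    nominal_day = cells$nominal_day, arm = cells$arm,
    baseline_tafamidis = cells$baseline_tafamidis,
    days_since_last_dose = ifelse(p1, NA_integer_, days_off),
    pattern = pattern, stringsAsFactors = FALSE
  )
}

#' Worst-decile donor pool
#'
#' Sorts observed changes by the parameter's worse direction and returns
#' the worst `ceiling(0.1 * n)` values (always at least one donor).
#'
#' @param values observed change-from-baseline values.
#' @param direction `"decrease_is_worse"` or `"increase_is_worse"`.
#' @return Numeric vector of donor values.
#' @export
worst_decile_pool <- function(values, direction) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty donor pool", call. = FALSE)
  k <- ceiling(0.1 * length(values))
  sorted <- sort(values, decreasing = (direction == "increase_is_worse"))
  sorted[seq_len(k)]
}

#' Worst-decile imputation for patients who died
#'
#' Samples with replacement from the worst 10% of observed changes from
#' all patients at the same visit, treatment arm and baseline tafamidis
#' group, then caps at the worst possible change (0 minus baseline). If
#' the visit/arm/tafamidis pool is empty the arm-level pool at the visit
#' is used instead (flagged in the result).
#'
#' @param cell list with `visit`, `arm`, `baseline_tafamidis`,
#'   `baseline_value`.
#' @param dataset a `trial_dataset` supplying the donor observations.
#' @param registry parameter registry (worse-direction lookup).
#' @param n_draws number of draws (default 1); uses R's global RNG.
#' @return List with `draws` (capped), `donor_pool_size` (decile size) and
#'   `fallback` (arm-level pool used).
#' @export
impute_worst_decile <- function(cell, dataset, registry = echo_registry(),
                                n_draws = 1L) {
  parameter <- unique(dataset$parameter)
  stopifnot(length(parameter) == 1L)
  dir <- worse_direction(parameter, registry)
  at_visit <- dataset[dataset$visit == cell$visit & dataset$observed &
                        dataset$arm == cell$arm, , drop = FALSE]
  pool <- at_visit$change_from_baseline[
    at_visit$baseline_tafamidis == cell$baseline_tafamidis]
  fallback <- FALSE
  if (!length(pool[!is.na(pool)])) {
    pool <- at_visit$change_from_baseline
    fallback <- TRUE
  }
  donors <- worst_decile_pool(pool, dir)
  draws <- donors[sample.int(length(donors), n_draws, replace = TRUE)]
  list(draws = apply_cap(draws, cell$baseline_value),
       donor_pool_size = length(donors), fallback = fallback)
}

#' Cap an imputed change at the worst possible change
#'
#' The worst possible change for a patient is 0 minus the baseline value
#' (the parameter cannot fall below zero); imputed changes are floored
#' there. The cap is a lower bound only: positive changes pass through.
#'
#' @param change imputed change from baseline.
#' @param baseline_value the patient's baseline value.
#' @return `max(change, -baseline_value)`, vectorized.
#' @export
apply_cap <- function(change, baseline_value) {
  pmax(change, -baseline_value)
}
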