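#' Month-30 ANCOVA on a completed dataset
#'
#' Ordinary least squares for the change from baseline at month 30 with
#' the baseline value as covariate and treatment arm, baseline tafamidis
#' use, treatment-by-tafamidis interaction, ATTR type and age group as
#' factors (tafamidis terms dropped outside the overall population). The
#' reported estimate is the LS-mean treatment difference under the same
#' equal-factor-weighting convention as the repeated-measures model: the
#' treatment coefficient plus half the treatment-by-tafamidis coefficient.
#'
#' @param completed a completed `trial_dataset` (no missing month-30
#'   changes in the analysis population).
#' @param spec an [mmrm_spec()]; `population` and `covariates` are
#'   honoured.
#' @return List with `estimate`, `se`, `df` (residual) and the `lm` fit.
#' @export
fit_ancova <- function(completed, spec = mmrm_spec()) {
  d <- filter_population(completed, spec)
  rows <- d[d$visit == "m30" & !is.na(d$baseline_value), , drop = FALSE]
  rows <- rows[!is.na(rows$change_from_baseline), , drop = FALSE]
  if (!nrow(rows)) stop("no month-30 changes to analyse", call. = FALSE)
  overall <- spec$population == "overall"
  with_taf <- overall && length(unique(rows$baseline_tafamidis)) == 2L
  dat <- data.frame(
    y = rows$change_from_baseline,
    trt = as.numeric(rows$arm == "vutrisiran")
  )
  form <- "y ~ trt"
  if ("baseline" %in% spec$covariates) {
    dat$baseline <- rows$baseline_value
    form <- paste(form, "+ baseline")
  }
  if (with_taf) {
    dat$tafamidis <- as.numeric(rows$baseline_tafamidis)
    form <- paste(form, "+ tafamidis + trt:tafamidis")
  }
  if ("attr" %in% spec$covariates) {
    dat$attr_variant <- as.numeric(rows$attr_type == "variant")
    form <- paste(form, "+ attr_variant")
  }
  if ("age" %in% spec$covariates) {
    dat$age_ge75 <- as.numeric(rows$age_group == "ge75")
    form <- paste(form, "+ age_ge75")
  }
  fit <- lm(stats::as.formula(form), data = dat)
  if (any(is.na(coef(fit)))) {
    stop("ANCOVA design is rank deficient; aliased terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  cn <- names(coef(fit))
  cvec <- stats::setNames(numeric(length(cn)), cn)
  cvec["trt"] <- 1
  if ("trt:tafamidis" %in% cn) cvec["trt:tafamidis"] <- 0.5
  est <- sum(cvec * coef(fit))
  se <- sqrt(drop(t(cvec) %*% vcov(fit) %*% cvec))
  list(estimate = est, se = se, df = fit$df.residual, fit = fit)
}

#' Combine multiply-imputed estimates by Rubin's rules
#'
#' Pooled estimate `q_bar = mean(q_i)`, within-imputation variance
#' `u_bar = mean(se_i^2)`, between-imputation variance
#' `b = var(q_i)`, total variance `T = u_bar + (1 + 1/m) b`, degrees of
#' freedom by the Barnard-Rubin small-sample formula (given a finite
#' complete-data df) and t-based interval and p-value.
#'
#' @param estimates per-imputation point estimates (length m >= 2).
#' @param ses per-imputation standard errors.
#' @param alpha two-sided level (default 0.05).
#' @param df_com complete-data degrees of freedom (e.g. the ANCOVA
#'   residual df); `Inf` gives the classic large-sample Rubin df.
#' @return A one-row data frame of class `pooled_estimate` with `q_bar`,
#'   `u_bar`, `b`, `total_variance`, `se`, `df`, `ci_low`, `ci_high`,
#'   `p_value`, `m`.
#' @export
rubin_pool <- function(estimates, ses, alpha = 0.05, df_com = Inf) {
  m <- length(estimates)
  if (m < 2) stop("Rubin's rules need m >= 2 imputations", call. = FALSE)
  bad <- which(!is.finite(estimates) | !is.finite(ses))
  if (length(bad)) {
    stop("nonfinite estimate or SE at imputation index: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  q_bar <- mean(estimates)
  u_bar <- mean(ses^2)
  b <- sum((estimates - q_bar)^2) / (m - 1)
  total <- u_bar + (1 + 1 / m) * b
  lambda <- (1 + 1 / m) * b / total
  if (b > 0 && total > 0) {
    df_old <- (m - 1) / lambda^2
    df <- if (is.finite(df_com)) {
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
      1 / (1 / df_old + 1 / df_obs)
    } else df_old
  } else {
    df <- if (is.finite(df_com)) (df_com + 1) / (df_com + 3) * df_com
      else Inf
  }
  se <- sqrt(total)
  tcrit <- qt(1 - alpha / 2, df)
  p <- if (se > 0) 2 * pt(-abs(q_bar / se), df) else as.numeric(q_bar == 0)
  out <- data.frame(q_bar = q_bar, u_bar = u_bar, b = b,
                    total_variance = total, se = se, df = df,
                    ci_low = q_bar - tcrit * se,
                    ci_high = q_bar + tcrit * se,
                    p_value = p, m = m)
  class(out) <- c("pooled_estimate", "data.frame")
  out
}

#' Pooled sensitivity-analysis treatment difference
#'
#' Fits the month-30 ANCOVA to each completed dataset of a
#' pattern-mixture imputation run and pools the LS-mean treatment
#' differences by Rubin's rules, yielding the sensitivity counterpart of
#' the primary repeated-measures month-30 contrast.
#'
#' @param run an `imputation_run` from [run_pattern_mixture()].
#' @param spec an [mmrm_spec()].
#' @param alpha two-sided level (default 0.05).
#' @return One-row data frame: `parameter`, `population`, pooled columns
#'   from [rubin_pool()]; per-imputation estimates in
#'   `attr(, "imputations")`.
#' @export
sensitivity_report <- function(run, spec = mmrm_spec(), alpha = 0.05) {
  stopifnot(inherits(run, "imputation_run"))
  est <- se <- numeric(run$m)
  df_com <- NA_real_
  for (k in seq_len(run$m)) {
    a <- fit_ancova(completed_dataset(run, k), spec)
    est[k] <- a$estimate
    se[k] <- a$se
    df_com <- a$df
  }
  pooled <- rubin_pool(est, se, alpha = alpha, df_com = df_com)
  out <- cbind(data.frame(parameter = run$parameter,
                          population = spec$population,
                          stringsAsFactors = FALSE), pooled)
  class(out) <- c("pooled_estimate", "data.frame")
  attr(out, "imputations") <- data.frame(index = seq_len(run$m),
                                         estimate = est, se = se)
  out
}
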