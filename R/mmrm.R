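#' Model specification for the repeated-measures analysis
#'
#' Mirrors the primary analysis model: change from baseline at the four
#' post-baseline visits, baseline value as a covariate, and fixed effects
#' for visit, treatment-by-visit, ATTR type and age group. In the overall
#' population baseline tafamidis use and its interaction with treatment are
#' added; the monotherapy population (no baseline tafamidis) and the
#' tafamidis subgroup drop both terms.
#'
#' @param parameter registry key to analyse; `NULL` uses all rows (single
#'   parameter datasets).
#' @param population `"overall"`, `"monotherapy"` (baseline tafamidis
#'   non-users) or `"tafamidis_subgroup"`.
#' @param covariates subset of `c("baseline", "attr", "age")`; empty gives
#'   the saturated arm-by-visit cell-means model used by closed-form
#'   checks.
#' @param cell_means if `TRUE` (default) the treatment effect is coded as
#'   one treatment-by-visit dummy per visit (the month-30 contrast is a
#'   single coefficient); if `FALSE`, a treatment main effect plus
#'   interaction dummies beyond the first visit (same column span).
#' @param alpha two-sided level for confidence intervals (default 0.05).
#' @param df_method `"satterthwaite"` (default) or `"residual"`.
#' @return A list of class `mmrm_spec`.
#' @export
mmrm_spec <- function(parameter = NULL,
                      population = c("overall", "monotherapy",
                                     "tafamidis_subgroup"),
                      covariates = c("baseline", "attr", "age"),
                      cell_means = TRUE,
                      alpha = 0.05,
                      df_method = c("satterthwaite", "residual")) {
  population <- match.arg(population)
  df_method <- match.arg(df_method)
  stopifnot(all(covariates %in% c("baseline", "attr", "age")))
  structure(list(parameter = parameter, population = population,
                 covariates = covariates, cell_means = cell_means,
                 alpha = alpha, df_method = df_method),
            class = "mmrm_spec")
}

filter_population <- function(dataset, spec) {
  d <- dataset
  if (!is.null(spec$parameter)) d <- d[d$parameter == spec$parameter, ,
                                       drop = FALSE]
  if (spec$population == "monotherapy") {
    d <- d[!d$baseline_tafamidis, , drop = FALSE]
  } else if (spec$population == "tafamidis_subgroup") {
    d <- d[d$baseline_tafamidis, , drop = FALSE]
  }
  d
}

#' Build the fixed-effects design for the repeated-measures model
#'
#' Restricts to the requested population, drops patients without a
#' baseline value, takes observed post-baseline changes as the response
#' and assembles the fixed-effect matrix under reference coding (placebo,
#' no tafamidis, wild type, age < 75 as reference levels). The realized
#' design is checked for full column rank; aliased columns abort with
#' their names.
#'
#' @param dataset a `trial_dataset`.
#' @param spec an [mmrm_spec()].
#' @return A list of class `mmrm_design` with the design matrix `X`,
#'   response `y`, subject/visit indices and least-squares-mean metadata.
#' @export
build_design <- function(dataset, spec = mmrm_spec()) {
  d <- filter_population(dataset, spec)
  if (!nrow(d)) stop("no rows left after population filtering", call. = FALSE)
  excluded <- unique(d$patient_id[is.na(d$baseline_value)])
  d <- d[!d$patient_id %in% excluded, , drop = FALSE]
  rows <- d[d$visit != "baseline" & d$observed &
              !is.na(d$change_from_baseline), , drop = FALSE]
  if (!nrow(rows)) stop("no observed post-baseline changes", call. = FALSE)
  visits <- POST_VISITS[POST_VISITS %in% unique(rows$visit)]
  rows <- rows[order(match(rows$patient_id, unique(rows$patient_id)),
                     match(rows$visit, visits)), , drop = FALSE]
  arms <- c("placebo", "vutrisiran")
  arms <- arms[arms %in% unique(rows$arm)]
  two_arm <- length(arms) == 2L
  overall <- spec$population == "overall"
  taf_levels <- unique(rows$baseline_tafamidis)
  with_taf <- overall && length(taf_levels) == 2L

  n_obs <- nrow(rows)
  cols <- list("(Intercept)" = rep(1, n_obs))
  if ("baseline" %in% spec$covariates) cols$baseline <- rows$baseline_value
  if ("attr" %in% spec$covariates) {
    cols$attr_variant <- as.numeric(rows$attr_type == "variant")
  }
  if ("age" %in% spec$covariates) {
    cols$age_ge75 <- as.numeric(rows$age_group == "ge75")
  }
  if (with_taf) cols$tafamidis <- as.numeric(rows$baseline_tafamidis)
  for (v in visits[-1]) {
    cols[[paste0("v_", v)]] <- as.numeric(rows$visit == v)
  }
  if (two_arm) {
    trt <- as.numeric(rows$arm == "vutrisiran")
    if (spec$cell_means) {
      for (v in visits) cols[[paste0("trt_", v)]] <-
          trt * as.numeric(rows$visit == v)
    } else {
      cols$trt <- trt
      for (v in visits[-1]) cols[[paste0("trt_", v)]] <-
          trt * as.numeric(rows$visit == v)
    }
    if (with_taf) cols$trt_tafamidis <- trt * as.numeric(rows$baseline_tafamidis)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  subj <- match(rows$patient_id, unique(rows$patient_id))
  base_by_subject <- rows$baseline_value[!duplicated(rows$patient_id)]
  structure(list(
    X = X, y = rows$change_from_baseline,
    subject = subj, visit = rows$visit,
    visit_idx = match(rows$visit, visits), visits = visits,
    q = ncol(X), n_subjects = length(unique(subj)), n_obs = n_obs,
    mean_baseline = mean(base_by_subject),
    two_arm = two_arm, with_taf = with_taf, spec = spec,
    n_excluded_missing_baseline = length(excluded)
  ), class = "mmrm_design")
}

# per-missingness-pattern sufficient statistics; objective cost becomes
# independent of the number of subjects
make_pattern_stats <- function(design) {
  d <- length(design$visits)
  q <- design$q
  pat_key <- vapply(split(design$visit_idx, design$subject),
                    function(v) paste(sort(v), collapse = ","), character(1))
  subj_pat <- pat_key[match(design$subject, as.integer(names(pat_key)))]
  stats <- list()
  for (p in unique(subj_pat)) {
    J <- as.integer(strsplit(p, ",")[[1]])
    k <- length(J)
    idx <- which(subj_pat == p)
    # rows already sorted subject-major, visit-minor
    Xp <- design$X[idx, , drop = FALSE]
    yp <- design$y[idx]
    n_p <- length(idx) / k
    Sxx <- matrix(0, q * q, k * k)
    Sxy <- matrix(0, q, k * k)
    Syy <- numeric(k * k)
    Xa <- lapply(seq_len(k), function(a)
      Xp[seq(a, length(idx), by = k), , drop = FALSE])
    ya <- lapply(seq_len(k), function(a) yp[seq(a, length(idx), by = k)])
    for (a in seq_len(k)) for (b in seq_len(k)) {
      ab <- a + (b - 1L) * k
      Sxx[, ab] <- as.vector(crossprod(Xa[[a]], Xa[[b]]))
      Sxy[, ab] <- as.vector(crossprod(Xa[[a]], ya[[b]]))
      Syy[ab] <- sum(ya[[a]] * ya[[b]])
    }
    stats[[length(stats) + 1L]] <-
      list(J = J, n = n_p, Sxx = Sxx, Sxy = Sxy, Syy = Syy)
  }
  stats
}

start_theta <- function(design) {
  d <- length(design$visits)
  beta0 <- qr.coef(qr(design$X), design$y)
  resid <- design$y - design$X %*% beta0
  R <- matrix(NA_real_, design$n_subjects, d)
  R[cbind(design$subject, design$visit_idx)] <- resid
  S <- suppressWarnings(stats::cov(R, use = "pairwise.complete.obs"))
  S[!is.finite(S)] <- 0
  diag(S)[diag(S) <= 0] <- stats::var(resid)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  floor_val <- 1e-6 * max(e$values, 1e-8)
  vals <- pmax(e$values, floor_val)
  S <- e$vectors %*% (vals * t(e$vectors))
  L <- t(chol(S))
  c(log(diag(L)), L[lower.tri(L)])
}

#' Fit the repeated-measures model by REML
#'
#' Maximizes the (restricted) Gaussian likelihood over the fixed effects
#' and the free parameters of the unstructured within-subject covariance,
#' parameterized by the log-Cholesky factor. Each subject contributes
#' through the observed-visit submatrix of the covariance; no imputation
#' takes place. Optimization is quasi-Newton (BFGS) with the analytic
#' gradient, started from the pairwise-complete covariance of ordinary
#' least-squares residuals (eigenvalue-floored to positive definiteness).
#'
#' @param design an `mmrm_design` from [build_design()].
#' @param reml restricted (default) or ordinary maximum likelihood.
#' @param control optional list: `maxit` (default 300), `reltol`
#'   (default 1e-14), `restarts` (default 2).
#' @return A list of class `mmrm_fit`: `beta`, `sigma`, `vcov_beta`,
#'   `theta`, `vcov_theta`, `reml_loglik`, `converged`, `grad_norm`,
#'   sample sizes and the design.
#' @export
fit_mmrm <- function(design, reml = TRUE, control = list()) {
  stopifnot(inherits(design, "mmrm_design"))
  maxit <- control$maxit %||% 300L
  reltol <- control$reltol %||% 1e-14
  restarts <- control$restarts %||% 2L
  d <- length(design$visits)
  q <- design$q
  st <- make_pattern_stats(design)
  fn <- function(th) reml_neg2ll(th, st, q, reml, d)
  gr <- function(th) reml_neg2ll_grad(th, st, q, reml, d)
  th <- start_theta(design)
  opt <- stats::optim(th, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  trace <- data.frame(restart = 0L, value = opt$value,
                      convergence = opt$convergence)
  for (r in seq_len(restarts)) {
    opt2 <- stats::optim(opt$par, fn, gr, method = "BFGS",
                         control = list(maxit = maxit, reltol = reltol))
    trace <- rbind(trace, data.frame(restart = r, value = opt2$value,
                                     convergence = opt2$convergence))
    improved <- opt$value - opt2$value
    opt <- opt2
    if (improved < 1e-10) break
  }
  # Newton polish: BFGS localizes the optimum; a few damped Newton steps on
  # the analytic gradient push the gradient to ~1e-10 so closed-form
  # equivalences hold to tight tolerance
  for (nstep in 1:6) {
    g0 <- gr(opt$par)
    if (max(abs(g0)) < 1e-10 * (1 + abs(opt$value))) break
    H <- tryCatch(stats::optimHess(opt$par, fn, gr), error = function(e) NULL)
    if (is.null(H)) break
    step <- tryCatch(solve(H, g0), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cand <- opt$par - step
    fcand <- fn(cand)
    if (is.finite(fcand) && fcand <= opt$value + 1e-8) {
      opt$par <- cand
      opt$value <- fcand
    } else break
  }
  comp <- reml_components(opt$par, st, q, reml, d)
  if (!isTRUE(comp$ok)) stop("covariance collapsed during optimization",
                             call. = FALSE)
  g <- gr(opt$par)
  grad_norm <- max(abs(g))
  H <- tryCatch(stats::optimHess(opt$par, fn, gr), error = function(e) NULL)
  vcov_theta <- if (!is.null(H)) {
    tryCatch(2 * solve(H), error = function(e) NULL)
  }
  beta <- as.numeric(comp$beta)
  names(beta) <- colnames(design$X)
  vb <- comp$vcov_beta
  dimnames(vb) <- list(names(beta), names(beta))
  sigma <- comp$sigma
  dimnames(sigma) <- list(design$visits, design$visits)
  n_const <- design$n_obs - if (reml) q else 0L
  converged <- opt$convergence == 0 && is.finite(comp$neg2ll)
  structure(list(
    beta = beta, sigma = sigma, vcov_beta = vb,
    theta = opt$par, vcov_theta = vcov_theta,
    reml_loglik = -0.5 * (comp$neg2ll + n_const * log(2 * pi)),
    neg2ll = comp$neg2ll,
    converged = converged, grad_norm = grad_norm,
    n_subjects = design$n_subjects, n_observations = design$n_obs,
    reml = reml, design = design, pattern_stats = st,
    optimizer_trace = trace
  ), class = "mmrm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lsmean_vector <- function(design, arm, visit) {
  cn <- colnames(design$X)
  cvec <- stats::setNames(numeric(design$q), cn)
  cvec["(Intercept)"] <- 1
  if ("baseline" %in% cn) cvec["baseline"] <- design$mean_baseline
  if ("attr_variant" %in% cn) cvec["attr_variant"] <- 0.5
  if ("age_ge75" %in% cn) cvec["age_ge75"] <- 0.5
  if ("tafamidis" %in% cn) cvec["tafamidis"] <- 0.5
  if (visit != design$visits[1]) cvec[paste0("v_", visit)] <- 1
  if (arm == "vutrisiran") {
    if (!design$two_arm) stop("dataset has a single arm", call. = FALSE)
    if (design$spec$cell_means) {
      cvec[paste0("trt_", visit)] <- 1
    } else {
      cvec["trt"] <- 1
      if (visit != design$visits[1]) cvec[paste0("trt_", visit)] <- 1
    }
    if ("trt_tafamidis" %in% cn) cvec["trt_tafamidis"] <- 0.5
  }
  cvec
}

#' Least-squares means by arm
#'
#' Model-predicted change at a visit with classification factors weighted
#' equally across their levels and the baseline covariate fixed at its
#' sample mean over the analysis set.
#'
#' @param fit an `mmrm_fit`; must have converged.
#' @param visit one of the modelled visits, or `NULL` for all.
#' @return Data frame with `visit`, `arm`, `estimate`, `se`.
#' @export
ls_means <- function(fit, visit = NULL) {
  stopifnot(inherits(fit, "mmrm_fit"))
  if (!fit$converged) stop("model did not converge; no LS means",
                           call. = FALSE)
  visits <- visit %||% fit$design$visits
  stopifnot(all(visits %in% fit$design$visits))
  arms <- if (fit$design$two_arm) c("placebo", "vutrisiran") else "placebo"
  out <- expand.grid(visit = visits, arm = arms, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  est <- se <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    cv <- lsmean_vector(fit$design, out$arm[i], out$visit[i])
    est[i] <- sum(cv * fit$beta)
    se[i] <- sqrt(drop(t(cv) %*% fit$vcov_beta %*% cv))
  }
  out$estimate <- est
  out$se <- se
  out
}

satterthwaite_df <- function(fit, cvec) {
  if (is.null(fit$vcov_theta)) return(NA_real_)
  st <- fit$pattern_stats
  q <- fit$design$q
  d <- length(fit$design$visits)
  f0 <- reml_cvc(fit$theta, st, q, cvec, d)
  npar <- length(fit$theta)
  g <- numeric(npar)
  for (k in seq_len(npar)) {
    h <- 1e-5 * (1 + abs(fit$theta[k]))
    tp <- tm <- fit$theta
    tp[k] <- tp[k] + h
    tm[k] <- tm[k] - h
    g[k] <- (reml_cvc(tp, st, q, cvec, d) -
               reml_cvc(tm, st, q, cvec, d)) / (2 * h)
  }
  denom <- drop(t(g) %*% fit$vcov_theta %*% g)
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  max(1, 2 * f0^2 / denom)
}

#' Placebo-corrected treatment contrast at a visit
#'
#' LS-mean difference (vutrisiran minus placebo) with its standard error,
#' degrees of freedom (Satterthwaite by default), confidence interval at
#' the spec's alpha and two-sided p-value.
#'
#' @param fit an `mmrm_fit`; must have converged.
#' @param visit one of the modelled visits.
#' @return One-row data frame (class `ls_mean_contrast`) with per-arm LS
#'   means, `difference`, `se`, `df`, `ci_low`, `ci_high`, `p_value`.
#' @export
treatment_contrast <- function(fit, visit = "m30") {
  stopifnot(inherits(fit, "mmrm_fit"))
  if (!fit$converged) stop("model did not converge; no contrasts",
                           call. = FALSE)
  if (!visit %in% fit$design$visits) {
    stop("visit not in model: ", visit, call. = FALSE)
  }
  if (!fit$design$two_arm) stop("treatment contrast needs two arms",
                                call. = FALSE)
  cp <- lsmean_vector(fit$design, "placebo", visit)
  cv <- lsmean_vector(fit$design, "vutrisiran", visit)
  cdiff <- cv - cp
  diff <- sum(cdiff * fit$beta)
  se <- sqrt(drop(t(cdiff) %*% fit$vcov_beta %*% cdiff))
  df <- if (fit$design$spec$df_method == "satterthwaite") {
    satterthwaite_df(fit, cdiff)
  } else {
    fit$n_observations - fit$design$q
  }
  if (!is.finite(df)) df <- fit$n_observations - fit$design$q
  alpha <- fit$design$spec$alpha
  tcrit <- qt(1 - alpha / 2, df)
  tstat <- diff / se
  lm_p <- sum(cp * fit$beta)
  lm_v <- sum(cv * fit$beta)
  out <- data.frame(
    visit = visit,
    ls_mean_placebo = lm_p,
    se_placebo = sqrt(drop(t(cp) %*% fit$vcov_beta %*% cp)),
    ls_mean_vutrisiran = lm_v,
    se_vutrisiran = sqrt(drop(t(cv) %*% fit$vcov_beta %*% cv)),
    difference = diff, se = se, df = df,
    ci_low = diff - tcrit * se, ci_high = diff + tcrit * se,
    p_value = 2 * pt(-abs(tstat), df),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ls_mean_contrast", "data.frame")
  out
}

#' @export
print.mmrm_fit <- function(x, ...) {
  cat("MMRM fit (", if (x$reml) "REML" else "ML", "), ",
      x$n_subjects, " subjects, ", x$n_observations, " observations\n",
      sep = "")
  cat("log-likelihood:", format(x$reml_loglik, digits = 8),
      if (!x$converged) " (NOT converged)", "\n")
  cat("\nFixed effects:\n")
  print(round(x$beta, 4))
  cat("\nUnstructured covariance (visits ",
      paste(colnames(x$sigma), collapse = ", "), "):\n", sep = "")
  print(round(x$sigma, 3))
  invisible(x)
}
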