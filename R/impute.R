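# covariate matrix of the imputation models: ATTR type, NYHA class, age
# group, NT-proBNP stratum and the baseline value
imputation_covariates <- function(wide) {
  cbind(
    `(Intercept)` = 1,
    attr_variant = as.numeric(wide$attr_type == "variant"),
    nyha_iii = as.numeric(wide$nyha == "III"),
    age_ge75 = as.numeric(wide$age_group == "ge75"),
    ntprobnp_high = as.numeric(wide$ntprobnp_high),
    baseline = wide$baseline_value
  )
}

#' MCMC multiple imputation under missing-at-random
#'
#' Data augmentation for a multivariate normal regression of the four
#' post-baseline changes on covariates: the I-step draws each missing cell
#' from its conditional normal given the observed cells of the same
#' patient, the P-step draws the coefficient matrix and covariance from
#' the conjugate normal-inverse-Wishart posterior under the Jeffreys
#' prior. Nonmonotone missingness is handled natively. One draw is
#' retained per imputation index, separated by `thin` iterations after
#' `burnin` burn-in iterations.
#'
#' @param Y numeric matrix (patients x visits) of changes with `NA` for
#'   missing cells.
#' @param X covariate matrix (patients x q), including the intercept.
#' @param m number of imputations.
#' @param burnin,thin chain control; defaults 500 and 100.
#' @return List of `m` completed copies of `Y`. With no missing cells the
#'   input is returned unchanged `m` times.
#' @export
impute_mcmc_mar <- function(Y, X, m = 100L, burnin = 500L, thin = 100L) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  stopifnot(nrow(Y) == nrow(X), m >= 1)
  if (!anyNA(Y)) return(replicate(m, Y, simplify = FALSE))
  cube <- da_chain(Y, X, burnin, thin, m)
  lapply(seq_len(m), function(k) {
    out <- matrix(cube[, , k], nrow = nrow(Y), ncol = ncol(Y))
    dimnames(out) <- dimnames(Y)
    out
  })
}

# one draw of (B, Sigma) from the normal-inverse-Wishart posterior of a
# complete-data multivariate regression Y ~ X under the Jeffreys prior
niw_draw <- function(Y, X) {
  n <- nrow(Y); q <- ncol(X); d <- ncol(Y)
  if (n - q < d) {
    stop("estimation sample too small for a proper posterior: n = ", n,
         ", covariates = ", q, ", visits = ", d, call. = FALSE)
  }
  XtXinv <- solve(crossprod(X))
  Bhat <- XtXinv %*% crossprod(X, Y)
  S <- crossprod(Y - X %*% Bhat)
  S <- (S + t(S)) / 2
  Sinv <- solve(S)
  W <- rWishart(1, n - q, (Sinv + t(Sinv)) / 2)[, , 1]
  Sigma <- solve(W)
  Sigma <- (Sigma + t(Sigma)) / 2
  Z <- matrix(rnorm(q * d), q, d)
  B <- Bhat + t(chol(XtXinv)) %*% Z %*% chol(Sigma)
  list(B = B, Sigma = Sigma)
}

# draw y[target] | y[observed] under N(mu, Sigma); `observed` excludes the
# target cells
conditional_mvn_draw <- function(y, target, mu, Sigma) {
  obs <- setdiff(which(!is.na(y)), target)
  if (!length(obs)) {
    cm <- mu[target]
    cv <- Sigma[target, target, drop = FALSE]
  } else {
    Soo <- Sigma[obs, obs, drop = FALSE]
    F <- solve(Soo, Sigma[obs, target, drop = FALSE])
    cm <- mu[target] + drop(crossprod(F, y[obs] - mu[obs]))
    cv <- Sigma[target, target, drop = FALSE] -
      Sigma[target, obs, drop = FALSE] %*% F
    cv <- (cv + t(cv)) / 2
  }
  e <- eigen(cv, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  drop(cm + e$vectors %*% (sqrt(vals) * rnorm(length(target))))
}

#' Copy-reference imputation of off-treatment missingness
#'
#' A deviating treated patient's outcome distribution is taken entirely
#' from the reference (placebo) arm: given a posterior draw of the
#' reference mean structure and covariance, the missing cells are drawn
#' from the reference conditional normal given the patient's observed
#' post-baseline changes and baseline covariate.
#'
#' @param y length-4 vector of the patient's changes (`NA` = missing).
#' @param target indices (1..4) of the cells to impute.
#' @param x reference-model covariate row (intercept, centred baseline).
#' @param ref_draw list with `B` and `Sigma` from the reference posterior,
#'   e.g. one element of the draws produced inside
#'   [run_pattern_mixture()].
#' @return `y` with the target cells filled (uncapped; the caller applies
#'   the 0-baseline cap).
#' @export
impute_copy_reference <- function(y, target, x, ref_draw) {
  mu <- drop(x %*% ref_draw$B)
  y[target] <- conditional_mvn_draw(y, target, mu, ref_draw$Sigma)
  y
}

#' Retrieved-dropout imputation
#'
#' Bayesian normal-regression imputation of a missing visit's change,
#' estimated solely from retrieved-dropout observations at that visit:
#' draws the residual variance from its scaled inverse chi-squared
#' posterior, the coefficients from their conditional normal, and the
#' imputed value from the posterior predictive. If the covariate design
#' is singular or the sample too small, the model falls back to intercept
#' plus baseline, then to intercept only.
#'
#' @param target_x covariate row of the patient being imputed.
#' @param est_y,est_X outcomes and covariates of the retrieved-dropout
#'   estimation sample (same column layout as `target_x`).
#' @return List with `draw` (uncapped) and `model` (`"full"`,
#'   `"baseline"` or `"intercept"`).
#' @export
impute_retrieved_dropout <- function(target_x, est_y, est_X) {
  est_X <- as.matrix(est_X)
  target_x <- as.numeric(target_x)
  try_model <- function(cols) {
    Xr <- est_X[, cols, drop = FALSE]
    n <- nrow(Xr); p <- ncol(Xr)
    if (n < p + 2) return(NULL)
    qrX <- qr(Xr)
    if (qrX$rank < p) return(NULL)
    bhat <- qr.coef(qrX, est_y)
    rss <- sum((est_y - Xr %*% bhat)^2)
    df <- n - p
    sigma2 <- rss / rchisq(1, df)
    if (!is.finite(sigma2) || sigma2 < 0) sigma2 <- 0
    XtXinv <- chol2inv(qr.R(qrX))
    beta <- bhat + drop(t(chol(sigma2 * XtXinv + diag(1e-12, p))) %*%
                          rnorm(p))
    drop(target_x[cols] %*% beta) + rnorm(1, 0, sqrt(sigma2))
  }
  full <- seq_len(ncol(est_X))
  baseline_cols <- intersect(c(1L, which(colnames(est_X) == "baseline")),
                             full)
  for (cand in list(full, baseline_cols, 1L)) {
    draw <- try_model(cand)
    if (!is.null(draw)) {
      model <- if (identical(cand, full)) "full"
        else if (length(cand) > 1L) "baseline" else "intercept"
      return(list(draw = draw, model = model))
    }
  }
  stop("retrieved-dropout estimation sample too small (",
       length(est_y), " observations)", call. = FALSE)
}

#' Run the full pattern-mixture multiple imputation
#'
#' Orchestrates the sensitivity analysis: classifies every missing
#' post-baseline cell into patterns P1-P4ii, runs the MCMC MAR chains
#' separately by treatment arm and baseline tafamidis group (with
#' off-treatment vutrisiran observations masked out of the estimation
#' sample), draws reference posteriors for copy-reference cells and
#' retrieved-dropout regressions for off-treatment cells, caps every
#' imputed change at 0 minus baseline, and assembles `m` completed
#' datasets with full per-cell provenance.
#'
#' Reproducibility: the chain and per-imputation draws are a deterministic
#' function of `seed`; each imputation index uses its own derived RNG
#' stream.
#'
#' @param dataset a single-parameter `trial_dataset` with missingness.
#' @param m number of imputations (default 100).
#' @param seed integer seed.
#' @param window_days on-treatment window (default 126).
#' @param burnin,thin MCMC control (defaults 500/100).
#' @param pattern1_all_missing see [classify_patterns()].
#' @param registry parameter registry for worse directions.
#' @return An object of class `imputation_run`: `m`, `seed`, `patterns`,
#'   `completed` (list of m patient-by-visit change matrices),
#'   `provenance` (per cell: pattern, method, donor-pool size), and the
#'   wide patient table `patients`.
#' @export
run_pattern_mixture <- function(dataset, m = 100L, seed = 1L,
                                window_days = 126L, burnin = 500L,
                                thin = 100L, pattern1_all_missing = FALSE,
                                registry = echo_registry()) {
  stopifnot(m >= 2)
  parameter <- unique(dataset$parameter)
  stopifnot(length(parameter) == 1L)
  wide <- to_wide(dataset)
  ycols <- paste0("y_", POST_VISITS)
  Y <- as.matrix(wide[, ycols])
  rownames(Y) <- wide$patient_id
  pat <- classify_patterns(dataset, window_days, pattern1_all_missing)
  unrouted <- setdiff(which(is.na(Y)),
                      match(pat$patient_id, wide$patient_id) +
                        (match(pat$visit, POST_VISITS) - 1L) * nrow(Y))
  if (length(unrouted)) {
    stop("unroutable missing cells at matrix positions: ",
         paste(unrouted, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)

  row_of <- match(pat$patient_id, wide$patient_id)
  col_of <- match(pat$visit, POST_VISITS)
  Xcov <- imputation_covariates(wide)
  nominal <- unname(NOMINAL_DAYS[POST_VISITS])

  # --- MAR chains by arm x tafamidis group (fixed order for determinism)
  mar_pat <- c(placebo = "P4ii_placebo_mar", vutrisiran = "P2_vutri_on_treatment")
  mar_draws <- list()
  for (a in c("placebo", "vutrisiran")) for (tf in c(FALSE, TRUE)) {
    key <- paste(a, tf)
    need <- pat$pattern == mar_pat[[a]] & pat$arm == a &
      pat$baseline_tafamidis == tf
    if (!any(need)) next
    g <- which(wide$arm == a & wide$baseline_tafamidis == tf)
    Yg <- Y[g, , drop = FALSE]
    if (a == "vutrisiran") {
      # estimation restricted to on-treatment data: mask observed
      # off-treatment cells
      off <- outer(wide$last_dose_day[g], nominal,
                   function(ld, dv) dv - ld > window_days)
      Yg[off] <- NA_real_
    }
    mar_draws[[key]] <- impute_mcmc_mar(Yg, Xcov[g, , drop = FALSE],
                                        m, burnin, thin)
    attr(mar_draws[[key]], "rows") <- g
  }

  # --- copy-reference posteriors per tafamidis group (complete-case
  # placebo reference, fresh (B, Sigma) draw per imputation index)
  ref_draws <- list()
  for (tf in c(FALSE, TRUE)) {
    if (!any(pat$pattern == "P3ii_vutri_copy_reference" &
               pat$baseline_tafamidis == tf)) next
    ref <- which(wide$arm == "placebo" & wide$baseline_tafamidis == tf &
                   stats::complete.cases(Y))
    if (length(ref) < 6L) {
      stop("copy reference needs at least 6 complete placebo patients in ",
           "the tafamidis=", tf, " group; have ", length(ref),
           call. = FALSE)
    }
    bl <- wide$baseline_value[ref]
    Xref <- cbind(1, bl - mean(bl))
    ref_draws[[paste0("taf_", tf)]] <- list(
      draws = lapply(seq_len(m), function(k) niw_draw(Y[ref, , drop = FALSE],
                                                      Xref)),
      baseline_center = mean(bl)
    )
  }

  # --- retrieved-dropout estimation samples per arm x taf x visit
  rd_sets <- list()
  rd_pat <- pat[pat$pattern %in% c("P3i_vutri_retrieved",
                                   "P4i_placebo_retrieved"), , drop = FALSE]
  if (nrow(rd_pat)) {
    for (i in seq_len(nrow(rd_pat))) {
      key <- paste(rd_pat$arm[i], rd_pat$baseline_tafamidis[i],
                   rd_pat$visit[i])
      if (!is.null(rd_sets[[key]])) next
      rd <- find_retrieved_dropouts(dataset, rd_pat$arm[i],
                                    rd_pat$baseline_tafamidis[i],
                                    window_days)
      ridx <- match(rd$patients, wide$patient_id)
      v <- match(rd_pat$visit[i], POST_VISITS)
      ok <- !is.na(Y[ridx, v]) &
        (nominal[v] - wide$last_dose_day[ridx]) > window_days
      if (sum(ok) >= 3L) {
        rd_sets[[key]] <- list(est_y = Y[ridx[ok], v],
                               est_X = Xcov[ridx[ok], , drop = FALSE],
                               n_donors = sum(ok))
      } else {
        # sparse visit: pool the retrieved set's off-treatment
        # observations across visits
        offobs <- which(outer(wide$last_dose_day[ridx], nominal,
                              function(ld, dv) dv - ld > window_days) &
                          !is.na(Y[ridx, , drop = FALSE]), arr.ind = TRUE)
        rd_sets[[key]] <- list(
          est_y = Y[ridx, , drop = FALSE][offobs],
          est_X = Xcov[ridx[offobs[, 1]], , drop = FALSE],
          n_donors = nrow(offobs)
        )
      }
    }
  }

  idx_seeds <- sample.int(.Machine$integer.max - 1L, m)

  n_cells <- nrow(pat)
  prov_method <- character(n_cells)
  prov_pool <- rep(NA_integer_, n_cells)
  completed <- vector("list", m)

  for (k in seq_len(m)) {
    set.seed(idx_seeds[k])
    Yk <- Y
    for (i in seq_len(n_cells)) {
      r <- row_of[i]; cc <- col_of[i]
      p <- pat$pattern[i]
      val <- NA_real_
      if (p %in% c("P2_vutri_on_treatment", "P4ii_placebo_mar")) {
        key <- paste(pat$arm[i], pat$baseline_tafamidis[i])
        g <- attr(mar_draws[[key]], "rows")
        val <- mar_draws[[key]][[k]][match(r, g), cc]
        prov_method[i] <- "mcmc_mar"
        prov_pool[i] <- length(g)
      } else if (p == "P1_death") {
        wd <- impute_worst_decile(
          list(visit = pat$visit[i], arm = pat$arm[i],
               baseline_tafamidis = pat$baseline_tafamidis[i],
               baseline_value = wide$baseline_value[r]),
          dataset, registry, n_draws = 1L)
        val <- wd$draws
        prov_method[i] <- if (wd$fallback) "worst_decile_arm_pool"
          else "worst_decile"
        prov_pool[i] <- wd$donor_pool_size
      } else if (p == "P3ii_vutri_copy_reference") {
        rg <- ref_draws[[paste0("taf_", pat$baseline_tafamidis[i])]]
        x <- c(1, wide$baseline_value[r] - rg$baseline_center)
        filled <- impute_copy_reference(Y[r, ], cc, x, rg$draws[[k]])
        val <- filled[cc]
        prov_method[i] <- "copy_reference"
        prov_pool[i] <- NA_integer_
      } else {  # retrieved dropout
        key <- paste(pat$arm[i], pat$baseline_tafamidis[i], pat$visit[i])
        rs <- rd_sets[[key]]
        rd <- impute_retrieved_dropout(Xcov[r, ], rs$est_y, rs$est_X)
        val <- rd$draw
        prov_method[i] <- paste0("retrieved_dropout_", rd$model)
        prov_pool[i] <- rs$n_donors
      }
      Yk[r, cc] <- apply_cap(val, wide$baseline_value[r])
    }
    completed[[k]] <- Yk
  }

  provenance <- if (n_cells) {
    do.call(rbind, lapply(seq_len(m), function(k) {
      data.frame(patient_id = pat$patient_id, visit = pat$visit,
                 imputation_index = rep(k, n_cells), pattern = pat$pattern,
                 method = prov_method, donor_pool_size = prov_pool,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(patient_id = character(), visit = character(),
               imputation_index = integer(), pattern = character(),
               method = character(), donor_pool_size = integer(),
               stringsAsFactors = FALSE)
  }

  structure(list(
    m = m, seed = seed, parameter = parameter, window_days = window_days,
    patterns = pat, patients = wide, completed = completed,
    provenance = provenance
  ), class = "imputation_run")
}

#' Extract one completed dataset from an imputation run
#'
#' @param run an `imputation_run`.
#' @param k imputation index in `1:m`.
#' @return A `trial_dataset` with no missing post-baseline changes.
#' @export
completed_dataset <- function(run, k) {
  stopifnot(inherits(run, "imputation_run"), k >= 1, k <= run$m)
  wide <- run$patients
  wide[, paste0("y_", POST_VISITS)] <- run$completed[[k]]
  from_wide(wide, run$parameter)
}

#' @export
print.imputation_run <- function(x, ...) {
  cat("Pattern-mixture imputation run: m =", x$m, ", seed =", x$seed, "\n")
  cat("Missing cells by pattern:\n")
  print(table(x$patterns$pattern))
  invisible(x)
}
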