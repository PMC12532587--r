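# shared fixtures and independent oracles used across test files

POSTV <- c("m12", "m18", "m24", "m30")

null_profile <- function(base = c(-2.5, -3.7, -5.0, -6.2)) {
  list(placebo = base, vutrisiran = base)
}

# complete, tafamidis-free trial for closed-form oracles
oracle_trial <- function(n_per_arm = 20, seed = 7) {
  cfg <- trial_config(n_per_arm = n_per_arm, tafamidis_fraction = 0,
                      death_hazard = 0, discontinuation_hazard = 0,
                      missingness_mode = "none", seed = seed)
  list(cfg = cfg, data = simulate_trial(cfg))
}

change_matrix <- function(dataset) {
  w <- to_wide(dataset)
  list(Y = as.matrix(w[, paste0("y_", POSTV)]), arm = w$arm, wide = w)
}

# pooled within-arm sample covariance with divisor n - (number of arms):
# the closed-form REML estimate under saturated arm-by-visit means
pooled_within_arm_cov <- function(Y, arm) {
  SS <- matrix(0, ncol(Y), ncol(Y))
  for (a in unique(arm)) {
    SS <- SS + crossprod(scale(Y[arm == a, , drop = FALSE], scale = FALSE))
  }
  SS / (nrow(Y) - length(unique(arm)))
}

# naive per-subject REML objective: independent of the package's
# sufficient-statistic path; used as a black-box oracle
naive_neg2reml <- function(design, theta) {
  d <- length(design$visits)
  L <- diag(exp(theta[seq_len(d)]), d)
  if (d > 1) L[lower.tri(L)] <- theta[(d + 1):length(theta)]
  S <- L %*% t(L)
  X <- design$X; y <- design$y
  sub <- design$subject; vi <- design$visit_idx
  q <- ncol(X)
  XtWX <- matrix(0, q, q); XtWy <- numeric(q); ld <- 0
  for (i in unique(sub)) {
    idx <- which(sub == i); J <- vi[idx]
    W <- solve(S[J, J, drop = FALSE])
    XtWX <- XtWX + t(X[idx, , drop = FALSE]) %*% W %*% X[idx, , drop = FALSE]
    XtWy <- XtWy + t(X[idx, , drop = FALSE]) %*% W %*% y[idx]
    ld <- ld + as.numeric(determinant(S[J, J, drop = FALSE])$modulus)
  }
  b <- solve(XtWX, XtWy)
  quad <- 0
  for (i in unique(sub)) {
    idx <- which(sub == i); J <- vi[idx]
    r <- y[idx] - X[idx, , drop = FALSE] %*% b
    quad <- quad + drop(t(r) %*% solve(S[J, J, drop = FALSE]) %*% r)
  }
  ld + quad + as.numeric(determinant(XtWX)$modulus)
}

# hand-built four-patient-per-cell fixture covering all routing patterns
routing_fixture <- function() {
  mk <- function(id, arm, taf, death, last_dose, disc, y) {
    data.frame(patient_id = id, arm = arm, baseline_tafamidis = taf,
               attr_type = sample(c("wild_type", "variant"), 1),
               age_group = sample(c("lt75", "ge75"), 1),
               nyha = sample(c("I_II", "III"), 1),
               ntprobnp_high = stats::runif(1) < 0.3, death_day = death,
               last_dose_day = last_dose, discontinued = disc,
               baseline_value = 55 + stats::rnorm(1, 0, 6),
               y_m12 = y[1], y_m18 = y[2], y_m24 = y[3], y_m30 = y[4],
               stringsAsFactors = FALSE)
  }
  rows <- list(
    # P1: died day 700, missing m24/m30
    mk("p1", "vutrisiran", FALSE, 700L, 672L, FALSE, c(-1, -2, NA, NA)),
    # P2: on-treatment gap at m18 (last dose at study end)
    mk("p2", "vutrisiran", FALSE, NA, 840L, FALSE, c(-1, NA, -2, -3)),
    # P3: discontinued day 430, last dose 420; m24/m30 off treatment
    mk("p3", "vutrisiran", FALSE, NA, 420L, TRUE, c(-1, -2, NA, NA)),
    # P4: placebo discontinued, off-treatment m30 missing
    mk("p4", "placebo", FALSE, NA, 420L, TRUE, c(-2, -3, NA, NA))
  )
  # donors: complete patients in both arms so pools/references exist
  for (i in 1:30) {
    rows[[length(rows) + 1]] <-
      mk(sprintf("d%02d", i), if (i %% 2) "placebo" else "vutrisiran",
         FALSE, NA, 840L, FALSE, c(-1, -2, -3, -4) + stats::rnorm(4, 0, 0.5))
  }
  from_wide(do.call(rbind, rows), "lvef")
}
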