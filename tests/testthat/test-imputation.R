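test_that("MCMC imputation leaves complete data untouched", {
  set.seed(40)
  Y <- matrix(rnorm(80), 20, 4)
  X <- cbind(1, rnorm(20))
  out <- impute_mcmc_mar(Y, X, m = 5)
  expect_length(out, 5)
  for (k in 1:5) expect_identical(out[[k]], Y)
})

test_that("single-visit MCMC imputation matches the conjugate regression
           posterior", {
  set.seed(41)
  n <- 300
  x <- rnorm(n)
  y <- 2 + 1.5 * x + rnorm(n, 0, 1)
  miss <- seq_len(60)  # MCAR subset
  yna <- y
  yna[miss] <- NA
  X <- cbind(1, x)
  out <- impute_mcmc_mar(matrix(yna, ncol = 1), X, m = 60,
                         burnin = 200, thin = 20)
  imp <- sapply(out, function(Yk) Yk[miss, 1])
  # posterior-predictive mean equals the OLS prediction from observed rows
  fit <- lm(y[-miss] ~ x[-miss])
  pred <- fit$coefficients[1] + fit$coefficients[2] * x[miss]
  mc_se <- sqrt(1 / length(out)) * 1.2  # residual sd about 1
  expect_lt(abs(mean(imp - pred)), 3 * mc_se)
})

test_that("MCMC imputation draws missing cells with observed cells fixed", {
  set.seed(42)
  cfg <- trial_config(n_per_arm = 60, tafamidis_fraction = 0,
                      missingness_mode = "mcar", missingness_rate = 0.2,
                      death_hazard = 0, discontinuation_hazard = 0,
                      seed = 43)
  d <- apply_missingness(simulate_trial(cfg), cfg)
  w <- to_wide(d)
  Y <- as.matrix(w[, paste0("y_", POSTV)])
  out <- impute_mcmc_mar(Y, echosens:::imputation_covariates(w), m = 3,
                         burnin = 50, thin = 10)
  for (k in 1:3) {
    expect_false(anyNA(out[[k]]))
    expect_identical(out[[k]][!is.na(Y)], Y[!is.na(Y)])
  }
  # too few subjects for the covariate count aborts with a diagnostic
  expect_error(impute_mcmc_mar(Y[1:8, ], echosens:::imputation_covariates(w)[1:8, ],
                               m = 2), "estimation subjects")
})

test_that("retrieved-dropout imputation is exact for a degenerate donor set", {
  set.seed(44)
  est_X <- cbind(`(Intercept)` = 1, baseline = rnorm(12, 55, 5))
  est_y <- rep(-4.2, 12)  # identical change, zero residual variance
  draws <- replicate(20, impute_retrieved_dropout(c(1, 50), est_y, est_X)$draw)
  expect_equal(unname(draws), rep(-4.2, 20), tolerance = 1e-4)
  # singular design falls back rather than aborting
  bad_X <- cbind(`(Intercept)` = 1, baseline = rep(55, 12))
  out <- impute_retrieved_dropout(c(1, 55), est_y + rnorm(12, 0, 0.1), bad_X)
  expect_true(out$model %in% c("baseline", "intercept"))
  expect_error(impute_retrieved_dropout(c(1, 55), est_y[1], bad_X[1, , drop = FALSE]),
               "too small")
})

test_that("copy reference draws from the reference conditional", {
  set.seed(45)
  Sigma <- diag(4) + 0.5
  B <- rbind(c(-2, -3, -4, -5), c(0.1, 0.1, 0.1, 0.1))
  # no observed post-baseline values: marginal reference draw
  y <- rep(NA_real_, 4)
  draws <- replicate(4000, impute_copy_reference(y, 4, c(1, 0),
                                                 list(B = B, Sigma = Sigma))[4])
  expect_lt(abs(mean(draws) - (-5)), 3 * sqrt(1.5 / 4000))
  # conditioning shifts the mean: observed m24 far below its mean
  y2 <- c(NA, NA, -10, NA)
  draws2 <- replicate(4000, impute_copy_reference(y2, 4, c(1, 0),
                                                  list(B = B, Sigma = Sigma))[4])
  shift <- 0.5 / 1.5 * (-10 - (-4))  # Sigma_mo / Sigma_oo * deviation
  expect_lt(abs(mean(draws2) - (-5 + shift)), 3 * sqrt(1.5 / 4000))
})

test_that("copy reference tracks a shifted placebo profile", {
  # treated arm identical to placebo: copy-reference and MAR imputation
  # agree in mean; placebo worse by delta: copy-reference shifts by delta
  # the dominant noise is the estimation error of the two reference models
  # (~sd/sqrt(n) each), so large arms and several seeds keep the check
  # well powered; m mainly averages the posterior draws
  run_one <- function(delta, seed) {
    prof <- null_profile(c(-2, -3, -4, -5))
    prof$placebo <- prof$placebo - c(0, 0, 0, delta)
    cfg <- trial_config(n_per_arm = 500, tafamidis_fraction = 0,
                        mean_profile_by_arm = prof, baseline_effect = 0,
                        death_hazard = 0, discontinuation_hazard = 0,
                        missingness_mode = "none", seed = seed)
    d <- simulate_trial(cfg)
    w <- to_wide(d)
    # 100 treated dropouts: last dose day 420, m30 deleted
    drop_ids <- head(w$patient_id[w$arm == "vutrisiran"], 100)
    w$discontinued[w$patient_id %in% drop_ids] <- TRUE
    w$last_dose_day[w$patient_id %in% drop_ids] <- 420L
    w$y_m30[w$patient_id %in% drop_ids] <- NA
    d2 <- from_wide(w, "lvef")
    run_cr <- run_pattern_mixture(d2, m = 10, seed = 900 + seed,
                                  burnin = 100, thin = 20)
    # same cells under MAR: an effectively infinite window routes them P2
    run_mar <- run_pattern_mixture(d2, m = 10, seed = 900 + seed,
                                   window_days = 100000L,
                                   burnin = 100, thin = 20)
    stopifnot(all(run_cr$patterns$pattern == "P3ii_vutri_copy_reference"),
              all(run_mar$patterns$pattern == "P2_vutri_on_treatment"))
    idx <- cbind(match(drop_ids, w$patient_id), 4)
    c(cr = mean(sapply(run_cr$completed, function(Y) mean(Y[idx]))),
      mar = mean(sapply(run_mar$completed, function(Y) mean(Y[idx]))))
  }
  null_gaps <- sapply(46:48, function(s) {
    r <- run_one(0, s)
    r["cr"] - r["mar"]
  })
  expect_lt(abs(mean(null_gaps)), 1.0)
  shift_res <- run_one(6, 49)
  expect_lt(abs((shift_res["mar"] - shift_res["cr"]) - 6), 2.0)
})

test_that("a run without missingness returns m identical copies", {
  tr <- oracle_trial(n_per_arm = 15, seed = 48)
  run <- run_pattern_mixture(tr$data, m = 3, seed = 49)
  cm <- change_matrix(tr$data)
  for (k in 1:3) expect_equal(unname(run$completed[[k]]), unname(cm$Y))
  expect_equal(nrow(run$patterns), 0)
})

test_that("the orchestrator routes, caps, and is seed-deterministic", {
  set.seed(50)
  d <- routing_fixture()
  run <- run_pattern_mixture(d, m = 6, seed = 51, burnin = 100, thin = 20)
  # routing provenance covers exactly the expected pattern set
  expect_setequal(unique(run$provenance$pattern),
                  c("P1_death", "P2_vutri_on_treatment",
                    "P3ii_vutri_copy_reference", "P4ii_placebo_mar"))
  # completed datasets are gap-free and respect the cap
  w <- run$patients
  miss_idx <- which(is.na(as.matrix(w[, paste0("y_", POSTV)])))
  rows <- (miss_idx - 1) %% nrow(w) + 1
  for (k in 1:6) {
    expect_false(anyNA(run$completed[[k]]))
    expect_true(all(run$completed[[k]][miss_idx] +
                      w$baseline_value[rows] >= -1e-9))
  }
  # observed cells never altered
  obs_idx <- which(!is.na(as.matrix(w[, paste0("y_", POSTV)])))
  expect_identical(run$completed[[3]][obs_idx],
                   as.matrix(w[, paste0("y_", POSTV)])[obs_idx])
  # determinism and per-index independence
  run2 <- run_pattern_mixture(d, m = 6, seed = 51, burnin = 100, thin = 20)
  expect_identical(run$completed, run2$completed)
  expect_false(identical(run$completed[[1]], run$completed[[2]]))
  expect_error(run_pattern_mixture(d, m = 1, seed = 1), "m >= 2")
})

test_that("completed datasets round-trip into the long trial format", {
  set.seed(52)
  d <- routing_fixture()
  run <- run_pattern_mixture(d, m = 2, seed = 53, burnin = 100, thin = 20)
  cd <- completed_dataset(run, 1)
  expect_s3_class(cd, "trial_dataset")
  expect_true(all(cd$observed[cd$visit != "baseline"]))
  expect_false(anyNA(cd$change_from_baseline))
})
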