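test_that("the routing fixture hits every pattern exactly as prescribed", {
  set.seed(101)
  d <- routing_fixture()
  pat <- classify_patterns(d)
  get <- function(id) sort(paste(pat$visit[pat$patient_id == id],
                                 pat$pattern[pat$patient_id == id]))
  # died day 700: m24 (day 730) and m30 (day 913) are P1
  expect_equal(get("p1"), c("m24 P1_death", "m30 P1_death"))
  # on-treatment gap: 548 - 840 < 126 days after last dose
  expect_equal(get("p2"), "m18 P2_vutri_on_treatment")
  # off-treatment vutrisiran without 10 retrieved dropouts: copy reference
  expect_equal(get("p3"), c("m24 P3ii_vutri_copy_reference",
                            "m30 P3ii_vutri_copy_reference"))
  # placebo off-treatment without retrieved dropouts: MAR
  expect_equal(get("p4"), c("m24 P4ii_placebo_mar", "m30 P4ii_placebo_mar"))
})

test_that("window arithmetic routes P2 vs P3 at 126 days", {
  set.seed(102)
  d <- routing_fixture()
  w <- to_wide(d)
  # vutrisiran, last dose 440, missing visit at day 548: 108 <= 126 days
  w$last_dose_day[w$patient_id == "p2"] <- 440L
  d2 <- from_wide(w, "lvef")
  pat <- classify_patterns(d2)
  expect_equal(pat$pattern[pat$patient_id == "p2"], "P2_vutri_on_treatment")
  expect_equal(pat$days_since_last_dose[pat$patient_id == "p2"], 548 - 440)
  # last dose 300, missing at day 548: 248 > 126 days
  w$last_dose_day[w$patient_id == "p2"] <- 300L
  pat2 <- classify_patterns(from_wide(w, "lvef"))
  expect_match(pat2$pattern[pat2$patient_id == "p2"], "^P3")
})

test_that("retrieved-dropout sufficiency switches at exactly 10 patients", {
  set.seed(103)
  base <- routing_fixture()
  add_retrieved <- function(d, k) {
    w <- to_wide(d)
    for (i in seq_len(k)) {
      row <- w[w$patient_id == "d02", ]
      row$patient_id <- sprintf("r%02d", i)
      row$arm <- "vutrisiran"
      row$discontinued <- TRUE
      row$last_dose_day <- 420L  # 913 - 420 = 493 > 126: qualifies at m30
      row[, paste0("y_", POSTV)] <- c(-1, -2, NA, -5)
      w <- rbind(w, row)
    }
    from_wide(w, "lvef")
  }
  d9 <- add_retrieved(base, 9)
  expect_false(find_retrieved_dropouts(d9, "vutrisiran", FALSE)$sufficient)
  expect_equal(classify_patterns(d9)$pattern[
    classify_patterns(d9)$patient_id == "p3"][1],
    "P3ii_vutri_copy_reference")
  d10 <- add_retrieved(base, 10)
  rd <- find_retrieved_dropouts(d10, "vutrisiran", FALSE)
  expect_true(rd$sufficient)
  expect_equal(length(rd$patients), 10)
  expect_equal(classify_patterns(d10)$pattern[
    classify_patterns(d10)$patient_id == "p3"][1], "P3i_vutri_retrieved")
})

test_that("an on-treatment month-30 assessment does not count as retrieved", {
  set.seed(104)
  d <- routing_fixture()
  w <- to_wide(d)
  # discontinued but last dose 840: 913 - 840 = 73 <= 126 days
  w$discontinued[w$patient_id == "d02"] <- TRUE
  w$last_dose_day[w$patient_id == "d02"] <- 840L
  d2 <- from_wide(w, "lvef")
  expect_false("d02" %in%
                 find_retrieved_dropouts(d2, "vutrisiran", FALSE)$patients)
})

test_that("worst-decile pools take the extreme tail in the worse direction", {
  pool10 <- c(-12, -3, -2, -1, 0, 1, 2, 3, 4, 5)
  expect_equal(worst_decile_pool(pool10, "decrease_is_worse"), -12)
  pool20 <- c(-12, -9, seq(-5, 12, length.out = 18))
  expect_equal(sort(worst_decile_pool(pool20, "decrease_is_worse")),
               c(-12, -9))
  expect_equal(sort(worst_decile_pool(pool20, "increase_is_worse")),
               sort(tail(sort(pool20), 2)))
  expect_error(worst_decile_pool(numeric(0), "decrease_is_worse"), "empty")
})

test_that("worst-decile imputation draws from the right pool and caps", {
  set.seed(105)
  d <- routing_fixture()
  cell <- list(visit = "m30", arm = "vutrisiran", baseline_tafamidis = FALSE,
               baseline_value = 55)
  out <- impute_worst_decile(cell, d, n_draws = 50)
  obs <- d$change_from_baseline[d$visit == "m30" & d$observed &
                                  d$arm == "vutrisiran"]
  worst <- worst_decile_pool(obs, "decrease_is_worse")
  expect_true(all(out$draws %in% apply_cap(worst, 55)))
  expect_equal(out$donor_pool_size, length(worst))
  # cap binds when baseline is small
  cell$baseline_value <- 2
  out2 <- impute_worst_decile(cell, d, n_draws = 20)
  expect_true(all(out2$draws >= -2))
})

test_that("the cap floors imputed changes at zero minus baseline", {
  expect_equal(apply_cap(-60, 55), -55)
  expect_equal(apply_cap(-3, 55), -3)
  expect_equal(apply_cap(5, 18), 5)  # lower bound only
  expect_equal(apply_cap(c(-60, -3, 5), c(55, 55, 18)), c(-55, -3, 5))
})

test_that("every missing cell gets exactly one pattern under random
           death/dosing configurations", {
  for (r in 1:12) {
    cfg <- trial_config(n_per_arm = 60, missingness_mode = "mcar",
                        missingness_rate = 0.1, death_hazard = 2e-4,
                        discontinuation_hazard = 6e-4,
                        off_treatment_retention = 0.5, seed = 300 + r)
    d <- apply_missingness(simulate_trial(cfg), cfg)
    pat <- classify_patterns(d)
    n_missing <- sum(!d$observed[d$visit != "baseline"])
    expect_equal(nrow(pat), n_missing)
    expect_false(any(duplicated(pat[, c("patient_id", "visit")])))
    expect_true(all(pat$pattern %in% echosens:::PATTERNS))
    # arm exclusivity: P2/P3 vutrisiran only, P4 placebo only
    expect_true(all(pat$arm[grepl("^P2|^P3", pat$pattern)] == "vutrisiran"))
    expect_true(all(pat$arm[grepl("^P4", pat$pattern)] == "placebo"))
    # P1 overrides the window rules after death
    died <- !is.na(pat$days_since_last_dose)
    p1 <- pat$pattern == "P1_death"
    w <- to_wide(d)
    dd <- w$death_day[match(pat$patient_id, w$patient_id)]
    expect_true(all(pat$pattern[!is.na(dd) & dd < 913 &
                                  pat$nominal_day >= dd] == "P1_death"))
  }
})

test_that("a vutrisiran patient without dosing information is a
           configuration error", {
  d <- routing_fixture()
  w <- to_wide(d)
  w$last_dose_day[w$patient_id == "p2"] <- NA_integer_
  expect_error(classify_patterns(from_wide(w, "lvef")), "p2")
})
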