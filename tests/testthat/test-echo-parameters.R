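test_that("mean LV wall thickness averages septal and posterior walls", {
  expect_equal(mean_lv_wall_thickness(18, 18), 18)
  expect_equal(mean_lv_wall_thickness(20, 16), 18)
  expect_equal(mean_lv_wall_thickness(18.3, 18.1), 18.2)
  expect_error(mean_lv_wall_thickness(-1, 10), "non-negative")
})

test_that("relative wall thickness is 2*PWd/LVEDD with a positive LVEDD", {
  expect_equal(relative_wall_thickness(10, 40), 0.5)
  expect_equal(relative_wall_thickness(0, 40), 0)
  expect_equal(relative_wall_thickness(18.2, 42.7), 2 * 18.2 / 42.7)
  expect_error(relative_wall_thickness(10, 0), "positive")
})

test_that("Devereux mass matches independent hand evaluation", {
  # zero wall thickness leaves only the additive constant
  expect_equal(lv_mass_devereux(0, 4.3, 0), 0.6)
  # independent evaluation: 0.8*1.04*((1.8+4.3+1.8)^3 - 4.3^3) + 0.6
  hand <- 0.8 * 1.04 * ((1.8 + 4.3 + 1.8)^3 - 4.3^3) + 0.6
  expect_equal(lv_mass_devereux(1.8, 4.3, 1.8), hand)
  expect_equal(signif(lv_mass_devereux(1.8, 4.3, 1.8), 4), 344.7)
  # indexing: Table-1 magnitude
  expect_equal(round(index_to_bsa(lv_mass_devereux(1.8, 4.3, 1.8), 1.90), 1),
               181.4)
  expect_error(index_to_bsa(300, 0), "positive")
  # mm-scale inputs are a unit error, not silently converted
  expect_error(lv_mass_devereux(18, 43, 18), "cm")
})

test_that("body surface area follows Du Bois with a Mosteller option", {
  expect_equal(body_surface_area(180, 80),
               0.007184 * 180^0.725 * 80^0.425)
  expect_equal(round(body_surface_area(180, 80), 3), 1.996)
  expect_equal(body_surface_area(1, 1), 0.007184)
  # doubling weight at fixed height scales BSA by 2^0.425
  expect_equal(body_surface_area(170, 140) / body_surface_area(170, 70),
               2^0.425)
  expect_equal(body_surface_area(180, 80, "mosteller"),
               sqrt(180 * 80 / 3600))
  expect_error(body_surface_area(0, 80), "positive")
})

test_that("biplane Simpson volume reduces to the cylinder closed form", {
  # all discs equal d in both planes: (pi/4) d^2 L
  expect_equal(biplane_simpson_volume(rep(4, 20), rep(4, 20), 8),
               (pi / 4) * 16 * 8)
  expect_equal(round(biplane_simpson_volume(rep(4, 20), rep(4, 20), 8), 2),
               100.53)
  # brute-force disc summation on unequal discs
  set.seed(1)
  a <- runif(20, 2, 5); b <- runif(20, 2, 5); L <- 7.5
  brute <- sum(pi / 4 * a * b * (L / 20))
  expect_equal(biplane_simpson_volume(a, b, L), brute)
  expect_error(biplane_simpson_volume(rep(4, 19), rep(4, 20), 8), "length 20")
})

test_that("ejection fraction and LVOT stroke volume match hand arithmetic", {
  expect_equal(round(lvef(95.6, 43.4), 1), 54.6)
  expect_true(lvef(95.6, 43.4) >= 0 && lvef(95.6, 43.4) <= 100)
  expect_error(lvef(0, 0), "positive")
  expect_error(lvef(50, 60), "exceed")
  expect_equal(stroke_volume_lvot(2.0, 0), 0)
  expect_equal(stroke_volume_lvot(2.0, 16.5), pi * 1^2 * 16.5)
  expect_equal(signif(stroke_volume_lvot(2.0, 16.5), 3), 51.8)
  expect_equal(stroke_volume_lvot(4, 10) / stroke_volume_lvot(2, 10), 4)
})

test_that("Doppler ratios cancel units and flag zero denominators", {
  r <- doppler_ratios(806.7, 489.0, 58.5, 41.3)
  expect_equal(round(r$e_over_e_prime_lateral, 2), 13.79)
  expect_equal(r$e_a_ratio, 806.7 / 489.0)
  expect_equal(r$e_over_e_prime_average, 806.7 / mean(c(58.5, 41.3)))
  expect_equal(doppler_ratios(500, 500)$e_a_ratio, 1)
  same <- doppler_ratios(800, e_prime_lateral = 50, e_prime_septal = 50)
  expect_equal(same$e_over_e_prime_average, 800 / 50)
  # zero denominator: the ratio is flagged missing, not an abort
  z <- doppler_ratios(800, a_wave = 0)
  expect_true(is.na(z$e_a_ratio))
})

test_that("change from baseline propagates missing visits and needs baseline", {
  cf <- change_from_baseline(c(baseline = 55, m12 = 53, m18 = NA,
                               m24 = 50, m30 = 49))
  expect_equal(cf$change_from_baseline, c(-2, NA, -5, -6))
  expect_equal(cf$observed, c(TRUE, FALSE, TRUE, TRUE))
  flat <- change_from_baseline(c(baseline = 18.2, m12 = 18.2, m18 = 18.2,
                                 m24 = 18.2, m30 = 18.2))
  expect_equal(flat$change_from_baseline, rep(0, 4))
  expect_error(change_from_baseline(c(baseline = NA, m12 = 53)), "excluded")
})

test_that("derived panel is a pure function of the record", {
  rec <- list(ivsd = 18, pwd = 18.4, lvedd = 43, height = 180, weight = 80,
              lvot_diameter = 2.0, lvot_vti = 16.5,
              e_wave = 800, a_wave = 420,
              e_prime_lateral = 58, e_prime_septal = 41, gls = -14.2)
  p1 <- derive_panel(rec)
  p2 <- derive_panel(rec)
  expect_identical(p1, p2)
  expect_equal(p1$mean_lv_wall_thickness, 18.2)
  expect_equal(p1$relative_wall_thickness, 2 * 18.4 / 43)
  expect_equal(p1$stroke_volume, stroke_volume_lvot(2.0, 16.5))
  expect_equal(p1$lv_mass_index,
               lv_mass_devereux(1.8, 4.3, 1.84) / body_surface_area(180, 80))
  expect_equal(p1$absolute_gls, 14.2)
  # cm-scale linear dimensions are rejected, never converted
  expect_error(derive_panel(list(ivsd = 1.8, pwd = 1.8, lvedd = 4.3)), "mm")
  expect_error(derive_panel(list(lvot_diameter = 20, lvot_vti = 16.5)), "cm")
})

test_that("registry covers the reported parameters with directions", {
  reg <- echo_registry()
  expect_false(any(duplicated(reg$key)))
  for (k in c("mean_lv_wall_thickness", "lv_mass_index", "lvef",
              "absolute_gls", "stroke_volume", "e_over_e_prime_average",
              "e_a_ratio", "rv_s_prime", "ivc_diameter", "tr_velocity")) {
    expect_true(k %in% reg$key, label = paste("registry has", k))
  }
  expect_equal(worse_direction("lvef"), "decrease_is_worse")
  expect_equal(worse_direction("mean_lv_wall_thickness"), "increase_is_worse")
  expect_equal(worse_direction("absolute_gls"), "decrease_is_worse")
  # registry is configurable
  over <- echo_registry(overrides = c(lvef = "increase_is_worse"))
  expect_equal(worse_direction("lvef", over), "increase_is_worse")
  expect_error(echo_registry(overrides = c(nope = "increase_is_worse")),
               "unknown")
})
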